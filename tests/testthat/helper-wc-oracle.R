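# Independent brute-force evaluation of the Weir & Cockerham (1984)
# variance components, written as plain per-allele loops straight from the
# published component definitions. Used only as a test oracle; deliberately
# shares no code with the package implementation.

oracle_fis <- function(a1, a2) {
  a1 <- unname(a1); a2 <- unname(a2)
  n <- length(a1)
  alleles <- unique(c(a1, a2))
  if (length(alleles) < 2 || n < 2) return(NA_real_)
  sum_b <- 0; sum_c <- 0
  for (al in alleles) {
    cnt <- 0; nhet <- 0
    for (i in seq_len(n)) {
      cnt <- cnt + (a1[i] == al) + (a2[i] == al)
      if (a1[i] != a2[i] && (a1[i] == al || a2[i] == al)) nhet <- nhet + 1
    }
    p <- cnt / (2 * n)
    hbar <- nhet / n
    b <- (n / (n - 1)) * (p * (1 - p) - ((2 * n - 1) / (4 * n)) * hbar)
    cc <- hbar / 2
    sum_b <- sum_b + b; sum_c <- sum_c + cc
  }
  if (sum_b + sum_c == 0) return(NA_real_)
  1 - sum_c / (sum_b + sum_c)
}

oracle_theta <- function(a1, a2, sex) {
  a1 <- unname(a1); a2 <- unname(a2)
  f <- sex == "F"
  n1 <- sum(f); n2 <- sum(!f)
  if (n1 < 2 || n2 < 2) return(NA_real_)
  alleles <- unique(c(a1, a2))
  if (length(alleles) < 2) return(NA_real_)
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  sum_a <- 0; sum_b <- 0; sum_c <- 0
  for (al in alleles) {
    count_in <- function(idx) {
      cnt <- 0; nhet <- 0
      for (i in idx) {
        cnt <- cnt + (a1[i] == al) + (a2[i] == al)
        if (a1[i] != a2[i] && (a1[i] == al || a2[i] == al)) nhet <- nhet + 1
      }
      c(cnt, nhet)
    }
    g1 <- count_in(which(f)); g2 <- count_in(which(!f))
    p1 <- g1[1] / (2 * n1); p2 <- g2[1] / (2 * n2)
    h1 <- g1[2] / n1; h2 <- g2[2] / n2
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) -
      ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    sum_a <- sum_a + a; sum_b <- sum_b + b; sum_c <- sum_c + cc
  }
  den <- sum_a + sum_b + sum_c
  if (den == 0) return(NA_real_)
  sum_a / den
}

# random small tables (<= 3 individuals per sex, <= 3 alleles) for the
# oracle-equivalence suite
random_small_table <- function(seed) {
  set.seed(seed)
  n_f <- sample(2:3, 1); n_m <- sample(2:3, 1)
  alleles <- c(150L, 152L, 154L)[seq_len(sample(2:3, 1))]
  n <- n_f + n_m
  a1 <- sample(alleles, n, replace = TRUE)
  a2 <- sample(alleles, n, replace = TRUE)
  genotype_table(sprintf("i%02d", 1:n), "L1",
                 matrix(a1), matrix(a2),
                 sex = rep(c("F", "M"), c(n_f, n_m)))
}
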