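# run expr with a locally-seeded RNG, restoring global state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# per-individual allele-dosage and heterozygote-indicator matrices for one
# locus (typed individuals only); columns are the distinct alleles
make_dosage <- function(a1, a2) {
  alleles <- sort(unique(c(a1, a2)))
  k1 <- match(a1, alleles); k2 <- match(a2, alleles)
  n <- length(a1); K <- length(alleles)
  dos <- matrix(0L, n, K)
  dos[cbind(seq_len(n), k1)] <- dos[cbind(seq_len(n), k1)] + 1L
  dos[cbind(seq_len(n), k2)] <- dos[cbind(seq_len(n), k2)] + 1L
  het <- matrix(FALSE, n, K)
  is_het <- k1 != k2
  het[cbind(which(is_het), k1[is_het])] <- TRUE
  het[cbind(which(is_het), k2[is_het])] <- TRUE
  list(alleles = alleles, dos = dos, het = het)
}

# Weir-Cockerham (1984) within-sample inbreeding coefficient f for a single
# sample, from dosage/het matrices: per allele, b and c variance components,
# f = 1 - sum(c)/sum(b+c). NA when monomorphic (denominator 0).
fis_from_mats <- function(dos, het) {
  n <- nrow(dos)
  if (n < 2) return(NA_real_)
  p <- colSums(dos) / (2 * n)
  hbar <- colMeans(het)
  b <- (n / (n - 1)) * (p * (1 - p) - (2 * n - 1) / (4 * n) * hbar)
  cc <- hbar / 2
  den <- sum(b + cc)
  if (abs(den) < .Machine$double.eps * 4) return(NA_real_)
  1 - sum(cc) / den
}

# Weir-Cockerham (1984) theta for a 2-group partition, components a, b, c
# summed over alleles before the ratio. is_m: logical, TRUE = group 2.
theta_from_mats <- function(dos, het, is_m) {
  n2 <- sum(is_m); n1 <- nrow(dos) - n2
  if (n1 < 2 || n2 < 2) return(NA_real_)
  d1 <- colSums(dos[!is_m, , drop = FALSE])
  d2 <- colSums(dos[is_m, , drop = FALSE])
  p1 <- d1 / (2 * n1); p2 <- d2 / (2 * n2)
  h1 <- colSums(het[!is_m, , drop = FALSE]) / n1
  h2 <- colSums(het[is_m, , drop = FALSE]) / n2
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  den <- sum(a + b + cc)
  if (abs(den) < .Machine$double.eps * 4) return(NA_real_)
  sum(a) / den
}

#' Per-locus heterozygosity statistics
#'
#' Observed heterozygosity, unbiased expected heterozygosity and allele
#' count for one locus in one sex group. `H_E` uses the small-sample
#' correction `(2n/(2n-1)) * (1 - sum(p_i^2))` with `n` typed diploids.
#'
#' @param table a [genotype_table()].
#' @param locus locus name.
#' @param group `"ALL"`, `"F"` or `"M"`.
#' @return data.frame with columns `locus`, `group`, `n_typed`, `A`,
#'   `H_O`, `H_E`.
#' @export
het_stats <- function(table, locus, group = "ALL") {
  tc <- typed_calls(table, locus, group_rows(table, group))
  n <- length(tc$a1)
  if (n == 0) stop("no typed individuals at ", locus, " in group ", group)
  alleles <- c(tc$a1, tc$a2)
  p <- as.numeric(table(alleles)) / (2 * n)
  A <- length(p)
  H_O <- mean(tc$a1 != tc$a2)
  H_E <- if (n > 1) (2 * n / (2 * n - 1)) * (1 - sum(p^2)) else 1 - sum(p^2)
  data.frame(locus = locus, group = group, n_typed = n, A = A,
             H_O = H_O, H_E = H_E, stringsAsFactors = FALSE)
}

#' Weir-Cockerham within-group inbreeding coefficient (F_IS)
#'
#' The small-sample estimator `f` of Weir & Cockerham (1984) for a single
#' sample, computed from per-allele variance components. Negative values
#' indicate heterozygote excess (the male signature of a fixed X/Y allele
#' difference), positive values a heterozygote deficit (the signature of
#' null alleles).
#'
#' @inheritParams het_stats
#' @return Numeric `f` in `[-1, 1]`, or `NA` if the group is monomorphic at
#'   the locus (F_IS is undefined there, not zero).
#' @export
fis_wc <- function(table, locus, group = "ALL") {
  tc <- typed_calls(table, locus, group_rows(table, group))
  if (length(tc$a1) < 2) return(NA_real_)
  m <- make_dosage(tc$a1, tc$a2)
  fis_from_mats(m$dos, m$het)
}

#' Weir-Cockerham F_ST between females and males
#'
#' Treats the two sexes as subpopulations and computes the Weir & Cockerham
#' (1984) theta for that two-group partition, summing the a, b, c variance
#' components over alleles before taking the ratio. Elevated values flag
#' sex-linked loci.
#'
#' @inheritParams het_stats
#' @return Numeric theta, or `NA` if the locus is monomorphic overall.
#' @export
fst_wc_sex <- function(table, locus) {
  rows <- group_rows(table, "FM")
  tc <- typed_calls(table, locus, rows)
  sex <- table$ind$sex[tc$rows]
  if (sum(sex == "F") == 0 || sum(sex == "M") == 0) {
    stop("both sexes must be typed at ", locus)
  }
  if (length(unique(c(tc$a1, tc$a2))) < 2) return(NA_real_)
  m <- make_dosage(tc$a1, tc$a2)
  theta_from_mats(m$dos, m$het, sex == "M")
}

#' Permutation p-value for a per-locus statistic
#'
#' Two permutation schemes match the two null hypotheses of a sex-linkage
#' scan: `"ALLELES_WITHIN_GROUP"` shuffles the 2n allele copies among the
#' group's individuals (random mating within the group; the F_IS null) and
#' `"SEX_LABELS"` shuffles sex assignments among typed individuals (no
#' sex-genotype association; the F_ST null). The p-value uses the add-one
#' convention `(k + 1) / (n_perm + 1)`; ties with the observed value count
#' as extreme.
#'
#' @inheritParams het_stats
#' @param stat `"fst"`, `"fis"`, or a function `f(a1, a2, sex)` of the typed
#'   allele vectors and sex labels returning a scalar.
#' @param scheme permutation scheme (see above); defaults to the natural
#'   null for the named statistic.
#' @param group group for `"fis"` / `"ALLELES_WITHIN_GROUP"`.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer RNG seed; the result is fully reproducible.
#' @param sidedness `"GREATER"` (one-sided, the F_ST default) or
#'   `"TWO_SIDED"` (on `|stat|`, the F_IS default).
#' @return list with `observed`, `n_perm`, `n_as_extreme`, `p`, `seed`.
#' @export
permute_p <- function(table, locus, stat = c("fst", "fis"),
                      scheme = NULL, group = "ALL",
                      n_perm = 10000, seed = 1, sidedness = NULL) {
  stopifnot(n_perm >= 1)
  custom <- is.function(stat)
  if (!custom) stat <- match.arg(stat)
  if (is.null(scheme)) {
    scheme <- if (!custom && stat == "fis") "ALLELES_WITHIN_GROUP"
              else "SEX_LABELS"
  }
  scheme <- match.arg(scheme, c("ALLELES_WITHIN_GROUP", "SEX_LABELS"))
  if (is.null(sidedness)) {
    sidedness <- if (!custom && stat == "fis") "TWO_SIDED" else "GREATER"
  }
  sidedness <- match.arg(sidedness, c("GREATER", "TWO_SIDED"))

  rows <- if (scheme == "SEX_LABELS") group_rows(table, "FM")
          else group_rows(table, group)
  tc <- typed_calls(table, locus, rows)
  sex <- table$ind$sex[tc$rows]
  n <- length(tc$a1)
  if (n < 2) stop("degenerate: fewer than 2 typed individuals at ", locus)

  m <- make_dosage(tc$a1, tc$a2)
  stat_value <- function(a1, a2, sexv) {
    if (custom) return(stat(a1, a2, sexv))
    mm <- make_dosage(a1, a2)
    if (stat == "fis") fis_from_mats(mm$dos, mm$het)
    else theta_from_mats(mm$dos, mm$het, sexv == "M")
  }
  observed <- if (!custom && stat == "fis") fis_from_mats(m$dos, m$het)
    else if (!custom) theta_from_mats(m$dos, m$het, sex == "M")
    else stat(tc$a1, tc$a2, sex)
  if (is.na(observed)) {
    stop("statistic undefined on observed data at ", locus)
  }
  crit <- if (sidedness == "GREATER") observed else abs(observed)
  eps <- 1e-12

  n_extreme <- with_seed(seed, {
    k <- 0L
    is_m <- sex == "M"
    for (b in seq_len(n_perm)) {
      if (scheme == "SEX_LABELS") {
        perm_m <- sample(is_m)
        s <- if (custom) {
          sexv <- ifelse(perm_m, "M", "F")
          stat(tc$a1, tc$a2, sexv)
        } else if (stat == "fst") {
          theta_from_mats(m$dos, m$het, perm_m)
        } else {
          fis_from_mats(m$dos[perm_m, , drop = FALSE],
                        m$het[perm_m, , drop = FALSE])
        }
      } else {
        pool <- sample(c(tc$a1, tc$a2))
        p1 <- pool[seq(1, 2 * n - 1, by = 2)]
        p2 <- pool[seq(2, 2 * n, by = 2)]
        s <- stat_value(p1, p2, sex)
      }
      if (!is.na(s)) {
        sv <- if (sidedness == "GREATER") s else abs(s)
        if (sv >= crit - eps) k <- k + 1L
      }
    }
    k
  })
  p <- (n_extreme + 1) / (n_perm + 1)
  list(observed = observed, n_perm = as.integer(n_perm),
       n_as_extreme = as.integer(n_extreme), p = p, seed = as.integer(seed))
}

# G log-likelihood-ratio statistic of a contingency table of counts
g_statistic <- function(tab) {
  tab <- as.matrix(tab)
  N <- sum(tab)
  if (N == 0) return(0)
  e <- outer(rowSums(tab), colSums(tab)) / N
  nz <- tab > 0
  2 * sum(tab[nz] * log(tab[nz] / e[nz]))
}

#' Genotypic linkage disequilibrium test for a locus pair
#'
#' G log-likelihood-ratio statistic on the genotype-by-genotype contingency
#' table of co-typed individuals, with a permutation null obtained by
#' shuffling the second locus's genotypes among individuals. With several
#' population blocks the statistic is summed across populations and
#' permutation is within population. Loci on a shared non-recombining
#' haplotype (e.g. Y-linked loci) show strong LD under this test.
#'
#' @inheritParams het_stats
#' @param locus_a,locus_b locus names.
#' @param n_perm,seed permutation settings.
#' @return list with `locus_a`, `locus_b`, `g_statistic` (`NA` if either
#'   locus has < 2 alleles among co-typed individuals; then `p = 1`),
#'   `p`, `n_perm`, `seed`.
#' @export
ld_test <- function(table, locus_a, locus_b, n_perm = 1000, seed = 1) {
  ja <- locus_index(table, locus_a); jb <- locus_index(table, locus_b)
  co <- !is.na(table$a1[, ja]) & !is.na(table$a1[, jb])
  if (sum(co) < 2) stop("fewer than 2 co-typed individuals")
  ga <- paste(table$a1[co, ja], table$a2[co, ja], sep = "/")
  gb <- paste(table$a1[co, jb], table$a2[co, jb], sep = "/")
  pop <- table$ind$pop[co]
  mono_a <- length(unique(c(table$a1[co, ja], table$a2[co, ja]))) < 2
  mono_b <- length(unique(c(table$a1[co, jb], table$a2[co, jb]))) < 2
  if (mono_a || mono_b) {
    return(list(locus_a = locus_a, locus_b = locus_b,
                g_statistic = NA_real_, p = 1,
                n_perm = as.integer(n_perm), seed = as.integer(seed)))
  }
  g_total <- function(gb_v) {
    s <- 0
    for (p in unique(pop)) {
      i <- pop == p
      s <- s + g_statistic(table(ga[i], gb_v[i]))
    }
    s
  }
  obs <- g_total(gb)
  k <- with_seed(seed, {
    k <- 0L
    for (b in seq_len(n_perm)) {
      gperm <- gb
      for (p in unique(pop)) {
        i <- which(pop == p)
        gperm[i] <- gb[sample(i)]
      }
      if (g_total(gperm) >= obs - 1e-12) k <- k + 1L
    }
    k
  })
  list(locus_a = locus_a, locus_b = locus_b, g_statistic = obs,
       p = (k + 1) / (n_perm + 1),
       n_perm = as.integer(n_perm), seed = as.integer(seed))
}

#' Allele-dosage trend test for sex association
#'
#' For every allele at the locus, individuals are scored by their dosage of
#' that allele (0, 1 or 2 copies) and a Cochran-Armitage trend test with
#' scores 0, 1, 2 is run against sex as the binary outcome
#' (via [stats::prop.trend.test()]; 1-df chi-square reference). The locus
#' p-value is the smallest Holm-adjusted per-allele p-value.
#'
#' @inheritParams het_stats
#' @return list with `locus`, `per_allele` (data.frame: `allele`,
#'   `statistic`, `p`, `p_holm`) and `locus_p`.
#' @export
trend_test <- function(table, locus) {
  rows <- group_rows(table, "FM")
  tc <- typed_calls(table, locus, rows)
  sex <- table$ind$sex[tc$rows]
  if (sum(sex == "F") == 0 || sum(sex == "M") == 0) {
    stop("trend test requires typed individuals of both sexes at ", locus)
  }
  m <- make_dosage(tc$a1, tc$a2)
  out <- lapply(seq_along(m$alleles), function(k) {
    d <- m$dos[, k]
    stat <- 0; p <- 1
    groups <- sort(unique(d))
    if (length(groups) > 1) {
      x <- vapply(groups, function(g) sum(sex == "M" & d == g), numeric(1))
      n <- vapply(groups, function(g) sum(d == g), numeric(1))
      tt <- suppressWarnings(
        stats::prop.trend.test(x, n, score = groups))
      stat <- unname(tt$statistic)
      p <- tt$p.value
      if (!is.finite(stat)) { stat <- 0; p <- 1 }
    }
    c(allele = m$alleles[k], statistic = stat, p = p)
  })
  pa <- as.data.frame(do.call(rbind, out))
  pa$p_holm <- stats::p.adjust(pa$p, method = "holm")
  list(locus = locus, per_allele = pa, locus_p = min(pa$p_holm))
}

#' Null-allele diagnostics from homozygote excess
#'
#' A non-amplifying (null) allele inflates apparent homozygosity. This
#' reports two point estimators of the null-allele frequency based on the
#' gap between expected and observed heterozygosity -- Chakraborty's
#' `(H_E - H_O) / (H_E + H_O)` and Brookfield's estimator 1
#' `(H_E - H_O) / (1 + H_E)` -- plus a randomization p-value for homozygote
#' excess obtained by reassorting the group's allele copies into genotypes
#' (Hardy-Weinberg resampling) and counting homozygotes. A null is
#' suspected when the excess is significant and Chakraborty's estimate is
#' positive; a Y-specific null drives male estimates toward 1 while female
#' estimates stay near 0.
#'
#' @inheritParams het_stats
#' @param alpha significance level for the excess test.
#' @param n_perm,seed randomization settings.
#' @return list with `locus`, `group`, `n_typed`, `H_O`, `H_E`,
#'   `r_chakraborty`, `r_brookfield1`, `homozygote_excess_p`,
#'   `null_suspected`.
#' @export
null_allele_scan <- function(table, locus, group, alpha = 0.05,
                             n_perm = 1000, seed = 1) {
  tc <- typed_calls(table, locus, group_rows(table, group))
  n <- length(tc$a1)
  if (n < 5) stop("null-allele scan needs >= 5 typed individuals in group")
  hs <- het_stats(table, locus, group)
  H_O <- hs$H_O; H_E <- hs$H_E
  if (H_E <= 0) {
    return(list(locus = locus, group = group, n_typed = n, H_O = H_O,
                H_E = H_E, r_chakraborty = NA_real_,
                r_brookfield1 = NA_real_, homozygote_excess_p = 1,
                null_suspected = FALSE))
  }
  r_c <- (H_E - H_O) / (H_E + H_O)
  r_b <- (H_E - H_O) / (1 + H_E)
  hom_obs <- sum(tc$a1 == tc$a2)
  pool <- c(tc$a1, tc$a2)
  k <- with_seed(seed, {
    k <- 0L
    for (b in seq_len(n_perm)) {
      s <- sample(pool)
      hom <- sum(s[seq(1, 2 * n - 1, 2)] == s[seq(2, 2 * n, 2)])
      if (hom >= hom_obs) k <- k + 1L
    }
    k
  })
  p <- (k + 1) / (n_perm + 1)
  list(locus = locus, group = group, n_typed = n, H_O = H_O, H_E = H_E,
       r_chakraborty = r_c, r_brookfield1 = r_b,
       homozygote_excess_p = p,
       null_suspected = isTRUE(p < alpha && r_c > 0))
}

#' Holm step-down ("sequential Bonferroni") correction
#'
#' Wraps [stats::p.adjust()] with `method = "holm"` and returns the full
#' decision: raw and adjusted p-values in input order and rejection flags
#' at `alpha`. Controls the family-wise error rate; rejections are always
#' a subset of uncorrected rejections.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @param alpha family-wise significance level.
#' @return list with `raw_p`, `adjusted_p`, `rejected`, `alpha`.
#' @export
holm_correct <- function(pvals, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  if (length(pvals) == 0) {
    return(list(raw_p = numeric(0), adjusted_p = numeric(0),
                rejected = logical(0), alpha = alpha))
  }
  if (any(!is.na(pvals) & (pvals <= 0 | pvals > 1))) {
    stop("p-values must lie in (0, 1]")
  }
  adj <- stats::p.adjust(pvals, method = "holm")
  list(raw_p = pvals, adjusted_p = adj,
       rejected = !is.na(adj) & adj <= alpha, alpha = alpha)
}
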