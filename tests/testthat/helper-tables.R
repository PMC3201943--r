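# build a genotype_table from a compact spec: list of "a/b" or NA strings
# per individual, one locus; or a matrix-like list for several loci
make_table <- function(calls, sex = NULL, loci = "L1", pop = "pop1") {
  if (!is.list(calls)) calls <- list(calls)
  n <- length(calls[[1]])
  parse_call <- function(x) {
    if (is.na(x)) return(c(NA_integer_, NA_integer_))
    as.integer(strsplit(x, "/")[[1]])
  }
  a1 <- a2 <- matrix(NA_integer_, n, length(calls))
  for (j in seq_along(calls)) {
    m <- vapply(calls[[j]], parse_call, integer(2))
    a1[, j] <- m[1, ]; a2[, j] <- m[2, ]
  }
  if (is.null(sex)) sex <- NA_character_
  genotype_table(ids = sprintf("i%02d", seq_len(n)), loci = loci,
                 a1 = a1, a2 = a2, sex = sex, pop = pop)
}

# n_hom homozygotes a/a, n_het heterozygotes a/b, as call strings
calls_hom_het <- function(n_hom, n_het, a = 150, b = 152) {
  c(rep(paste0(a, "/", a), n_hom), rep(paste0(a, "/", b), n_het))
}
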