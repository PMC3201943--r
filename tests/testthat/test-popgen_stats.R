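test_that("heterozygosity statistics match the unbiased formulas", {
  # monomorphic: A = 1, both heterozygosities 0
  mono <- make_table(rep("150/150", 6))
  h <- het_stats(mono, "L1")
  expect_equal(c(h$A, h$H_O, h$H_E), c(1, 0, 0))
  # two individuals both 150/152: H_E = (4/3) * (1 - 0.5) = 2/3
  h2 <- het_stats(make_table(rep("150/152", 2)), "L1")
  expect_equal(h2$H_O, 1)
  expect_equal(h2$H_E, 2 / 3)
  # 5x 150/150 + 5x 152/152: H_E = (20/19) * 0.5
  h3 <- het_stats(make_table(c(rep("150/150", 5), rep("152/152", 5))), "L1")
  expect_equal(h3$H_O, 0)
  expect_equal(h3$H_E, 10 / 19)
  expect_error(het_stats(make_table(c("150/150", NA), sex = c("F", "M")),
                         "L1", "M"), "no typed")
})

test_that("unbiased H_E approaches 1 - sum(p^2) for large samples", {
  set.seed(42)
  n <- 1e4
  a1 <- sample(c(150L, 152L, 154L), n, TRUE, prob = c(0.5, 0.3, 0.2))
  a2 <- sample(c(150L, 152L, 154L), n, TRUE, prob = c(0.5, 0.3, 0.2))
  gt <- genotype_table(sprintf("i%05d", 1:n), "L1", matrix(a1), matrix(a2))
  h <- het_stats(gt, "L1")
  p <- as.numeric(table(c(a1, a2))) / (2 * n)
  expect_lt(abs(h$H_E - (1 - sum(p^2))), 1e-3)
})

test_that("F_IS hits its boundary values and is undefined when monomorphic", {
  # complete heterozygote excess
  expect_equal(fis_wc(make_table(rep("150/152", 10)), "L1"), -1)
  # complete homozygosity at p = 0.5
  expect_equal(fis_wc(make_table(c(rep("150/150", 5), rep("152/152", 5))),
                      "L1"), 1)
  # monomorphic: undefined, never 0
  expect_true(is.na(fis_wc(make_table(rep("150/150", 10)), "L1")))
  # Hardy-Weinberg proportions at p = 0.5, large n: f ~ 0
  hw <- make_table(c(rep("150/150", 25), rep("150/152", 50),
                     rep("152/152", 25)))
  expect_lt(abs(fis_wc(hw, "L1")), 0.02)
})

test_that("between-sex F_ST behaves at the fixed and identical extremes", {
  fixed <- make_table(c(rep("150/150", 24), rep("152/152", 24)),
                      sex = rep(c("F", "M"), each = 24))
  expect_equal(fst_wc_sex(fixed, "L1"), 1)
  same <- make_table(rep(c("150/150", "150/152", "152/152"), times = 16),
                     sex = rep(c("F", "M"), each = 24))
  expect_lt(abs(fst_wc_sex(same, "L1")), 0.05)
  expect_true(is.na(fst_wc_sex(
    make_table(rep("150/150", 8), sex = rep(c("F", "M"), 4)), "L1")))
  expect_error(fst_wc_sex(make_table(rep("150/152", 4),
                                     sex = rep("F", 4)), "L1"),
               "both sexes")
})

test_that("implementation matches brute-force WC84 oracle on small tables", {
  n_match_f <- 0L; n_match_t <- 0L
  for (s in 1:150) {
    gt <- random_small_table(s)
    a1 <- gt$a1[, 1]; a2 <- gt$a2[, 1]
    of <- oracle_fis(a1, a2)
    f <- fis_wc(gt, "L1")
    expect_equal(f, of, tolerance = 1e-12)
    if (!is.na(of)) n_match_f <- n_match_f + 1L
    ot <- oracle_theta(a1, a2, gt$ind$sex)
    th <- fst_wc_sex(gt, "L1")
    if (is.na(ot)) {
      expect_true(is.na(th))
    } else {
      expect_lt(abs(th - ot), 1e-10)
      n_match_t <- n_match_t + 1L
    }
  }
  # the suite must actually exercise defined statistics
  expect_gt(n_match_f, 100)
  expect_gt(n_match_t, 100)
})

test_that("permutation p-values follow the add-one convention", {
  # statistic invariant under label shuffling -> p = 1
  const_stat <- function(a1, a2, sex) 1
  gt <- make_table(calls_hom_het(10, 10), sex = rep(c("F", "M"), 10))
  r <- permute_p(gt, "L1", const_stat, scheme = "SEX_LABELS",
                 n_perm = 99, seed = 4)
  expect_equal(r$p, 1)
  # observed strictly more extreme than every replicate -> 1/(n+1)
  fixed <- make_table(c(rep("150/150", 12), rep("152/152", 12)),
                      sex = rep(c("F", "M"), each = 12))
  r2 <- permute_p(fixed, "L1", "fst", n_perm = 999, seed = 7)
  expect_equal(r2$p, 1 / 1000)
  expect_equal(r2$observed, 1)
  # same seed -> identical result object
  r3 <- permute_p(fixed, "L1", "fst", n_perm = 999, seed = 7)
  expect_identical(r2, r3)
  expect_error(permute_p(make_table(rep("150/150", 10),
                                    sex = rep(c("F", "M"), 5)),
                         "L1", "fst", n_perm = 9, seed = 1),
               "undefined")
})

test_that("male heterozygote excess is flagged by the F_IS permutation test", {
  gt <- make_table(rep("150/152", 24), sex = rep("M", 24))
  r <- permute_p(gt, "L1", "fis", group = "M", n_perm = 999, seed = 11)
  expect_equal(r$observed, -1)
  expect_lt(r$p, 0.01)
})

test_that("trend test matches the closed-form Cochran-Armitage statistic", {
  # F dosages (8, 2, 0), M dosages (2, 6, 2) of allele 150 across 10 + 10
  calls <- c(rep("152/152", 8), rep("150/152", 2),           # females
             rep("152/152", 2), rep("150/152", 6), rep("150/150", 2))
  gt <- make_table(calls, sex = rep(c("F", "M"), each = 10))
  tt <- trend_test(gt, "L1")
  # hand evaluation: T = 4, pbar = 1/2, var term = 2.2, chi2 = 16 / 2.2
  chi_hand <- 16 / 2.2
  row150 <- tt$per_allele[tt$per_allele$allele == 150, ]
  expect_equal(row150$statistic, chi_hand, tolerance = 1e-10)
  expect_equal(row150$p, stats::pchisq(chi_hand, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  # allele at dosage 1 in every male, 0 in every female: chi2 = N = 48
  sep <- make_table(c(rep("150/150", 24), rep("150/177", 24)),
                    sex = rep(c("F", "M"), each = 24))
  tt2 <- trend_test(sep, "L1")
  row177 <- tt2$per_allele[tt2$per_allele$allele == 177, ]
  expect_equal(row177$statistic, 48, tolerance = 1e-10)
  expect_lt(row177$p, 1e-6)
  # identical dosage distributions in both sexes: statistic 0, p 1
  bal <- make_table(rep(c("150/150", "150/152", "152/152"), 4),
                    sex = rep(c("F", "M"), 6))
  tt3 <- trend_test(bal, "L1")
  expect_equal(tt3$per_allele$statistic, c(0, 0))
  expect_equal(tt3$locus_p, 1)
})

test_that("null-allele diagnostics track homozygote excess", {
  # all homozygous, 2 alleles: Chakraborty r = 1, excess significant
  hom <- make_table(c(rep("150/150", 12), rep("152/152", 12)),
                    sex = rep("M", 24))
  r <- null_allele_scan(hom, "L1", "M", n_perm = 999, seed = 3)
  expect_equal(r$r_chakraborty, 1)
  expect_true(r$null_suspected)
  # estimators equal their defining formulas on any table
  mix <- make_table(calls_hom_het(6, 4), sex = rep("F", 10))
  h <- het_stats(mix, "L1", "F")
  r2 <- null_allele_scan(mix, "L1", "F", n_perm = 499, seed = 5)
  expect_equal(r2$r_chakraborty, (h$H_E - h$H_O) / (h$H_E + h$H_O))
  expect_equal(r2$r_brookfield1, (h$H_E - h$H_O) / (1 + h$H_E))
  # H_O above H_E: no excess, never suspected
  het <- make_table(rep("150/152", 12), sex = rep("M", 12))
  r3 <- null_allele_scan(het, "L1", "M", n_perm = 499, seed = 6)
  expect_lt(r3$r_chakraborty, 0)
  expect_false(r3$null_suspected)
  # monomorphic: estimators undefined
  r4 <- null_allele_scan(make_table(rep("150/150", 8), sex = rep("M", 8)),
                         "L1", "M", n_perm = 99, seed = 1)
  expect_true(is.na(r4$r_chakraborty))
  expect_false(r4$null_suspected)
})

test_that("Holm step-down matches hand computation and its invariants", {
  d <- holm_correct(c(0.01, 0.02, 0.03), alpha = 0.05)
  expect_equal(d$adjusted_p, c(0.03, 0.04, 0.04))
  expect_equal(d$rejected, c(TRUE, TRUE, TRUE))
  expect_equal(holm_correct(0.04)$adjusted_p, 0.04)
  all1 <- holm_correct(rep(1, 5))
  expect_true(all(all1$adjusted_p == 1) && !any(all1$rejected))
  expect_length(holm_correct(numeric(0))$adjusted_p, 0)
  # adjusted >= raw; rejections subset of uncorrected; order-invariant
  set.seed(9)
  p <- runif(20)^2
  d2 <- holm_correct(p, alpha = 0.05)
  expect_true(all(d2$adjusted_p >= d2$raw_p))
  expect_true(all(which(d2$rejected) %in% which(p <= 0.05)))
  perm <- sample(20)
  d3 <- holm_correct(p[perm], alpha = 0.05)
  expect_equal(d3$adjusted_p, d2$adjusted_p[perm])
  expect_error(holm_correct(c(0.5, 1.2)), "0, 1")
})
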