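test_that("male-specific alleles are exactly those absent from females", {
  # all males het for allele 179, no female carries it
  gt <- make_table(c(rep("175/175", 24), rep("175/179", 24)),
                   sex = rep(c("F", "M"), each = 24))
  r <- find_male_specific_alleles(gt, "L1")
  expect_equal(r$alleles$allele, 179)
  expect_equal(r$alleles$male_carrier_fraction, 1.0)
  # one female carrier disqualifies the allele
  gt2 <- make_table(c(rep("175/175", 23), "175/179", rep("175/179", 24)),
                    sex = rep(c("F", "M"), each = 24))
  expect_equal(nrow(find_male_specific_alleles(gt2, "L1")$alleles), 0)
  # identical allele sets: empty report
  gt3 <- make_table(rep("150/152", 8), sex = rep(c("F", "M"), 4))
  expect_equal(nrow(find_male_specific_alleles(gt3, "L1")$alleles), 0)
  expect_error(find_male_specific_alleles(
    make_table(rep("150/152", 4), sex = rep("F", 4)), "L1"), "male")
})

test_that("random sex labels almost never produce a male-specific allele", {
  set.seed(77)
  base <- make_table(
    paste(sample(c(150, 152, 154, 156), 48, TRUE),
          sample(c(150, 152, 154, 156), 48, TRUE), sep = "/"))
  hits <- 0L
  for (b in 1:200) {
    gt <- base
    gt$ind$sex <- sample(rep(c("F", "M"), each = 24))
    msa <- find_male_specific_alleles(gt, "L1")
    if (nrow(msa$alleles) > 0 &&
        any(msa$alleles$male_carrier_fraction == 1)) hits <- hits + 1L
  }
  expect_lt(hits / 200, 0.01)
})

test_that("locus classification applies the decision rules in order", {
  # X-monomorphic females, all males het X/Y, F_ST significant
  xy <- make_table(c(rep("175/175", 24), rep("175/179", 24)),
                   sex = rep(c("F", "M"), each = 24))
  cl <- classify_locus(xy, "L1", fst_significant = TRUE, seed = 2)
  expect_equal(cl$call, "XY_DIFFERENTIATED")
  expect_true(cl$evidence$has_male_specific_allele)
  expect_lt(cl$evidence$male_fis, 0)
  # polymorphic, zero het males, male-only null signal
  fcalls <- rep(c("150/152", "150/154", "152/154", "150/150"), 6)
  mcalls <- rep(c("150/150", "152/152", "154/154"), 8)
  ynull <- make_table(c(fcalls, mcalls), sex = rep(c("F", "M"), each = 24))
  cl2 <- classify_locus(ynull, "L1", fst_significant = FALSE,
                        n_perm = 999, seed = 3)
  expect_equal(cl2$call, "Y_NULL")
  expect_true(cl2$evidence$zero_het_males)
  expect_true(cl2$evidence$male_only_null_signal)
  expect_gt(cl2$evidence$male_fis, 0)
  # monomorphic locus
  mono <- make_table(rep("150/150", 20), sex = rep(c("F", "M"), 10))
  expect_equal(classify_locus(mono, "L1", FALSE)$call, "UNINFORMATIVE")
  # autosomal-looking locus
  auto <- make_table(rep(c("150/152", "150/150", "152/152"), 8),
                     sex = rep(c("F", "M"), 12))
  expect_equal(classify_locus(auto, "L1", FALSE, seed = 4)$call,
               "UNDIFFERENTIATED")
})

test_that("carrier-fraction threshold tau_m gates the XY call", {
  # male-specific allele carried by 18 of 24 males (75%)
  gt <- make_table(c(rep("175/175", 24), rep("175/179", 18),
                     rep("175/175", 6)),
                   sex = rep(c("F", "M"), each = 24))
  strict <- classify_locus(gt, "L1", fst_significant = TRUE, seed = 5)
  expect_false(strict$call == "XY_DIFFERENTIATED")
  relaxed <- classify_locus(gt, "L1", fst_significant = TRUE,
                            tau_m = 0.5, seed = 5)
  expect_equal(relaxed$call, "XY_DIFFERENTIATED")
})

test_that("heavy male missingness suspends the Y-null rule", {
  fcalls <- rep(c("150/152", "150/154", "152/154"), 8)
  mcalls <- c(rep("150/150", 8), rep("152/152", 6), rep(NA, 10))
  gt <- make_table(c(fcalls, mcalls), sex = rep(c("F", "M"), each = 24))
  cl <- classify_locus(gt, "L1", fst_significant = FALSE,
                       n_perm = 499, seed = 6)
  expect_true(cl$evidence$high_missing_males)
  expect_false(cl$call == "Y_NULL")
})

test_that("region summary reproduces span arithmetic and its invariants", {
  calls <- rep(c("XY_DIFFERENTIATED", "Y_NULL",
                 "XY_DIFFERENTIATED", "Y_NULL"), each = 2)
  pos <- c(3.2, 4.0, 5.1, 7.4, 9.4, 11.8, 14.7, 19.6) * 1e6
  r <- summarize_regions(calls, pos)
  expect_equal(r$span_mb, 16.4)
  expect_equal(nrow(r$intervals), 4)
  expect_equal(r$intervals$lo_mb, c(3.2, 5.1, 9.4, 14.7))
  expect_equal(r$intervals$hi_mb, c(4.0, 7.4, 11.8, 19.6))
  # order invariance and duplicate positions
  sh <- sample(length(calls))
  r2 <- summarize_regions(calls[sh], pos[sh])
  expect_equal(r2$span_mb, r$span_mb)
  r3 <- summarize_regions(c(calls, calls[1]), c(pos, pos[1]))
  expect_equal(r3$span_mb, r$span_mb)
  expect_equal(r3$intervals, r$intervals)
  # single locus: zero span; none: empty intervals
  expect_equal(summarize_regions("Y_NULL", 5e6)$span_mb, 0)
  none <- summarize_regions(c("UNDIFFERENTIATED", "UNINFORMATIVE"),
                            c(1e6, 2e6))
  expect_equal(none$span_mb, 0)
  expect_equal(nrow(none$intervals), 0)
  # intervening undifferentiated locus splits; uninformative does not
  r4 <- summarize_regions(c("Y_NULL", "UNDIFFERENTIATED", "Y_NULL"),
                          c(1e6, 2e6, 3e6))
  expect_equal(nrow(r4$intervals), 2)
  r5 <- summarize_regions(c("Y_NULL", "UNINFORMATIVE", "Y_NULL"),
                          c(1e6, 2e6, 3e6))
  expect_equal(nrow(r5$intervals), 1)
  # fraction needs a chromosome length
  r6 <- summarize_regions(c("Y_NULL", "Y_NULL"), c(1e6, 3e6), 10)
  expect_equal(r6$span_mb, 2)
  expect_equal(r6$fraction, 0.2)
})
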