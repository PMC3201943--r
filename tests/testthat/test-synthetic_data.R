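pool4 <- stats::setNames(rep(0.25, 4), c(150, 152, 154, 156))

test_that("locus specifications validate their generative parameters", {
  expect_error(locus_spec("a", 1, "XY_DIFF", pool4), "y_allele")
  expect_error(locus_spec("a", 1, "XY_DIFF", pool4, y_allele = 150),
               "collides")
  expect_error(locus_spec("a", 1, "AUTOSOMAL",
                          stats::setNames(c(0.5, 0.4), c(150, 152))),
               "sum to 1")
  ok <- locus_spec("a", 1, "XY_DIFF", pool4, y_allele = 171)
  expect_s3_class(ok, "locus_spec")
})

test_that("simulation is deterministic and mode signatures hold exactly", {
  loci <- list(
    locus_spec("auto", 1e6, "AUTOSOMAL", pool4),
    locus_spec("xy", 2e6, "XY_DIFF", pool4, y_allele = 171),
    locus_spec("ynull", 3e6, "Y_NULL", pool4))
  cfg <- sim_config(20, 20, loci, missing_rate = 0, seed = 99)
  sim <- simulate_genotypes(cfg)
  sim2 <- simulate_genotypes(cfg)
  expect_identical(sim$table$a1, sim2$table$a1)
  expect_identical(sim$table$a2, sim2$table$a2)
  males <- sim$table$ind$sex == "M"
  # XY_DIFF, mutation 0: every male heterozygous and carrying the Y allele
  expect_true(all(sim$table$a2[males, "xy"] == 171 |
                  sim$table$a1[males, "xy"] == 171))
  expect_true(all(sim$table$a1[males, "xy"] != sim$table$a2[males, "xy"]))
  expect_equal(het_stats(sim$table, "xy", "M")$H_O, 1)
  # Y_NULL: males scored homozygous (H_O = 0) but allele pool polymorphic
  expect_true(all(sim$table$a1[males, "ynull"] ==
                  sim$table$a2[males, "ynull"]))
  expect_equal(het_stats(sim$table, "ynull", "M")$H_O, 0)
  expect_gt(het_stats(sim$table, "ynull", "M")$H_E, 0)
  # females never see the Y allele
  expect_false(any(sim$table$a1[!males, "xy"] == 171 |
                   sim$table$a2[!males, "xy"] == 171))
  # truth table consistent
  expect_equal(sim$truth$loci$mode, c("AUTOSOMAL", "XY_DIFF", "Y_NULL"))
})

test_that("sample allele frequencies recover the generating pool", {
  loci <- list(locus_spec("a", 1e6, "AUTOSOMAL", pool4))
  sim <- simulate_genotypes(sim_config(10000, 10000, loci, seed = 13))
  alle <- c(sim$table$a1[, 1], sim$table$a2[, 1])
  freq <- as.numeric(table(alle)) / length(alle)
  expect_true(all(abs(freq - 0.25) < 0.02))
})

test_that("Y-null loci are invisible in a near-monomorphic population", {
  lowpool <- stats::setNames(c(0.998, 0.002), c(150, 152))
  sim <- simulate_genotypes(sim_config(
    24, 24, list(locus_spec("yn", 1e6, "Y_NULL", lowpool)), seed = 21))
  # usually monomorphic -> uninformative: the reason Y-null detection
  # requires a polymorphic X pool
  A <- het_stats(sim$table, "yn", "ALL")$A
  cl <- classify_locus(sim$table, "yn",
                       fst_significant = FALSE, seed = 3)
  if (A == 1) expect_equal(cl$call, "UNINFORMATIVE")
  else expect_true(cl$call %in% c("UNDIFFERENTIATED", "Y_NULL"))
})

test_that("presets encode the two study designs", {
  py <- preset_config("PYOREALAMPI_LIKE", seed = 3)
  expect_equal(c(py$n_females, py$n_males), c(24L, 24L))
  expect_length(py$loci, 14)
  expect_equal(sum(vapply(py$loci, `[[`, character(1), "mode")
                   == "XY_DIFF"), 13L)
  ts <- preset_config("THREESPINE_LIKE", seed = 3)
  expect_equal(c(ts$n_females, ts$n_males), c(25L, 23L))
  modes <- vapply(ts$loci, `[[`, character(1), "mode")
  expect_equal(sum(modes == "Y_NULL"), 7L)
  expect_equal(sum(modes == "XY_DIFF"), 5L)
  # same preset + seed -> identical tables
  t1 <- simulate_genotypes(preset_config("BALTIC_LIKE", seed = 8))
  t2 <- simulate_genotypes(preset_config("BALTIC_LIKE", seed = 8))
  expect_identical(t1$table$a1, t2$table$a1)
})

test_that("diversity presets reproduce the intended H_E contrast", {
  py <- simulate_genotypes(preset_config("PYOREALAMPI_LIKE", seed = 4,
                                         missing_rate = 0))
  he_f <- vapply(py$table$loci$name, function(l) {
    het_stats(py$table, l, "F")$H_E
  }, numeric(1))
  expect_lt(mean(he_f), 0.05)  # near-monomorphic X pool
  ba <- simulate_genotypes(preset_config("BALTIC_LIKE", seed = 4,
                                         missing_rate = 0))
  he_fb <- vapply(ba$table$loci$name, function(l) {
    het_stats(ba$table, l, "F")$H_E
  }, numeric(1))
  expect_gt(mean(he_fb), 0.4)  # multi-allelic X pool
})

test_that("stepwise mutation perturbs transmitted alleles at the set rate", {
  loci <- list(locus_spec("m", 1e6, "AUTOSOMAL",
                          stats::setNames(1, 150), mutation_rate = 0.5))
  sim <- simulate_genotypes(sim_config(500, 500, loci, seed = 17))
  alle <- c(sim$table$a1[, 1], sim$table$a2[, 1])
  expect_true(all(alle %in% c(148, 150, 152)))
  expect_lt(abs(mean(alle != 150) - 0.5), 0.05)
})
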