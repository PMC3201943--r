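#' Specify one simulated locus
#'
#' Defines the generative model for a single microsatellite under male
#' heterogamety. Three modes cover the observable outcomes of
#' recombination suppression:
#' \itemize{
#'   \item `AUTOSOMAL` -- both sexes draw two alleles from the same pool.
#'   \item `XY_DIFF` -- a fixed Y allele, absent from the X pool, carried by
#'     every male alongside one X allele (every male heterozygous).
#'   \item `Y_NULL` -- the Y copy does not amplify, so males are scored as
#'     homozygous for their single X allele (apparent homozygote excess).
#' }
#'
#' @param name locus name.
#' @param position_bp 1-based physical position.
#' @param mode `"AUTOSOMAL"`, `"XY_DIFF"` or `"Y_NULL"`.
#' @param x_allele_freqs named numeric vector: names are allele sizes (bp),
#'   values frequencies summing to 1.
#' @param y_allele Y-linked allele size; required for `XY_DIFF` and must not
#'   occur in the X pool.
#' @param motif_step mutation step size in bp (repeat-unit length).
#' @param mutation_rate per-transmission probability of a single-step
#'   mutation (stepwise model, direction equiprobable).
#' @return list of class `locus_spec`.
#' @export
locus_spec <- function(name, position_bp, mode, x_allele_freqs,
                       y_allele = NA_integer_, motif_step = 2,
                       mutation_rate = 0) {
  mode <- match.arg(mode, c("AUTOSOMAL", "XY_DIFF", "Y_NULL"))
  f <- as.numeric(x_allele_freqs)
  al <- as.integer(names(x_allele_freqs))
  if (any(is.na(al))) stop("x_allele_freqs must be named by allele size")
  if (abs(sum(f) - 1) > 1e-9) stop("x_allele_freqs must sum to 1")
  if (any(f < 0)) stop("negative allele frequency")
  if (mode == "XY_DIFF") {
    if (is.na(y_allele)) stop("XY_DIFF requires y_allele")
    if (as.integer(y_allele) %in% al[f > 0]) {
      stop("y_allele ", y_allele, " collides with the X allele pool")
    }
  }
  structure(list(name = as.character(name),
                 position_bp = as.integer(position_bp),
                 mode = mode,
                 x_allele_freqs = stats::setNames(f, al),
                 y_allele = as.integer(y_allele),
                 motif_step = as.integer(motif_step),
                 mutation_rate = mutation_rate),
            class = "locus_spec")
}

#' Assemble a simulation configuration
#'
#' @param n_females,n_males sample sizes.
#' @param loci list of [locus_spec()] objects.
#' @param missing_rate per-call probability of a missing genotype.
#' @param seed integer RNG seed.
#' @param linkage_group label written into the marker map.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_females, n_males, loci, missing_rate = 0,
                       seed = 1, linkage_group = "XII") {
  stopifnot(n_females >= 0, n_males >= 0,
            missing_rate >= 0, missing_rate < 1)
  if (!all(vapply(loci, inherits, logical(1), "locus_spec"))) {
    stop("loci must be a list of locus_spec objects")
  }
  nm <- vapply(loci, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate locus names in config")
  structure(list(n_females = as.integer(n_females),
                 n_males = as.integer(n_males),
                 loci = loci, missing_rate = missing_rate,
                 seed = as.integer(seed),
                 linkage_group = as.character(linkage_group)),
            class = "sim_config")
}

# one stepwise-mutation pass over a vector of transmitted alleles
apply_smm <- function(alleles, step, rate) {
  if (rate <= 0) return(alleles)
  hit <- stats::runif(length(alleles)) < rate
  dir <- sample(c(-1L, 1L), length(alleles), replace = TRUE)
  alleles[hit] <- alleles[hit] + dir[hit] * step
  alleles
}

#' Simulate an XY genotype table
#'
#' Draws genotypes under the model of [locus_spec()]: females receive two
#' independent X draws; males receive one X draw plus, depending on mode,
#' the fixed Y allele (`XY_DIFF`), a duplicated score of their X allele
#' (`Y_NULL`; how a non-amplifying Y manifests on a fragment gel), or a
#' second draw from the same pool (`AUTOSOMAL`). Stepwise mutation is
#' applied per transmitted allele; missing calls are inserted at
#' `missing_rate`. The Y is a single non-recombining haplotype shared by
#' all males, so LD among Y-linked loci arises automatically. Loci are
#' otherwise conditionally independent given sex. Fully reproducible from
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `table` (a [genotype_table()], sexes attached) and
#'   `truth` (list: per-locus data.frame `loci` with generating `mode` and
#'   `y_allele`, plus `n_females`, `n_males`, `seed`).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  nf <- config$n_females; nm <- config$n_males
  n <- nf + nm
  ids <- c(sprintf("F%02d", seq_len(nf)), sprintf("M%02d", seq_len(nm)))
  sex <- c(rep("F", nf), rep("M", nm))
  L <- length(config$loci)
  a1 <- a2 <- matrix(NA_integer_, n, L)
  with_seed(config$seed, {
    for (j in seq_len(L)) {
      sp <- config$loci[[j]]
      al <- as.integer(names(sp$x_allele_freqs))
      draw_x <- function(k) {
        x <- al[sample.int(length(al), k, replace = TRUE,
                           prob = sp$x_allele_freqs)]
        apply_smm(x, sp$motif_step, sp$mutation_rate)
      }
      if (nf > 0) {
        a1[seq_len(nf), j] <- draw_x(nf)
        a2[seq_len(nf), j] <- draw_x(nf)
      }
      if (nm > 0) {
        mi <- nf + seq_len(nm)
        x <- draw_x(nm)
        if (sp$mode == "AUTOSOMAL") {
          a1[mi, j] <- x; a2[mi, j] <- draw_x(nm)
        } else if (sp$mode == "XY_DIFF") {
          y <- apply_smm(rep(sp$y_allele, nm), sp$motif_step,
                         sp$mutation_rate)
          a1[mi, j] <- x; a2[mi, j] <- y
        } else {  # Y_NULL: only the X copy amplifies, scored homozygous
          a1[mi, j] <- x; a2[mi, j] <- x
        }
      }
      if (config$missing_rate > 0) {
        drop <- stats::runif(n) < config$missing_rate
        a1[drop, j] <- NA_integer_; a2[drop, j] <- NA_integer_
      }
    }
  })
  loci_df <- data.frame(
    name = vapply(config$loci, `[[`, character(1), "name"),
    linkage_group = config$linkage_group,
    position_bp = vapply(config$loci, `[[`, integer(1), "position_bp"),
    motif = NA_character_, stringsAsFactors = FALSE)
  tab <- genotype_table(ids = ids, loci = loci_df, a1 = a1, a2 = a2,
                        sex = sex)
  truth <- list(
    loci = data.frame(
      name = loci_df$name, mode = vapply(config$loci, `[[`, character(1),
                                         "mode"),
      y_allele = vapply(config$loci, `[[`, integer(1), "y_allele"),
      position_bp = loci_df$position_bp, stringsAsFactors = FALSE),
    n_females = nf, n_males = nm, seed = config$seed)
  list(table = tab, truth = truth)
}

# allele pools: HIGH = 8 alleles, symmetric Dirichlet(1) frequencies;
# LOW = near-monomorphic (0.998 / 0.002). X alleles sit on an even-size
# lattice and Y alleles on an odd one, so stepwise mutation never makes a
# Y allele collide with the X pool.
rdirichlet1 <- function(k) { g <- stats::rgamma(k, 1); g / sum(g) }

diversity_pool <- function(preset, base) {
  if (preset == "HIGH") {
    al <- base + 2L * (0:7)
    stats::setNames(rdirichlet1(8), al)
  } else {
    stats::setNames(c(0.998, 0.002), c(base, base + 2L))
  }
}

#' Preset simulation configurations
#'
#' Three ready-made designs mirroring common study layouts:
#' \itemize{
#'   \item `PYOREALAMPI_LIKE` -- 24 females + 24 males, 14 loci, a
#'     near-monomorphic X pool (population H_E about 0.004), 13 `XY_DIFF`
#'     loci plus one autosomal locus that is effectively monomorphic
#'     (uninformative): the pond-population pattern where every polymorphic
#'     locus carries one fixed male-specific allele.
#'   \item `BALTIC_LIKE` -- 24 + 24, 14 loci, multi-allelic X pools
#'     (8 alleles, symmetric Dirichlet(1) frequencies), 13 `XY_DIFF` plus
#'     one autosomal: a high-diversity marine population.
#'   \item `THREESPINE_LIKE` -- 25 females + 23 males, 14 loci at
#'     positions spanning 0.5-19.6 Mb, multi-allelic pools, 5 `XY_DIFF`
#'     loci in two position clusters (3.2-4.0 and 9.4-11.8 Mb), 7 `Y_NULL`
#'     in two clusters (5.1-7.4 and 14.7-19.6 Mb) and 2 autosomal: a
#'     degenerate-Y layout.
#' }
#'
#' @param preset one of the names above.
#' @param seed integer seed (drives both pool frequencies and genotypes).
#' @param missing_rate per-call missing probability (default 0.02, a
#'   typical genotyping failure rate).
#' @return A [sim_config()].
#' @export
preset_config <- function(preset = c("PYOREALAMPI_LIKE", "BALTIC_LIKE",
                                     "THREESPINE_LIKE"),
                          seed = 1, missing_rate = 0.02) {
  preset <- match.arg(preset)
  with_seed(seed * 2L + 1L, {
    if (preset %in% c("PYOREALAMPI_LIKE", "BALTIC_LIKE")) {
      div <- if (preset == "PYOREALAMPI_LIKE") "LOW" else "HIGH"
      pos <- c(188976L, 3625645L, 4802750L, 4843632L, 5616109L, 7178391L,
               7695994L, 9015356L, 10780938L, 12581231L, 15639505L,
               16027500L, 16138995L, 18276705L)
      loci <- lapply(1:14, function(i) {
        base <- 150L + 20L * ((i - 1L) %% 5L)
        pool <- diversity_pool(div, base)
        if (i == 1L) {
          locus_spec(sprintf("sim%02d", i), pos[i], "AUTOSOMAL", pool)
        } else {
          locus_spec(sprintf("sim%02d", i), pos[i], "XY_DIFF", pool,
                     y_allele = base + 21L)
        }
      })
      sim_config(24, 24, loci, missing_rate = missing_rate, seed = seed,
                 linkage_group = "XII")
    } else {
      pos_mb <- c(0.5, 3.2, 4.0, 5.1, 6.2, 7.4, 9.4, 11.3, 11.8, 12.9,
                  14.7, 16.5, 18.0, 19.6)
      mode <- c("AUTOSOMAL", "XY_DIFF", "XY_DIFF",
                "Y_NULL", "Y_NULL", "Y_NULL",
                "XY_DIFF", "XY_DIFF", "XY_DIFF", "AUTOSOMAL",
                "Y_NULL", "Y_NULL", "Y_NULL", "Y_NULL")
      loci <- lapply(1:14, function(i) {
        base <- 150L + 20L * ((i - 1L) %% 5L)
        pool <- diversity_pool("HIGH", base)
        locus_spec(sprintf("sim%02d", i), as.integer(pos_mb[i] * 1e6),
                   mode[i], pool,
                   y_allele = if (mode[i] == "XY_DIFF") base + 21L
                              else NA_integer_)
      })
      sim_config(25, 23, loci, missing_rate = missing_rate, seed = seed,
                 linkage_group = "XIX")
    }
  })
}
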