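#' Male-specific alleles at a locus
#'
#' Lists every allele carried by at least one male and by no female, with
#' the fraction of typed males carrying it. Under male heterogamety an
#' allele restricted to males and present in (nearly) all of them is the
#' classic signature of a Y-linked allele.
#'
#' @inheritParams het_stats
#' @return list with `locus`, `alleles` (data.frame: `allele`,
#'   `male_carrier_fraction`), `n_typed_males`.
#' @export
find_male_specific_alleles <- function(table, locus) {
  tm <- typed_calls(table, locus, group_rows(table, "M"))
  tf <- typed_calls(table, locus, group_rows(table, "F"))
  if (length(tm$a1) == 0) stop("no typed males at ", locus)
  if (length(tf$a1) == 0) stop("no typed females at ", locus)
  male_alleles <- sort(unique(c(tm$a1, tm$a2)))
  female_alleles <- unique(c(tf$a1, tf$a2))
  specific <- setdiff(male_alleles, female_alleles)
  n_m <- length(tm$a1)
  frac <- vapply(specific, function(a) {
    sum(tm$a1 == a | tm$a2 == a) / n_m
  }, numeric(1))
  list(locus = locus,
       alleles = data.frame(allele = specific,
                            male_carrier_fraction = frac),
       n_typed_males = n_m)
}

#' Classify a locus by its sex-differentiation signature
#'
#' Decision rules, applied in order:
#' \itemize{
#'   \item `UNINFORMATIVE` -- monomorphic overall (no information).
#'   \item `XY_DIFFERENTIATED` -- at least one male-specific allele with
#'     carrier fraction >= `tau_m` among typed males, and significant
#'     between-sex F_ST (after any multiple-testing correction applied by
#'     the caller).
#'   \item `Y_NULL` -- polymorphic, zero heterozygous typed males, and a
#'     null-allele signal in males but not in females (the signature of a
#'     deleted or non-amplifying Y copy).
#'   \item `UNDIFFERENTIATED` otherwise.
#' }
#' Loci where more than `max_missing_males` of males are untyped are only
#' flagged (`high_missing_males`), never called `Y_NULL`.
#'
#' @inheritParams het_stats
#' @param fst_significant logical: is between-sex F_ST significant for this
#'   locus (normally after Holm correction across loci)?
#' @param msa result of [find_male_specific_alleles()]; computed if `NULL`.
#' @param null_m,null_f results of [null_allele_scan()] for males and
#'   females; computed if `NULL` (with `n_perm`, `seed`).
#' @param tau_m minimum male carrier fraction for the XY call (default 1:
#'   the allele must be carried by every typed male).
#' @param alpha significance level used for any internally computed tests.
#' @param max_missing_males missingness threshold above which the Y-null
#'   rule is suspended.
#' @param n_perm,seed settings for internally computed null-allele scans.
#' @return list with `locus`, `call` and an `evidence` list of flags.
#' @export
classify_locus <- function(table, locus, fst_significant,
                           msa = NULL, null_m = NULL, null_f = NULL,
                           tau_m = 1.0, alpha = 0.05,
                           max_missing_males = 0.2,
                           n_perm = 1000, seed = 1) {
  tc_all <- typed_calls(table, locus, group_rows(table, "ALL"))
  A_all <- length(unique(c(tc_all$a1, tc_all$a2)))
  males <- group_rows(table, "M")
  tm <- typed_calls(table, locus, males)
  miss_m <- if (length(males)) 1 - length(tm$a1) / length(males) else 1
  high_missing <- miss_m > max_missing_males

  if (A_all < 2) {
    return(list(locus = locus, call = "UNINFORMATIVE",
                evidence = list(has_male_specific_allele = FALSE,
                                fst_significant = FALSE,
                                zero_het_males = NA,
                                male_fis = NA_real_,
                                male_only_null_signal = FALSE,
                                near_specific_alleles = integer(0),
                                high_missing_males = high_missing)))
  }
  if (is.null(msa)) msa <- find_male_specific_alleles(table, locus)
  strong <- msa$alleles$male_carrier_fraction >= tau_m - 1e-12
  has_msa <- nrow(msa$alleles) > 0 && any(strong)
  # alleles male-biased but not strictly male-specific are reported as
  # evidence only, never auto-called
  tf <- typed_calls(table, locus, group_rows(table, "F"))
  male_alleles <- unique(c(tm$a1, tm$a2))
  near <- integer(0)
  for (a in setdiff(male_alleles, msa$alleles$allele)) {
    fr_m <- sum(tm$a1 == a | tm$a2 == a) / length(tm$a1)
    fr_f <- sum(tf$a1 == a | tf$a2 == a) / length(tf$a1)
    if (fr_m >= 0.75 && fr_f <= 0.15) near <- c(near, a)
  }
  zero_het_males <- length(tm$a1) > 0 && all(tm$a1 == tm$a2)
  male_fis <- fis_wc(table, locus, "M")

  if (has_msa && isTRUE(fst_significant)) {
    call <- "XY_DIFFERENTIATED"
    null_sig <- FALSE
  } else {
    if (is.null(null_m)) {
      null_m <- tryCatch(
        null_allele_scan(table, locus, "M", alpha = alpha,
                         n_perm = n_perm, seed = seed),
        error = function(e) list(null_suspected = FALSE))
    }
    if (is.null(null_f)) {
      null_f <- tryCatch(
        null_allele_scan(table, locus, "F", alpha = alpha,
                         n_perm = n_perm, seed = seed + 1L),
        error = function(e) list(null_suspected = FALSE))
    }
    null_sig <- isTRUE(null_m$null_suspected) &&
      !isTRUE(null_f$null_suspected)
    call <- if (zero_het_males && null_sig && !high_missing) "Y_NULL"
            else "UNDIFFERENTIATED"
  }
  list(locus = locus, call = call,
       evidence = list(has_male_specific_allele = has_msa,
                       fst_significant = isTRUE(fst_significant),
                       zero_het_males = zero_het_males,
                       male_fis = male_fis,
                       male_only_null_signal = null_sig,
                       near_specific_alleles = near,
                       high_missing_males = high_missing))
}

#' Summarize differentiated loci into chromosomal intervals
#'
#' Walks loci in map order and merges consecutive `XY_DIFFERENTIATED` /
#' `Y_NULL` loci into maximal intervals. An interval is closed when an
#' `UNDIFFERENTIATED` locus intervenes or when the differentiation class
#' changes; `UNINFORMATIVE` (monomorphic) loci are skipped and never split
#' an interval. The span is the distance from the first to the last
#' differentiated position, in Mb (bp / 1e6, reported to 1 decimal).
#'
#' @param calls character vector of locus calls (see [classify_locus()]).
#' @param position_bp integer vector of 1-based positions, same length.
#' @param chromosome_length_mb optional chromosome length for the covered
#'   fraction; `NA` leaves the fraction undefined.
#' @return list with `intervals` (data.frame: `lo_mb`, `hi_mb`, `class`),
#'   `span_mb`, `chromosome_length_mb`, `fraction`.
#' @examples
#' summarize_regions(c("XY_DIFFERENTIATED", "Y_NULL"), c(3.2e6, 19.6e6))
#' @export
summarize_regions <- function(calls, position_bp,
                              chromosome_length_mb = NA_real_) {
  stopifnot(length(calls) == length(position_bp))
  ord <- order(position_bp)
  calls <- calls[ord]; pos <- position_bp[ord]
  diff_class <- c("XY_DIFFERENTIATED", "Y_NULL")
  keep <- calls != "UNINFORMATIVE"
  calls <- calls[keep]; pos <- pos[keep]
  lo <- hi <- numeric(0); cls <- character(0)
  cur_lo <- cur_hi <- NA_real_; cur_cls <- NA_character_
  flush <- function() {
    if (!is.na(cur_lo)) {
      lo <<- c(lo, cur_lo); hi <<- c(hi, cur_hi); cls <<- c(cls, cur_cls)
    }
    cur_lo <<- cur_hi <<- NA_real_; cur_cls <<- NA_character_
  }
  for (i in seq_along(calls)) {
    if (calls[i] %in% diff_class) {
      if (!is.na(cur_cls) && calls[i] != cur_cls) flush()
      if (is.na(cur_lo)) { cur_lo <- pos[i]; cur_cls <- calls[i] }
      cur_hi <- pos[i]
    } else {
      flush()
    }
  }
  flush()
  mb <- function(x) round(x / 1e6, 1)
  intervals <- data.frame(lo_mb = mb(lo), hi_mb = mb(hi), class = cls,
                          stringsAsFactors = FALSE)
  # drop duplicate intervals arising from co-located loci
  intervals <- unique(intervals)
  span <- if (length(lo)) mb(max(hi)) - mb(min(lo)) else 0
  frac <- if (!is.na(chromosome_length_mb) && length(lo)) {
    span / chromosome_length_mb
  } else NA_real_
  list(intervals = intervals, span_mb = round(span, 1),
       chromosome_length_mb = chromosome_length_mb, fraction = frac)
}

#' Full per-locus sex-linkage scan
#'
#' Runs the whole analysis chain on a labelled genotype table: per-sex
#' heterozygosity, Weir-Cockerham F_IS per sex with allele-permutation
#' significance, between-sex F_ST with sex-label-permutation significance,
#' allele-dosage trend test, male-specific alleles, per-sex null-allele
#' diagnostics, Holm ("sequential Bonferroni") correction within each test
#' family across loci, and locus classification.
#'
#' @param table a [genotype_table()] with sexes attached.
#' @param loci loci to scan (default: all).
#' @param n_perm permutations per test (study default 10000).
#' @param alpha family-wise significance level.
#' @param seed integer seed; every permutation stream is derived from it.
#' @param tau_m minimum male carrier fraction for the XY call.
#' @return list of class `sexlink_scan` with `per_locus` (data.frame),
#'   `classification` (data.frame), `msa` (named list),
#'   `region` placeholder (`NULL`; see [summarize_regions()]),
#'   and the run parameters.
#' @export
scan_sex_linkage <- function(table, loci = table$loci$name,
                             n_perm = 10000, alpha = 0.05, seed = 1,
                             tau_m = 1.0) {
  stopifnot(inherits(table, "genotype_table"))
  if (!any(table$ind$sex %in% "F") || !any(table$ind$sex %in% "M")) {
    stop("scan requires both sexes; attach sex labels first")
  }
  rows <- lapply(seq_along(loci), function(i) {
    locus <- loci[i]
    s <- seed + 17L * i
    h_all <- het_stats(table, locus, "ALL")
    h_f <- het_stats(table, locus, "F")
    h_m <- het_stats(table, locus, "M")
    poly_f <- h_f$A > 1; poly_m <- h_m$A > 1; poly <- h_all$A > 1
    fis_f <- if (poly_f) fis_wc(table, locus, "F") else NA_real_
    fis_m <- if (poly_m) fis_wc(table, locus, "M") else NA_real_
    p_fis_f <- if (poly_f && !is.na(fis_f)) {
      permute_p(table, locus, "fis", group = "F",
                n_perm = n_perm, seed = s)$p
    } else NA_real_
    p_fis_m <- if (poly_m && !is.na(fis_m)) {
      permute_p(table, locus, "fis", group = "M",
                n_perm = n_perm, seed = s + 1L)$p
    } else NA_real_
    fst <- if (poly) fst_wc_sex(table, locus) else NA_real_
    p_fst <- if (poly && !is.na(fst)) {
      permute_p(table, locus, "fst", n_perm = n_perm, seed = s + 2L)$p
    } else NA_real_
    trend_p <- if (poly) trend_test(table, locus)$locus_p else NA_real_
    data.frame(locus = locus,
               n_f = h_f$n_typed, n_m = h_m$n_typed,
               A = h_all$A, A_f = h_f$A, A_m = h_m$A,
               H_O_f = h_f$H_O, H_E_f = h_f$H_E,
               H_O_m = h_m$H_O, H_E_m = h_m$H_E,
               F_IS_f = fis_f, p_FIS_f = p_fis_f,
               F_IS_m = fis_m, p_FIS_m = p_fis_m,
               F_ST = fst, p_FST = p_fst, trend_p = trend_p,
               stringsAsFactors = FALSE)
  })
  per_locus <- do.call(rbind, rows)

  holm_col <- function(p) {
    out <- rep(NA_real_, length(p))
    ok <- !is.na(p)
    if (any(ok)) out[ok] <- stats::p.adjust(p[ok], method = "holm")
    out
  }
  per_locus$p_FIS_f_holm <- holm_col(per_locus$p_FIS_f)
  per_locus$p_FIS_m_holm <- holm_col(per_locus$p_FIS_m)
  per_locus$p_FST_holm <- holm_col(per_locus$p_FST)
  per_locus$trend_p_holm <- holm_col(per_locus$trend_p)

  msa <- stats::setNames(lapply(loci, function(l) {
    tryCatch(find_male_specific_alleles(table, l), error = function(e) NULL)
  }), loci)

  # null-allele diagnostics per sex, with Holm correction of the
  # homozygote-excess p-values across loci within each sex family
  # ("sequential Bonferroni for all multiple comparisons")
  null_by_sex <- lapply(c(F = "F", M = "M"), function(g) {
    res <- lapply(seq_along(loci), function(i) {
      tryCatch(null_allele_scan(table, loci[i], g, alpha = alpha,
                                n_perm = min(n_perm, 2000),
                                seed = seed + 1000L + i +
                                  1000000L * (g == "M")),
               error = function(e) NULL)
    })
    p <- vapply(res, function(r) {
      if (is.null(r)) NA_real_ else r$homozygote_excess_p
    }, numeric(1))
    adj <- rep(NA_real_, length(p))
    ok <- !is.na(p)
    if (any(ok)) adj[ok] <- stats::p.adjust(p[ok], method = "holm")
    for (i in seq_along(res)) {
      if (!is.null(res[[i]])) {
        res[[i]]$homozygote_excess_p_holm <- adj[i]
        res[[i]]$null_suspected <- isTRUE(
          adj[i] < alpha && !is.na(res[[i]]$r_chakraborty) &&
            res[[i]]$r_chakraborty > 0)
      }
    }
    res
  })

  cls <- lapply(seq_along(loci), function(i) {
    locus <- loci[i]
    fst_sig <- !is.na(per_locus$p_FST_holm[i]) &&
      per_locus$p_FST_holm[i] <= alpha
    cl <- classify_locus(table, locus, fst_significant = fst_sig,
                         msa = msa[[locus]],
                         null_m = null_by_sex$M[[i]],
                         null_f = null_by_sex$F[[i]],
                         tau_m = tau_m, alpha = alpha,
                         n_perm = min(n_perm, 2000),
                         seed = seed + 1000L + i)
    pos <- table$loci$position_bp[locus_index(table, locus)]
    data.frame(locus = locus, position_bp = pos, call = cl$call,
               has_male_specific_allele =
                 cl$evidence$has_male_specific_allele,
               fst_significant = cl$evidence$fst_significant,
               zero_het_males = cl$evidence$zero_het_males,
               male_fis = cl$evidence$male_fis,
               male_only_null_signal = cl$evidence$male_only_null_signal,
               high_missing_males = cl$evidence$high_missing_males,
               stringsAsFactors = FALSE)
  })
  classification <- do.call(rbind, cls)

  out <- list(per_locus = per_locus, classification = classification,
              msa = msa, n_perm = n_perm, alpha = alpha, seed = seed,
              tau_m = tau_m)
  class(out) <- "sexlink_scan"
  out
}

#' @export
print.sexlink_scan <- function(x, ...) {
  cat("sexlink_scan of", nrow(x$per_locus), "loci (n_perm =", x$n_perm,
      ", alpha =", x$alpha, ")\n")
  print(table(x$classification$call))
  invisible(x)
}
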