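#' Pairwise linkage-disequilibrium scan
#'
#' Runs [ld_test()] on every unordered pair of loci (k loci give
#' `choose(k, 2)` tests) and applies Holm correction across the pairs.
#'
#' @inheritParams scan_sex_linkage
#' @param n_perm permutations per pair.
#' @return data.frame with `locus_a`, `locus_b`, `g_statistic`, `p`,
#'   `p_holm`, `significant_after_correction`.
#' @export
ld_scan <- function(table, loci = table$loci$name, n_perm = 1000,
                    alpha = 0.05, seed = 1) {
  if (length(loci) < 2) stop("LD scan needs at least 2 loci")
  pairs <- utils::combn(loci, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    r <- ld_test(table, pairs[1, i], pairs[2, i], n_perm = n_perm,
                 seed = seed + i)
    data.frame(locus_a = r$locus_a, locus_b = r$locus_b,
               g_statistic = r$g_statistic, p = r$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- stats::p.adjust(out$p, method = "holm")
  out$significant_after_correction <- out$p_holm <= alpha
  out
}

fmt_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), NA, sprintf("%.4f", x))
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

write_manifest <- function(path, command, params, inputs = character(0)) {
  digest <- if (length(inputs)) {
    as.list(tools::md5sum(inputs))
  } else NULL
  manifest <- c(list(command = command,
                     tool = "microXY",
                     version = as.character(
                       utils::packageVersion("microXY")),
                     timestamp = format(Sys.time(), tz = "UTC",
                                        "%Y-%m-%dT%H:%M:%SZ")),
                params,
                list(input_md5 = digest))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' End-to-end sex-linkage scan from files
#'
#' Reads a Genepop genotype file, a sex-label TSV and (optionally) a marker
#' map, runs [scan_sex_linkage()], [ld_scan()] and [summarize_regions()],
#' and writes: `per_locus_stats.tsv`, `ld_pairs.tsv`,
#' `classification.tsv`, `regions.json` and `manifest.json` in `outdir`.
#' All reported numbers are re-derivable by calling the module functions
#' directly; given identical inputs and seed, the TSV outputs are
#' byte-identical across runs.
#'
#' @param genepop path to the Genepop file.
#' @param sexes path to the sex-label TSV (`id`, `sex`).
#' @param map optional path to a marker-map TSV; required for the region
#'   summary.
#' @param outdir output directory (created if needed).
#' @param n_perm,alpha,seed,tau_m scan parameters (see
#'   [scan_sex_linkage()]).
#' @param ld_n_perm permutations for the (heavier) pairwise LD stage.
#' @param chromosome_length_mb optional chromosome length for the covered
#'   fraction.
#' @param allele_digits Genepop allele-code width.
#' @return Invisibly, a list with all in-memory results.
#' @export
run_scan <- function(genepop, sexes, map = NULL, outdir = ".",
                     n_perm = 10000, alpha = 0.05, seed = 1, tau_m = 1.0,
                     ld_n_perm = min(n_perm, 1000),
                     chromosome_length_mb = NA_real_, allele_digits = 3) {
  tab <- read_genepop(genepop, allele_digits = allele_digits)
  tab <- attach_sex_labels(tab, read_sex_labels(sexes))
  if (!is.null(map)) {
    mp <- read_marker_map(map)
    extra <- setdiff(mp$name, tab$loci$name)
    missing_loci <- setdiff(tab$loci$name, mp$name)
    if (length(missing_loci)) {
      stop("locus set mismatch: loci absent from map: ",
           paste(missing_loci, collapse = ", "))
    }
    if (length(extra)) {
      message("map loci not in genotypes (ignored): ",
              paste(extra, collapse = ", "))
    }
    tab <- attach_marker_map(tab, mp)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  scan <- scan_sex_linkage(tab, n_perm = n_perm, alpha = alpha,
                           seed = seed, tau_m = tau_m)
  ld <- ld_scan(tab, n_perm = ld_n_perm, alpha = alpha, seed = seed)
  region <- summarize_regions(scan$classification$call,
                              scan$classification$position_bp,
                              chromosome_length_mb)

  fmt_tsv(scan$per_locus, file.path(outdir, "per_locus_stats.tsv"))
  fmt_tsv(ld, file.path(outdir, "ld_pairs.tsv"))
  fmt_tsv(scan$classification, file.path(outdir, "classification.tsv"))
  jsonlite::write_json(region, file.path(outdir, "regions.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(file.path(outdir, "manifest.json"), "scan",
                 list(n_perm = n_perm, ld_n_perm = ld_n_perm,
                      alpha = alpha, seed = seed, tau_m = tau_m),
                 inputs = c(genepop, sexes, map))
  invisible(list(table = tab, scan = scan, ld = ld, region = region))
}

#' Simulate a study and write its input files
#'
#' Generates a genotype table from a preset or custom configuration and
#' writes `genotypes.gen` (Genepop), `sexes.tsv`, `marker_map.tsv`,
#' `truth.json` and `manifest.json` to `outdir`.
#'
#' @param preset a [preset_config()] name, ignored when `config` is given.
#' @param config a [sim_config()], overriding `preset`.
#' @param seed integer seed.
#' @param outdir output directory.
#' @param force overwrite a non-empty `outdir`.
#' @return Invisibly, the list from [simulate_genotypes()].
#' @export
run_simulate <- function(preset = "PYOREALAMPI_LIKE", config = NULL,
                         seed = 1, outdir = ".", force = FALSE) {
  if (is.null(config)) config <- preset_config(preset, seed = seed)
  if (dir.exists(outdir) && length(dir(outdir)) > 0 && !force) {
    stop("output directory ", outdir, " is not empty (use force = TRUE)")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_genotypes(config)
  write_genepop(sim$table, file.path(outdir, "genotypes.gen"))
  utils::write.table(sim$table$ind[, c("id", "sex")],
                     file.path(outdir, "sexes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "U")
  utils::write.table(
    data.frame(locus = sim$table$loci$name,
               linkage_group = sim$table$loci$linkage_group,
               position_bp = sim$table$loci$position_bp,
               motif = sim$table$loci$motif),
    file.path(outdir, "marker_map.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, na = "")
  jsonlite::write_json(sim$truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(file.path(outdir, "manifest.json"), "simulate",
                 list(seed = seed,
                      n_females = config$n_females,
                      n_males = config$n_males,
                      missing_rate = config$missing_rate,
                      n_loci = length(config$loci)))
  invisible(sim)
}

parse_interval <- function(interval) {
  m <- regmatches(interval,
                  regexec("^(.+):([0-9]+)-([0-9]+)$", interval))[[1]]
  if (length(m) != 4) stop("interval must be 'chrom:start-end', got ",
                           interval)
  list(chrom = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
}

#' Cross-species primer design from FASTA input
#'
#' Extracts the target interval from the reference FASTA, detects
#' microsatellites there, aligns the region against the second species'
#' sequence to locate conserved windows, enumerates constraint-passing
#' primer pairs in the windows flanking each repeat, GTTT-tails the
#' reverse primers, and writes `primers.tsv` plus `manifest.json`.
#'
#' @param fasta_ref reference-species FASTA (record names must include the
#'   interval's chromosome).
#' @param fasta_other diverged-species FASTA (first record used).
#' @param interval target as `"chrom:start-end"` (1-based closed).
#' @param outdir output directory.
#' @param constraints primer constraints (see [design_primer_pairs()]).
#' @param flank_len how far from each repeat to look for windows (bp).
#' @param min_len,min_identity conserved-window thresholds.
#' @param min_repeats SSR thresholds (see [find_ssrs()]).
#' @param max_pairs_per_ssr pairs reported per repeat.
#' @return Invisibly, the primer data.frame.
#' @export
run_design <- function(fasta_ref, fasta_other, interval, outdir = ".",
                       constraints = default_primer_constraints(),
                       flank_len = 500, min_len = 20, min_identity = 0.9,
                       min_repeats = c("2" = 6, "3" = 6, "4" = 5,
                                       "5" = 4, "6" = 4),
                       max_pairs_per_ssr = 5) {
  ref <- Biostrings::readDNAStringSet(fasta_ref)
  oth <- Biostrings::readDNAStringSet(fasta_other)
  iv <- parse_interval(interval)
  hit <- which(vapply(strsplit(names(ref), "\\s+"), `[[`, character(1), 1)
               == iv$chrom)
  if (!length(hit)) stop("chromosome ", iv$chrom, " not in ", fasta_ref)
  refseq <- ref[[hit[1]]]
  if (iv$start < 1 || iv$end > length(refseq) || iv$start > iv$end) {
    stop("interval ", interval, " out of bounds for record of length ",
         length(refseq))
  }
  region <- as.character(Biostrings::subseq(refseq, iv$start, iv$end))
  other <- as.character(oth[[1]])
  ssrs <- find_ssrs(region, min_repeats = min_repeats)
  windows <- conserved_windows(region, other, min_len = min_len,
                               min_identity = min_identity)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (i in seq_len(nrow(ssrs))) {
    ssr <- ssrs[i, ]
    near <- windows[windows$ref_end >= ssr$start - flank_len &
                    windows$ref_start <= ssr$end + flank_len, ,
                    drop = FALSE]
    pairs <- design_primer_pairs(region, ssr, near,
                                 constraints = constraints,
                                 max_pairs = max_pairs_per_ssr)
    if (nrow(pairs) == 0) next
    pairs <- add_pigtail(pairs)
    pairs$locus <- sprintf("ssr%02d", i)
    pairs$motif <- ssr$motif
    pairs$repeat_count <- ssr$repeat_count
    pairs$ssr_start <- ssr$start + iv$start - 1L
    rows[[length(rows) + 1L]] <- pairs
  }
  primers <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus = character(0), motif = character(0),
               forward = character(0), reverse = character(0))
  cols <- intersect(c("locus", "motif", "repeat_count", "ssr_start",
                      "forward", "reverse", "tm_f", "tm_r", "gc_f", "gc_r",
                      "product_size", "reverse_tailed"), names(primers))
  fmt_tsv(primers[, cols, drop = FALSE],
          file.path(outdir, "primers.tsv"))
  write_manifest(file.path(outdir, "manifest.json"), "design",
                 list(interval = interval, flank_len = flank_len,
                      min_len = min_len, min_identity = min_identity),
                 inputs = c(fasta_ref, fasta_other))
  invisible(primers)
}
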