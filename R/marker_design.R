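#' Wallace-rule melting temperature
#'
#' `Tm = 2(A+T) + 4(G+C)` degrees C -- the classic rule of thumb, adequate
#' for the 17-25-mer primers this package designs.
#'
#' @param seq character vector of primer sequences (A/C/G/T).
#' @return numeric Tm in degrees C.
#' @export
wallace_tm <- function(seq) {
  vapply(toupper(seq), function(s) {
    b <- strsplit(s, "")[[1]]
    2 * sum(b %in% c("A", "T")) + 4 * sum(b %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
}

#' GC content in percent
#' @param seq character vector of sequences.
#' @return numeric percentage.
#' @export
gc_percent <- function(seq) {
  vapply(toupper(seq), function(s) {
    b <- strsplit(s, "")[[1]]
    100 * sum(b %in% c("G", "C")) / length(b)
  }, numeric(1), USE.NAMES = FALSE)
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# TRUE if the motif is a repetition of a shorter unit (e.g. "ACAC", "AA")
is_non_primitive <- function(motif) {
  k <- nchar(motif)
  for (d in seq_len(k - 1)) {
    if (k %% d == 0) {
      unit <- substr(motif, 1, d)
      if (paste(rep(unit, k / d), collapse = "") == motif) return(TRUE)
    }
  }
  FALSE
}

#' Detect perfect microsatellite repeats
#'
#' Scans a DNA sequence for maximal perfect tandem repeats of 2-6 bp
#' motifs. `N` breaks runs; motifs that are themselves repeats of a shorter
#' unit are suppressed (a homopolymer is never reported as a dinucleotide).
#' Overlapping candidates are resolved greedily, longest span first. Motifs
#' are reported as written at the start of the run (leading strand).
#'
#' @param sequence DNA string over A/C/G/T/N.
#' @param min_repeats named integer vector, minimum repeat count per motif
#'   length (names `"2"` to `"6"`).
#' @return data.frame with columns `motif`, `repeat_count`, `start`, `end`
#'   (1-based closed), ordered by `start`; zero rows if none found.
#' @examples
#' find_ssrs("TTTGATGATGATGATGATGATTTT")
#' @export
find_ssrs <- function(sequence,
                      min_repeats = c("2" = 6, "3" = 6, "4" = 5,
                                      "5" = 4, "6" = 4)) {
  s <- strsplit(toupper(sequence), "")[[1]]
  n <- length(s)
  cand <- list()
  for (k_chr in names(min_repeats)) {
    k <- as.integer(k_chr)
    minrep <- min_repeats[[k_chr]]
    if (n < k * minrep) next
    eq <- s[seq_len(n - k)] == s[(k + 1):n] &
      s[seq_len(n - k)] != "N" & s[(k + 1):n] != "N"
    r <- rle(eq)
    pos <- cumsum(c(1L, r$lengths))
    for (i in seq_along(r$lengths)) {
      if (!r$values[i]) next
      run_start <- pos[i]
      m <- r$lengths[i]
      reps <- (m + k) %/% k
      if (reps < minrep) next
      motif <- paste(s[run_start:(run_start + k - 1)], collapse = "")
      if (is_non_primitive(motif)) next
      cand[[length(cand) + 1L]] <- data.frame(
        motif = motif, repeat_count = reps, start = run_start,
        end = run_start + k * reps - 1L, stringsAsFactors = FALSE)
    }
  }
  if (!length(cand)) {
    return(data.frame(motif = character(0), repeat_count = integer(0),
                      start = integer(0), end = integer(0)))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(-(cand$end - cand$start), cand$start), , drop = FALSE]
  keep <- logical(nrow(cand))
  covered <- rep(FALSE, n)
  for (i in seq_len(nrow(cand))) {
    idx <- cand$start[i]:cand$end[i]
    if (!any(covered[idx])) { keep[i] <- TRUE; covered[idx] <- TRUE }
  }
  out <- cand[keep, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' Conserved windows between two orthologous sequences
#'
#' Globally aligns the reference flank against the diverged species' flank
#' (match +1, mismatch -1, gap open -2, gap extend -1), then reports
#' maximal gapless stretches of aligned columns whose identity meets
#' `min_identity` and whose length meets `min_len`, in reference
#' coordinates. These are the candidate cross-species primer-binding
#' sites.
#'
#' @param ref_flank,other_flank DNA strings.
#' @param min_len minimum window length (bp).
#' @param min_identity minimum fraction of matching columns.
#' @return data.frame with columns `ref_start`, `ref_end`, `identity`,
#'   `gapless` (always `TRUE`).
#' @export
conserved_windows <- function(ref_flank, other_flank, min_len = 20,
                              min_identity = 0.9) {
  stopifnot(nzchar(ref_flank), nzchar(other_flank))
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(toupper(ref_flank)),
    Biostrings::DNAString(toupper(other_flank)),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 2, gapExtension = 1)
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  q <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  gapless <- p != "-" & q != "-"
  match <- gapless & p == q
  refpos <- cumsum(p != "-")

  out <- list()
  r <- rle(gapless)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  cmatch <- cumsum(match)
  for (i in seq_along(r$lengths)) {
    if (!r$values[i]) next
    a <- starts[i]; b <- ends[i]
    mm <- which(!match[a:b]) + a - 1L
    cand_lo <- unique(c(a, mm + 1L)); cand_hi <- unique(c(b, mm - 1L))
    cand_lo <- cand_lo[cand_lo <= b]; cand_hi <- cand_hi[cand_hi >= a]
    for (lo in cand_lo) for (hi in cand_hi) {
      len <- hi - lo + 1L
      if (len < min_len) next
      ident <- (cmatch[hi] - cmatch[lo] + match[lo]) / len
      if (ident + 1e-12 >= min_identity) {
        out[[length(out) + 1L]] <- c(lo = lo, hi = hi, identity = ident)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(ref_start = integer(0), ref_end = integer(0),
                      identity = numeric(0), gapless = logical(0)))
  }
  w <- as.data.frame(do.call(rbind, out))
  # keep only maximal intervals (not contained in another kept interval)
  w <- w[order(w$lo, -w$hi), , drop = FALSE]
  maximal <- rep(TRUE, nrow(w))
  for (i in seq_len(nrow(w))) {
    if (any(w$lo <= w$lo[i] & w$hi >= w$hi[i] &
            (w$lo < w$lo[i] | w$hi > w$hi[i]))) maximal[i] <- FALSE
  }
  w <- w[maximal, , drop = FALSE]
  data.frame(ref_start = refpos[w$lo], ref_end = refpos[w$hi],
             identity = w$identity, gapless = TRUE)
}

default_primer_constraints <- function() {
  list(len = c(17L, 25L), tm = c(50, 65), gc = c(40, 60),
       product = c(70L, 450L), max_dtm = 5)
}

# enumerate constraint-passing primer cores inside windows of `region`
primer_candidates <- function(region, windows, constraints) {
  out <- list()
  for (i in seq_len(nrow(windows))) {
    lo <- windows$ref_start[i]; hi <- windows$ref_end[i]
    for (len in constraints$len[1]:constraints$len[2]) {
      if (hi - lo + 1L < len) next
      st <- lo:(hi - len + 1L)
      seqs <- substring(region, st, st + len - 1L)
      tm <- wallace_tm(seqs); gc <- gc_percent(seqs)
      ok <- tm >= constraints$tm[1] & tm <= constraints$tm[2] &
        gc >= constraints$gc[1] & gc <= constraints$gc[2]
      if (any(ok)) {
        out[[length(out) + 1L]] <- data.frame(
          start = st[ok], end = st[ok] + len - 1L, seq = seqs[ok],
          tm = tm[ok], gc = gc[ok], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      seq = character(0), tm = numeric(0), gc = numeric(0)))
  }
  do.call(rbind, out)
}

count_occurrences <- function(region, seq) {
  length(gregexpr(seq, region, fixed = TRUE)[[1]]) -
    (gregexpr(seq, region, fixed = TRUE)[[1]][1] == -1)
}

#' Enumerate primer pairs in conserved flanks around an SSR
#'
#' Forward candidates are taken from conserved windows upstream of the
#' repeat, reverse candidates (reverse-complemented) from windows
#' downstream. Candidates must satisfy length, Wallace Tm, GC and
#' product-size constraints, have a Tm difference within `max_dtm`, and
#' occur exactly once in the supplied region. Pairs are ranked by |dTm|,
#' then by product-size closeness to 200 bp.
#'
#' @param region DNA string (the reference region containing the SSR).
#' @param ssr one row of [find_ssrs()] output (needs `start`, `end`).
#' @param windows data.frame from [conserved_windows()] in `region`
#'   coordinates.
#' @param constraints list with `len`, `tm`, `gc`, `product` ranges and
#'   `max_dtm` (see `default_primer_constraints()`).
#' @param max_pairs cap on the number of returned pairs.
#' @return data.frame with columns `forward`, `reverse`, `tm_f`, `tm_r`,
#'   `gc_f`, `gc_r`, `f_start`, `r_end`, `product_size`, `reverse_tailed`;
#'   zero rows (not an error) when no windows flank the repeat.
#' @export
design_primer_pairs <- function(region, ssr, windows,
                                constraints = default_primer_constraints(),
                                max_pairs = 20) {
  region <- toupper(region)
  empty <- data.frame(forward = character(0), reverse = character(0),
                      tm_f = numeric(0), tm_r = numeric(0),
                      gc_f = numeric(0), gc_r = numeric(0),
                      f_start = integer(0), r_end = integer(0),
                      product_size = integer(0), reverse_tailed = logical(0))
  # windows often span the repeat itself; clip them to the two flanks
  clip <- function(w, lo, hi) {
    w$ref_start <- pmax(w$ref_start, lo)
    w$ref_end <- pmin(w$ref_end, hi)
    w[w$ref_end - w$ref_start + 1L >= constraints$len[1], , drop = FALSE]
  }
  up <- clip(windows, 1L, ssr$start - 1L)
  dn <- clip(windows, ssr$end + 1L, nchar(region))
  if (nrow(up) == 0 || nrow(dn) == 0) return(empty)
  fc <- primer_candidates(region, up, constraints)
  rc <- primer_candidates(region, dn, constraints)
  if (nrow(fc) == 0 || nrow(rc) == 0) return(empty)
  fc <- fc[vapply(fc$seq, function(s) count_occurrences(region, s) == 1,
                  logical(1)), , drop = FALSE]
  rc <- rc[vapply(rc$seq, function(s) count_occurrences(region, s) == 1,
                  logical(1)), , drop = FALSE]
  if (nrow(fc) == 0 || nrow(rc) == 0) return(empty)
  prod <- outer(fc$start, rc$end, function(f, r) r - f + 1L)
  dtm <- abs(outer(fc$tm, rc$tm, "-"))
  ok <- which(prod >= constraints$product[1] &
              prod <= constraints$product[2] &
              dtm <= constraints$max_dtm, arr.ind = TRUE)
  if (nrow(ok) == 0) return(empty)
  fi <- ok[, 1]; ri <- ok[, 2]
  pairs <- data.frame(
    forward = fc$seq[fi],
    reverse = vapply(rc$seq[ri], revcomp, character(1), USE.NAMES = FALSE),
    tm_f = fc$tm[fi], tm_r = rc$tm[ri],
    gc_f = fc$gc[fi], gc_r = rc$gc[ri],
    f_start = fc$start[fi], r_end = rc$end[ri],
    product_size = prod[ok], reverse_tailed = FALSE,
    stringsAsFactors = FALSE)
  ord <- order(abs(pairs$tm_f - pairs$tm_r),
               abs(pairs$product_size - 200L))
  pairs <- pairs[ord, , drop = FALSE]
  utils::head(pairs, max_pairs)
}

#' Add a GTTT pig-tail to reverse primers
#'
#' Prepends `GTTT` to the 5' end of the reverse primer, which promotes
#' uniform non-templated adenylation of PCR products and thus cleaner
#' fragment sizing. Tm/GC always refer to the untailed core; the
#' `reverse_tailed` flag prevents accidental double tailing.
#'
#' @param x a character vector of reverse primers, or a primer-pair
#'   data.frame from [design_primer_pairs()].
#' @return Same shape as the input, with tails added (and, for data
#'   frames, `reverse_tailed = TRUE`).
#' @export
add_pigtail <- function(x) {
  if (is.data.frame(x)) {
    if (nrow(x) && any(x$reverse_tailed)) {
      stop("reverse primers are already tailed")
    }
    x$reverse <- paste0("GTTT", x$reverse)
    x$reverse_tailed <- rep(TRUE, nrow(x))
    return(x)
  }
  if (any(!nzchar(x))) stop("empty primer sequence")
  paste0("GTTT", toupper(x))
}
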