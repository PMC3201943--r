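#' Read a Genepop-format genotype file
#'
#' Parses the classic Genepop dialect: a title line, one locus name per line
#' (or a single comma-separated line), then one or more `POP` blocks with one
#' individual per line as `id ,  g1 g2 ...`. Each diploid genotype is written
#' as two concatenated fixed-width allele codes (2 or 3 digits each); the
#' all-zero code is missing. Alleles here are microsatellite fragment sizes
#' in bp and are passed through untranslated.
#'
#' @param path path to a Genepop text file.
#' @param allele_digits 2 or 3: digits per allele code.
#' @return A [genotype_table()] with one population per `POP` block and all
#'   sexes unknown (attach them with [attach_sex_labels()]).
#' @export
read_genepop <- function(path, allele_digits = 3) {
  stopifnot(allele_digits %in% c(2, 3))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s+$", "", lines)
  if (length(lines) < 3) stop("Genepop parse error: file too short")
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("Genepop parse error: no POP line found")
  header <- lines[2:(first_pop - 1)]
  loci <- trimws(unlist(strsplit(header, ",")))
  loci <- loci[nzchar(loci)]
  if (length(loci) == 0) stop("Genepop parse error: no locus names")
  n_loci <- length(loci)

  ids <- character(); pops <- character()
  a1 <- a2 <- NULL
  rows1 <- list(); rows2 <- list()
  pop_i <- 0L
  for (k in seq(first_pop, length(lines))) {
    line <- lines[k]
    if (!nzchar(trimws(line))) next
    if (toupper(trimws(line)) == "POP") { pop_i <- pop_i + 1L; next }
    parts <- strsplit(line, ",")[[1]]
    if (length(parts) < 2) {
      stop("Genepop parse error at line ", k, ": expected 'id , genotypes'")
    }
    id <- trimws(parts[1])
    geno <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
    if (length(geno) != n_loci) {
      stop("Genepop parse error at line ", k, ": ", length(geno),
           " genotypes for ", n_loci, " loci")
    }
    w <- 2L * allele_digits
    bad <- nchar(geno) != w | grepl("\\D", geno)
    if (any(bad)) {
      stop("Genepop parse error at line ", k, ": malformed genotype '",
           geno[which(bad)[1]], "' (expected ", w, " digits)")
    }
    g1 <- as.integer(substr(geno, 1, allele_digits))
    g2 <- as.integer(substr(geno, allele_digits + 1, w))
    miss <- g1 == 0L | g2 == 0L
    g1[miss] <- NA_integer_; g2[miss] <- NA_integer_
    ids <- c(ids, id); pops <- c(pops, paste0("pop", pop_i))
    rows1[[length(rows1) + 1L]] <- g1
    rows2[[length(rows2) + 1L]] <- g2
  }
  if (length(ids) == 0) stop("Genepop parse error: no individuals")
  a1 <- do.call(rbind, rows1); a2 <- do.call(rbind, rows2)
  genotype_table(ids = ids, loci = loci, a1 = a1, a2 = a2, pop = pops)
}

#' Write a genotype table in Genepop format
#'
#' Inverse of [read_genepop()]: emits one `POP` block per population in the
#' table, 3- or 2-digit allele codes, `0...0` for missing calls.
#'
#' @param table a [genotype_table()].
#' @param path output file path.
#' @param allele_digits 2 or 3 digits per allele; allele sizes must fit.
#' @param title first line of the file.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(table, path, allele_digits = 3,
                          title = "microXY genotypes") {
  stopifnot(inherits(table, "genotype_table"), allele_digits %in% c(2, 3))
  maxa <- suppressWarnings(max(table$a2, na.rm = TRUE))
  if (is.finite(maxa) && maxa >= 10^allele_digits) {
    stop("allele size ", maxa, " does not fit in ", allele_digits, " digits")
  }
  fmt <- paste0("%0", allele_digits, "d")
  enc <- function(x) {
    out <- sprintf(fmt, x)
    out[is.na(x)] <- paste(rep("0", allele_digits), collapse = "")
    out
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(table$loci$name, con)
  for (p in unique(table$ind$pop)) {
    writeLines("POP", con)
    for (i in which(table$ind$pop == p)) {
      g <- paste0(enc(table$a1[i, ]), enc(table$a2[i, ]))
      writeLines(paste0(table$ind$id[i], " , ", paste(g, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read sex labels from a two-column TSV
#'
#' Expects a header row and columns `id` and `sex` (values `F`/`M`; anything
#' else is treated as unknown).
#'
#' @param path TSV path.
#' @return data.frame with columns `id`, `sex`.
#' @export
read_sex_labels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("id", "sex") %in% names(df))) {
    stop("sex label file must have columns 'id' and 'sex'")
  }
  df[, c("id", "sex")]
}

validate_marker_map <- function(df) {
  names(df) <- tolower(names(df))
  need <- c("name", "linkage_group", "position_bp")
  if ("locus" %in% names(df) && !"name" %in% names(df)) {
    names(df)[names(df) == "locus"] <- "name"
  }
  if (!all(need %in% names(df))) {
    stop("marker map needs columns: ", paste(need, collapse = ", "))
  }
  if (!"motif" %in% names(df)) df$motif <- NA_character_
  df <- df[, c("name", "linkage_group", "position_bp", "motif")]
  df$name <- as.character(df$name)
  df$position_bp <- as.integer(df$position_bp)
  if (any(!is.na(df$position_bp) & df$position_bp < 1)) {
    stop("position_bp must be >= 1 (1-based)")
  }
  if (anyDuplicated(df$name)) stop("duplicate locus names in marker map")
  df[order(df$linkage_group, df$position_bp), , drop = FALSE]
}

#' Read a marker map TSV
#'
#' Columns `locus` (or `name`), `linkage_group`, `position_bp` (1-based
#' physical position) and optional `motif`; rows are sorted by
#' (linkage_group, position).
#'
#' @param path TSV path with a header row.
#' @return data.frame with columns `name`, `linkage_group`, `position_bp`,
#'   `motif`.
#' @export
read_marker_map <- function(path) {
  validate_marker_map(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Attach a marker map to a genotype table
#'
#' @param table a [genotype_table()].
#' @param map data.frame from [read_marker_map()]; must cover every locus in
#'   the table.
#' @return The table with locus metadata filled in (locus order unchanged).
#' @export
attach_marker_map <- function(table, map) {
  map <- validate_marker_map(map)
  missing_loci <- setdiff(table$loci$name, map$name)
  if (length(missing_loci)) {
    stop("marker map missing loci: ", paste(missing_loci, collapse = ", "))
  }
  i <- match(table$loci$name, map$name)
  table$loci$linkage_group <- map$linkage_group[i]
  table$loci$position_bp <- map$position_bp[i]
  table$loci$motif <- map$motif[i]
  table
}

#' Mirror positions within an inverted assembly segment
#'
#' Some assembly segments are oriented opposite to the genetic map; marker
#' positions inside such a segment are corrected by reflecting them about
#' the segment midpoint. Positions outside `[seg_lo, seg_hi]` are returned
#' unchanged. The transform is its own inverse on the segment.
#'
#' @param pos integer vector of 1-based positions (bp).
#' @param seg_lo,seg_hi segment bounds (bp), `seg_lo <= seg_hi`.
#' @return Transformed positions: `seg_lo + (seg_hi - pos)` inside the
#'   segment, `pos` outside.
#' @examples
#' reverse_segment_coords(100, 50, 250)  # 200
#' @export
reverse_segment_coords <- function(pos, seg_lo, seg_hi) {
  if (seg_lo > seg_hi) stop("seg_lo must be <= seg_hi")
  inside <- !is.na(pos) & pos >= seg_lo & pos <= seg_hi
  pos[inside] <- seg_lo + (seg_hi - pos[inside])
  pos
}
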