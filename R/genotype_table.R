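#' Construct a genotype table
#'
#' The central container of the package: diploid allele-size calls for a set
#' of individuals at a set of microsatellite loci, together with sex labels
#' and optional population assignments. Alleles are fragment sizes in base
#' pairs, stored as positive integers; a call is an unordered pair, kept
#' sorted ascending, and a missing call is `NA` in both allele matrices.
#'
#' @param ids character vector of individual identifiers (unique).
#' @param loci character vector of locus names (unique), or a data.frame
#'   with columns `name`, `linkage_group`, `position_bp`, `motif` (a marker
#'   map, see [read_marker_map()]).
#' @param a1,a2 integer matrices (individuals x loci) of allele sizes in bp;
#'   `NA` in both marks a missing call. Pairs are re-sorted so `a1 <= a2`.
#' @param sex character vector of `"F"`, `"M"` or `NA` (unknown), recycled
#'   to `length(ids)`; defaults to all unknown.
#' @param pop character vector of population labels, recycled; defaults to
#'   a single population `"pop1"`.
#'
#' @return An object of class `genotype_table`: a list with elements
#'   `ind` (data.frame: `id`, `sex`, `pop`), `loci` (data.frame: `name`,
#'   `linkage_group`, `position_bp`, `motif`) and allele matrices `a1`, `a2`.
#' @examples
#' gt <- genotype_table(
#'   ids  = c("f1", "m1"),
#'   loci = "locA",
#'   a1   = matrix(c(150L, 150L), ncol = 1),
#'   a2   = matrix(c(150L, 152L), ncol = 1),
#'   sex  = c("F", "M")
#' )
#' gt
#' @export
genotype_table <- function(ids, loci, a1, a2, sex = NA_character_,
                           pop = "pop1") {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    stop("duplicate individual ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (is.data.frame(loci)) {
    loci_df <- validate_marker_map(loci)
  } else {
    loci_df <- data.frame(name = as.character(loci),
                          linkage_group = NA_character_,
                          position_bp = NA_integer_,
                          motif = NA_character_,
                          stringsAsFactors = FALSE)
  }
  if (anyDuplicated(loci_df$name)) stop("duplicate locus names")
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (!all(dim(a1) == c(length(ids), nrow(loci_df))) ||
      !all(dim(a2) == dim(a1))) {
    stop("allele matrices must be ", length(ids), " x ", nrow(loci_df))
  }
  if (any(xor(is.na(a1), is.na(a2)))) {
    stop("half-missing calls: a1 and a2 must be NA together")
  }
  if (any(a1 <= 0L, na.rm = TRUE) || any(a2 <= 0L, na.rm = TRUE)) {
    stop("allele sizes must be positive")
  }
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  dimnames(a1) <- dimnames(a2) <- list(ids, loci_df$name)
  sex <- toupper(as.character(rep_len(sex, length(ids))))
  sex[!sex %in% c("F", "M")] <- NA_character_
  obj <- list(
    ind = data.frame(id = ids, sex = sex,
                     pop = as.character(rep_len(pop, length(ids))),
                     stringsAsFactors = FALSE),
    loci = loci_df, a1 = a1, a2 = a2
  )
  class(obj) <- "genotype_table"
  obj
}

#' @export
print.genotype_table <- function(x, ...) {
  ns <- table(factor(x$ind$sex, levels = c("F", "M")), useNA = "always")
  cat("genotype_table: ", nrow(x$ind), " individuals (",
      ns[["F"]], " F, ", ns[["M"]], " M, ",
      sum(is.na(x$ind$sex)), " unknown) x ",
      nrow(x$loci), " loci\n", sep = "")
  miss <- mean(is.na(x$a1))
  cat(sprintf("missing calls: %.1f%%; populations: %s\n", 100 * miss,
              paste(unique(x$ind$pop), collapse = ", ")))
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) c(nrow(x$ind), nrow(x$loci))

# index of a locus by name, with a useful error
locus_index <- function(table, locus) {
  i <- match(locus, table$loci$name)
  if (is.na(i)) stop("unknown locus: ", locus)
  i
}

# row indices for a sex filter: "ALL" (any sex incl. unknown), "F", "M",
# or "FM" (known sex only)
group_rows <- function(table, group = c("ALL", "F", "M", "FM")) {
  group <- toupper(group[1])
  if (group %in% c("FEMALES", "FEMALE")) group <- "F"
  if (group %in% c("MALES", "MALE")) group <- "M"
  switch(group,
    ALL = seq_len(nrow(table$ind)),
    F   = which(table$ind$sex %in% "F"),
    M   = which(table$ind$sex %in% "M"),
    FM  = which(table$ind$sex %in% c("F", "M")),
    stop("unknown group filter: ", group)
  )
}

# allele pairs at one locus for chosen rows, dropping missing calls;
# returns list(a1, a2, rows) over typed individuals only
typed_calls <- function(table, locus, rows = seq_len(nrow(table$ind))) {
  j <- locus_index(table, locus)
  a1 <- table$a1[rows, j]; a2 <- table$a2[rows, j]
  keep <- !is.na(a1)
  list(a1 = a1[keep], a2 = a2[keep], rows = rows[keep])
}

#' Attach sex labels to a genotype table
#'
#' Sexes are supplied separately from genotypes (the Genepop format has no
#' sex field). Unlabelled individuals stay unknown and are excluded from all
#' sex-stratified statistics. Genotype calls are never modified.
#'
#' @param table a [genotype_table()].
#' @param labels named character vector or two-column data.frame
#'   (`id`, `sex`) mapping individual ids to `"F"`/`"M"`.
#' @return The table with sexes set.
#' @seealso [read_sex_labels()]
#' @export
attach_sex_labels <- function(table, labels) {
  stopifnot(inherits(table, "genotype_table"))
  if (is.data.frame(labels)) {
    labels <- stats::setNames(as.character(labels[[2]]),
                              as.character(labels[[1]]))
  }
  if (length(labels) == 0) return(table)
  ids <- names(labels)
  dup <- unique(ids[duplicated(ids)])
  for (d in dup) {
    if (length(unique(toupper(labels[ids == d]))) > 1) {
      stop("conflicting sex labels for id: ", d)
    }
  }
  labels <- labels[!duplicated(ids)]
  ids <- names(labels)
  missing_ids <- setdiff(ids, table$ind$id)
  if (length(missing_ids)) {
    stop("sex labels for unknown individual(s): ",
         paste(missing_ids, collapse = ", "))
  }
  sex <- toupper(as.character(labels))
  bad <- !sex %in% c("F", "M", "U", "UNKNOWN", "NA")
  if (any(bad)) stop("invalid sex code(s): ",
                     paste(unique(sex[bad]), collapse = ", "))
  sex[!sex %in% c("F", "M")] <- NA_character_
  table$ind$sex[match(ids, table$ind$id)] <- sex
  table
}
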