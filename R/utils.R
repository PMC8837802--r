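# Shared representation: a count table is a tibble whose first column is
# `sample_id` and whose remaining columns are taxa holding non-negative
# integer read counts. Helpers below convert to/from the matrix form used
# by vegan/picante and enforce the table contract everywhere.

#' Convert a count tibble to a sample-by-taxon matrix
#'
#' @param counts A count tibble (`sample_id` first column, taxon count
#'   columns).
#' @return Numeric matrix with sample ids as row names and taxon ids as
#'   column names.
#' @export
as_count_matrix <- function(counts) {
  counts <- validate_counts(counts)
  m <- as.matrix(counts[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- counts$sample_id
  m
}

#' Convert a sample-by-taxon matrix to a count tibble
#'
#' @param m Numeric matrix with sample row names and taxon column names.
#' @return A count tibble.
#' @export
as_count_tbl <- function(m) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  out <- as_tibble(m, rownames = "sample_id")
  out
}

#' Validate a count tibble
#'
#' Enforces the count-table contract: unique sample and taxon ids, integer
#' non-negative cells, and at least two samples and two taxa.
#'
#' @param counts A data frame; first column sample ids, rest counts.
#' @param arg Name used in error messages.
#' @return The validated table as a tibble (invisibly usable in pipes).
#' @export
validate_counts <- function(counts, arg = "counts") {
  if (!is.data.frame(counts)) {
    abort(sprintf("`%s` must be a data frame with a sample_id first column.", arg))
  }
  counts <- as_tibble(counts)
  if (names(counts)[1] != "sample_id") {
    names(counts)[1] <- "sample_id"
  }
  ids <- as.character(counts$sample_id)
  if (anyDuplicated(ids)) {
    abort(sprintf("`%s`: duplicated sample ids: %s", arg,
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  taxa <- names(counts)[-1]
  if (anyDuplicated(taxa)) {
    abort(sprintf("`%s`: duplicated taxon ids.", arg))
  }
  if (nrow(counts) < 2 || length(taxa) < 2) {
    abort(sprintf("`%s` needs at least 2 samples and 2 taxa.", arg))
  }
  vals <- as.matrix(counts[, -1, drop = FALSE])
  if (!is.numeric(vals)) abort(sprintf("`%s`: counts must be numeric.", arg))
  if (anyNA(vals)) abort(sprintf("`%s`: missing values are not allowed.", arg))
  if (any(vals < 0)) {
    bad <- ids[which(rowSums(vals < 0) > 0)[1]]
    abort(sprintf("`%s`: negative count in sample '%s'.", arg, bad))
  }
  if (any(vals != round(vals))) {
    bad <- ids[which(rowSums(vals != round(vals)) > 0)[1]]
    abort(sprintf("`%s`: non-integer count in sample '%s'.", arg, bad))
  }
  counts$sample_id <- ids
  counts
}

#' Validate a sample metadata tibble
#'
#' Requires `sample_id`, `study_id` and `compartment` columns; the
#' compartment must be exactly "rhizosphere" or "bulk". When a count table
#' is supplied, every metadata sample must appear in it.
#'
#' @param metadata Data frame of per-sample metadata.
#' @param counts Optional companion count tibble for cross-checking.
#' @return The validated metadata tibble.
#' @export
validate_metadata <- function(metadata, counts = NULL) {
  if (!is.data.frame(metadata)) abort("`metadata` must be a data frame.")
  metadata <- as_tibble(metadata)
  need <- c("sample_id", "study_id", "compartment")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) {
    abort(sprintf("`metadata` is missing column(s): %s", paste(miss, collapse = ", ")))
  }
  bad <- setdiff(unique(metadata$compartment), c("rhizosphere", "bulk"))
  if (length(bad)) {
    row1 <- which(metadata$compartment %in% bad)[1]
    abort(sprintf(
      "`metadata`: unknown compartment label '%s' (row %d); expected 'rhizosphere' or 'bulk'.",
      metadata$compartment[row1], row1))
  }
  if (anyDuplicated(metadata$sample_id)) abort("`metadata`: duplicated sample ids.")
  if (!is.null(counts)) {
    counts <- validate_counts(counts)
    miss_s <- setdiff(metadata$sample_id, counts$sample_id)
    if (length(miss_s)) {
      abort(sprintf("`metadata`: sample(s) absent from counts: %s",
                    paste(head(miss_s, 5), collapse = ", ")))
    }
  }
  metadata
}

# Row-normalise a count matrix to relative abundances.
rel_abund_matrix <- function(m) {
  rs <- rowSums(m)
  if (any(rs == 0)) {
    abort(sprintf("all-zero sample(s): %s",
                  paste(head(rownames(m)[rs == 0], 5), collapse = ", ")))
  }
  sweep(m, 1, rs, "/")
}

# Deterministic sub-seed derivation: keeps every stage independently
# reproducible from one user-facing seed (kept below 2^31).
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1000003L * as.integer(offset)) %% 2147483647L
}

log_msg <- function(...) inform(sprintf(...))
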