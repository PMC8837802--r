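# Readers and writers for the plain-text interchange formats shared by the
# whole pipeline. Everything is TSV (UTF-8, '#' comments) except the
# phylogeny (newick) and ground truth (JSON).

TAXONOMIC_RANKS <- c("Kingdom", "Phylum", "Class", "Order", "Family",
                     "Genus", "Species")

#' Read an ASV/taxon count table from TSV
#'
#' Expects a header row of taxon ids, a first column of sample ids, and
#' non-negative integer cells.
#'
#' @param path Path to a tab-separated file.
#' @return A validated count tibble.
#' @export
read_count_table <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  validate_counts(tbl, arg = path)
}

#' Write a count table to TSV
#' @param counts Count tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  readr::write_tsv(validate_counts(counts), path, progress = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' @param path Path to a tab-separated file with at least `sample_id`,
#'   `study_id` and `compartment` columns.
#' @return A validated metadata tibble.
#' @export
read_metadata <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  validate_metadata(tbl)
}

#' Write sample metadata to TSV
#' @param metadata Metadata tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  readr::write_tsv(validate_metadata(metadata), path, progress = FALSE)
  invisible(path)
}

#' Read a 7-rank taxonomy table from TSV
#'
#' @param path TSV with a `taxon_id` column followed by rank columns
#'   Kingdom through Genus (Species optional). Unassigned ranks are empty.
#' @return A taxonomy tibble.
#' @export
read_taxonomy <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  validate_taxonomy(tbl)
}

#' Validate a taxonomy tibble
#' @param taxonomy Data frame with `taxon_id` and rank columns.
#' @return The validated tibble.
#' @export
validate_taxonomy <- function(taxonomy) {
  taxonomy <- as_tibble(taxonomy)
  if (names(taxonomy)[1] != "taxon_id") names(taxonomy)[1] <- "taxon_id"
  need <- TAXONOMIC_RANKS[1:6]
  miss <- setdiff(need, names(taxonomy))
  if (length(miss)) {
    abort(sprintf("taxonomy is missing rank column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(taxonomy$taxon_id)) abort("taxonomy: duplicated taxon ids.")
  taxonomy
}

#' Write a taxonomy table to TSV
#' @param taxonomy Taxonomy tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  readr::write_tsv(validate_taxonomy(taxonomy), path, progress = FALSE)
  invisible(path)
}

#' Read a rooted phylogeny (newick)
#'
#' @param path Newick file; branch lengths required, tip labels are taxon
#'   ids.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_tree <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) abort(sprintf("malformed newick in '%s': %s",
                                                     path, conditionMessage(e))))
  if (is.null(tree)) abort(sprintf("malformed newick in '%s'.", path))
  if (is.null(tree$edge.length)) abort("tree has no branch lengths.")
  if (any(tree$edge.length < 0)) abort("tree has negative branch lengths.")
  if (anyDuplicated(tree$tip.label)) abort("tree tip labels are not unique.")
  tree
}

#' Write a phylogeny to newick
#' @param tree `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a per-taxon trait table from TSV
#'
#' Columns: `taxon_id`, `operon_copies` (rRNA operon copies per genome,
#' >= 1), `toxin_antitoxin_genes`, `sporulation_genes` (counts per genome),
#' `nsti` (nearest sequenced taxon index, >= 0).
#'
#' @param path TSV path.
#' @return A trait tibble.
#' @export
read_traits <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  validate_traits(tbl)
}

#' Validate a trait tibble
#' @param traits Data frame of per-taxon traits.
#' @return The validated tibble.
#' @export
validate_traits <- function(traits) {
  traits <- as_tibble(traits)
  need <- c("taxon_id", "operon_copies", "toxin_antitoxin_genes",
            "sporulation_genes", "nsti")
  miss <- setdiff(need, names(traits))
  if (length(miss)) {
    abort(sprintf("traits table missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(traits$taxon_id)) abort("traits: duplicated taxon ids.")
  if (any(traits$operon_copies < 1)) abort("traits: operon_copies must be >= 1.")
  if (any(traits$nsti < 0)) abort("traits: nsti must be >= 0.")
  if (any(traits$toxin_antitoxin_genes < 0) || any(traits$sporulation_genes < 0)) {
    abort("traits: gene counts must be non-negative.")
  }
  traits
}

#' Write a trait table to TSV
#' @param traits Trait tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_traits <- function(traits, path) {
  readr::write_tsv(validate_traits(traits), path, progress = FALSE)
  invisible(path)
}

#' Read a taxonomy-rule function map
#'
#' Plain-text format, one function per stanza: a header line
#' `function_name:` followed by one rule per line, `Rank:value` for
#' inclusion and `-Rank:value` for exclusion. `#` comments and blank lines
#' are ignored. Ranks must be one of Kingdom...Species. A taxon matches a
#' function when any inclusion rule matches its lineage and no exclusion
#' rule does.
#'
#' @param path Path to the map file.
#' @return A `function_map`: named list of tibbles with columns `rank`,
#'   `value`, `exclude`.
#' @export
read_function_map <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  parse_function_map(lines)
}

#' Parse function-map text lines
#' @param lines Character vector in the format of [read_function_map()].
#' @return A `function_map` object.
#' @export
parse_function_map <- function(lines) {
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  map <- list()
  current <- NULL
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl(":\\s*$", ln)) {
      current <- sub(":\\s*$", "", ln)
      if (current %in% names(map)) {
        abort(sprintf("function map: duplicate function name '%s'.", current))
      }
      map[[current]] <- tibble(rank = character(), value = character(),
                               exclude = logical())
    } else {
      if (is.null(current)) abort(sprintf("function map: rule before any function header: '%s'", ln))
      excl <- startsWith(ln, "-")
      rule <- sub("^-", "", ln)
      parts <- strsplit(rule, ":", fixed = TRUE)[[1]]
      if (length(parts) != 2) abort(sprintf("function map: malformed rule '%s'.", ln))
      rank <- trimws(parts[1]); value <- trimws(parts[2])
      if (!rank %in% TAXONOMIC_RANKS) {
        abort(sprintf("function map: unknown rank '%s' in rule '%s'.", rank, ln))
      }
      map[[current]] <- bind_rows(map[[current]],
                                  tibble(rank = rank, value = value, exclude = excl))
    }
  }
  structure(map, class = "function_map")
}

#' Write a function map to its text format
#' @param map A `function_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_function_map <- function(map, path) {
  out <- character()
  for (fn in names(map)) {
    rules <- map[[fn]]
    out <- c(out, paste0(fn, ":"),
             paste0(ifelse(rules$exclude, "-", ""), rules$rank, ":", rules$value),
             "")
  }
  readr::write_lines(out, path)
  invisible(path)
}

#' Cross-validate a data bundle
#'
#' Reports taxa present in the count table but missing from the taxonomy,
#' tree or trait table, as warnings; nothing is dropped.
#'
#' @param counts Count tibble.
#' @param taxonomy Optional taxonomy tibble.
#' @param tree Optional `phylo`.
#' @param traits Optional trait tibble.
#' @return A named list of character vectors of missing taxon ids.
#' @export
cross_validate_bundle <- function(counts, taxonomy = NULL, tree = NULL,
                                  traits = NULL) {
  taxa <- names(validate_counts(counts))[-1]
  out <- list()
  if (!is.null(taxonomy)) {
    out$missing_in_taxonomy <- setdiff(taxa, taxonomy$taxon_id)
  }
  if (!is.null(tree)) {
    out$missing_in_tree <- setdiff(taxa, tree$tip.label)
  }
  if (!is.null(traits)) {
    out$missing_in_traits <- setdiff(taxa, traits$taxon_id)
  }
  for (nm in names(out)) {
    if (length(out[[nm]])) {
      warn(sprintf("%s: %s", nm, paste(head(out[[nm]], 10), collapse = ", ")))
    }
  }
  invisible(out)
}
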