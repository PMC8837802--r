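# Community-weighted trait and function aggregation: NSTI quality
# filtering, weighted mean rRNA operon copy number (heterotrophic
# strategy), dormancy-system gene abundances (toxin-antitoxin,
# sporulation), and taxonomy-rule function abundances. All outputs depend
# only on relative abundances.

#' Remove taxa with poor prediction quality (NSTI filter)
#'
#' Taxa whose nearest-sequenced-taxon index exceeds `cutoff` are removed
#' (strict inequality: nsti exactly at the cutoff is retained). Taxa absent
#' from the trait table are excluded with a warning.
#'
#' @param counts Count tibble.
#' @param traits Trait tibble with an `nsti` column.
#' @param cutoff NSTI cutoff (default 2).
#' @param quiet Suppress the removal message.
#' @return The filtered count tibble.
#' @export
nsti_filter <- function(counts, traits, cutoff = 2.0, quiet = FALSE) {
  if (cutoff < 0) abort("`cutoff` must be >= 0.")
  traits <- validate_traits(traits)
  m <- as_count_matrix(counts)
  taxa <- colnames(m)
  missing <- setdiff(taxa, traits$taxon_id)
  if (length(missing)) {
    warn(sprintf("nsti_filter: %d taxa lack trait entries and are excluded: %s",
                 length(missing), paste(head(missing, 5), collapse = ", ")))
  }
  nsti <- traits$nsti[match(taxa, traits$taxon_id)]
  keep <- !is.na(nsti) & nsti <= cutoff
  if (sum(keep) < 2) abort("fewer than 2 taxa survive the NSTI filter.")
  if (!quiet && any(!keep)) {
    log_msg("nsti_filter: removed %d of %d taxa (%.2f%%).",
            sum(!keep), length(keep), 100 * mean(!keep))
  }
  as_count_tbl(m[, keep, drop = FALSE])
}

# Relative abundances, optionally corrected by 16S copy number (divide
# reads by operon copies, then renormalise) before trait weighting.
trait_rel_abund <- function(m, traits, copy_correct) {
  if (copy_correct) {
    cc <- traits$operon_copies[match(colnames(m), traits$taxon_id)]
    m <- sweep(m, 2, cc, "/")
  }
  rel_abund_matrix(m)
}

#' Community-weighted mean rRNA operon copy number
#'
#' sum_i p_i * c_i with p_i the relative abundance and c_i the per-genome
#' operon copy count: a proxy for the community's heterotrophic
#' (copiotroph vs oligotroph) strategy. By default abundances are NOT
#' corrected by 16S copy number here, since the trait itself is the copy
#' number (the correction would be partially self-referential); switchable.
#'
#' @param counts NSTI-filtered count tibble.
#' @param traits Trait tibble covering the count taxa.
#' @param copy_correct Correct abundances by operon copies first
#'   (default FALSE).
#' @return A tibble: sample_id, weighted_operon.
#' @export
weighted_mean_operon <- function(counts, traits, copy_correct = FALSE) {
  traits <- validate_traits(traits)
  m <- as_count_matrix(counts)
  miss <- setdiff(colnames(m), traits$taxon_id)
  if (length(miss)) abort(sprintf("taxa without traits: %s",
                                  paste(head(miss, 5), collapse = ", ")))
  p <- trait_rel_abund(m, traits, copy_correct)
  cc <- traits$operon_copies[match(colnames(m), traits$taxon_id)]
  tibble(sample_id = rownames(m),
         weighted_operon = as.numeric(p %*% cc))
}

#' Community-weighted dormancy gene abundance
#'
#' sum_i p_i * g_i with g_i the per-genome gene count of the chosen
#' dormancy system (toxin-antitoxin or sporulation). Abundances are
#' corrected by 16S copy number by default (switchable).
#'
#' @param counts NSTI-filtered count tibble.
#' @param traits Trait tibble covering the count taxa.
#' @param system "toxin_antitoxin" or "sporulation".
#' @param copy_correct Correct abundances by operon copies (default TRUE).
#' @return A tibble: sample_id, abundance (genes per genome, community
#'   weighted), system.
#' @export
dormancy_abundance <- function(counts, traits,
                               system = c("toxin_antitoxin", "sporulation"),
                               copy_correct = TRUE) {
  system <- match.arg(system)
  traits <- validate_traits(traits)
  m <- as_count_matrix(counts)
  miss <- setdiff(colnames(m), traits$taxon_id)
  if (length(miss)) abort(sprintf("taxa without traits: %s",
                                  paste(head(miss, 5), collapse = ", ")))
  gene_col <- switch(system, toxin_antitoxin = "toxin_antitoxin_genes",
                     sporulation = "sporulation_genes")
  g <- traits[[gene_col]][match(colnames(m), traits$taxon_id)]
  p <- trait_rel_abund(m, traits, copy_correct)
  tibble(sample_id = rownames(m), abundance = as.numeric(p %*% g),
         system = system)
}

# TRUE for taxa whose lineage matches >= 1 inclusion rule and no exclusion
# rule of `rules` (tibble rank/value/exclude).
match_function_rules <- function(taxonomy, rules) {
  lineage <- taxonomy
  hit_one <- function(rk, val) {
    if (!rk %in% names(lineage)) {
      abort(sprintf("function map rule names unknown rank '%s'.", rk))
    }
    lineage[[rk]] == val & !is.na(lineage[[rk]])
  }
  inc <- rules[!rules$exclude, , drop = FALSE]
  exc <- rules[rules$exclude, , drop = FALSE]
  included <- rep(FALSE, nrow(lineage))
  for (j in seq_len(nrow(inc))) {
    included <- included | hit_one(inc$rank[j], inc$value[j])
  }
  for (j in seq_len(nrow(exc))) {
    included <- included & !hit_one(exc$rank[j], exc$value[j])
  }
  included
}

#' Rule-based community function abundances
#'
#' A taxon carries a function when any of the function's inclusion rules
#' matches its lineage and no exclusion rule does; the function's abundance
#' in a sample is the summed relative abundance of matching taxa (taxa may
#' match several functions). Abundances are corrected by 16S copy number by
#' default.
#'
#' @param counts Count tibble.
#' @param taxonomy Taxonomy tibble covering the count taxa.
#' @param map A `function_map` (see [read_function_map()]).
#' @param traits Optional trait tibble enabling copy-number correction.
#' @param copy_correct Correct abundances by operon copies when traits are
#'   supplied (default TRUE).
#' @return A tibble: sample_id, one column per function, values in [0, 1].
#' @export
function_abundance <- function(counts, taxonomy, map, traits = NULL,
                               copy_correct = TRUE) {
  taxonomy <- validate_taxonomy(taxonomy)
  m <- as_count_matrix(counts)
  miss <- setdiff(colnames(m), taxonomy$taxon_id)
  if (length(miss)) abort(sprintf("taxa without taxonomy: %s",
                                  paste(head(miss, 5), collapse = ", ")))
  p <- if (!is.null(traits) && copy_correct) {
    trait_rel_abund(m, validate_traits(traits), TRUE)
  } else {
    rel_abund_matrix(m)
  }
  lineage <- taxonomy[match(colnames(m), taxonomy$taxon_id), , drop = FALSE]
  out <- tibble(sample_id = rownames(m))
  for (fn in names(map)) {
    hits <- match_function_rules(lineage, map[[fn]])
    out[[fn]] <- as.numeric(rowSums(p[, hits, drop = FALSE]))
  }
  out
}

#' All community trait/function variables in one table
#'
#' Convenience wrapper combining [weighted_mean_operon()],
#' [dormancy_abundance()] for both systems, and (optionally)
#' [function_abundance()].
#'
#' @param counts NSTI-filtered count tibble.
#' @param traits Trait tibble.
#' @param taxonomy,map Optional; when both are given, per-function columns
#'   are appended.
#' @return A tibble keyed by sample_id.
#' @export
community_traits <- function(counts, traits, taxonomy = NULL, map = NULL) {
  out <- weighted_mean_operon(counts, traits)
  ta <- dormancy_abundance(counts, traits, "toxin_antitoxin")
  sp <- dormancy_abundance(counts, traits, "sporulation")
  out$toxin_antitoxin <- ta$abundance[match(out$sample_id, ta$sample_id)]
  out$sporulation <- sp$abundance[match(out$sample_id, sp$sample_id)]
  if (!is.null(taxonomy) && !is.null(map)) {
    fa <- function_abundance(counts, taxonomy, map, traits = traits)
    out <- left_join(out, fa, by = "sample_id")
  }
  out
}
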