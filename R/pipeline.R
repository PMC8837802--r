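# End-to-end convenience: per-sample diversity + community trait variables,
# study-level effect records, and pooled random-effects summaries.

#' Run the paired rhizosphere/bulk pipeline
#'
#' Rarefies the counts, computes per-sample alpha diversity (with Faith PD
#' when a tree is given) and community-weighted traits (operon copy
#' number, dormancy gene systems, and rule-based functions when a map is
#' given), summarises each study into lnRR effect records, and pools them
#' with the random-effects model.
#'
#' @param counts Count tibble.
#' @param metadata Metadata tibble (sample_id, study_id, compartment).
#' @param tree Optional rooted `phylo` for Faith PD.
#' @param traits Optional trait tibble; enables NSTI filtering and trait
#'   variables.
#' @param taxonomy,function_map Optional; enable per-function variables.
#' @param depth Rarefaction depth (default 10000).
#' @param nsti_cutoff NSTI filter cutoff (default 2).
#' @param n_boot Bootstrap iterations for the pooled CIs (default 999).
#' @param seed Integer seed for rarefaction and bootstrap.
#' @return A list of class `rhizo_pipeline`: `alpha`, `community`
#'   (per-sample trait/function variables), `records` (effect records),
#'   `pooled` (a `meta_pool` tibble).
#' @export
run_pipeline <- function(counts, metadata, tree = NULL, traits = NULL,
                         taxonomy = NULL, function_map = NULL,
                         depth = 10000, nsti_cutoff = 2,
                         n_boot = 999, seed = 1L) {
  metadata <- validate_metadata(metadata, counts)
  rare <- rarefy_counts(counts, depth = depth, seed = derive_seed(seed, 1L))
  alpha <- alpha_diversity(rare, tree = tree)
  per_sample <- alpha
  community <- NULL
  if (!is.null(traits)) {
    filtered <- nsti_filter(rare, traits, cutoff = nsti_cutoff)
    community <- community_traits(filtered, traits,
                                  taxonomy = taxonomy, map = function_map)
    per_sample <- left_join(alpha, community, by = "sample_id")
  }
  records <- effects_from_samples(per_sample, metadata)
  # a variable can lose studies (e.g. a function absent from a compartment
  # makes the log-ratio undefined there); pooling needs at least 2
  k_per_var <- table(records$variable)
  too_few <- names(k_per_var)[k_per_var < 2]
  if (length(too_few)) {
    log_msg("run_pipeline: dropping variable(s) with < 2 usable studies: %s",
            paste(too_few, collapse = ", "))
    records <- records[!records$variable %in% too_few, ]
  }
  pooled <- pool_effects(records, n_boot = n_boot,
                         seed = derive_seed(seed, 2L))
  structure(list(alpha = alpha, community = community,
                 records = records, pooled = pooled),
            class = "rhizo_pipeline")
}
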