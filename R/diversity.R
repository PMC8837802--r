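# Per-sample diversity variables: rarefaction, alpha indices, Faith PD,
# Bray-Curtis/PCoA and PERMANOVA. These are the variables later summarised
# per study and fed to the meta-analysis.

#' Rarefy a count table to a fixed depth
#'
#' Each sample is subsampled without replacement to exactly `depth` reads in
#' a single seed-controlled draw. Samples whose total is below `depth` are
#' dropped and reported.
#'
#' @param counts Count tibble.
#' @param depth Target depth (reads per sample); default 10000.
#' @param seed Integer seed for the subsampling draw.
#' @param quiet Suppress the dropped-sample message.
#' @return A rarefied count tibble (possibly with fewer samples).
#' @export
rarefy_counts <- function(counts, depth = 10000, seed = 1L, quiet = FALSE) {
  if (depth <= 0) abort("`depth` must be a positive integer.")
  m <- as_count_matrix(counts)
  totals <- rowSums(m)
  keep <- totals >= depth
  if (!any(keep)) abort("no sample reaches the rarefaction depth.")
  if (any(!keep) && !quiet) {
    log_msg("rarefy_counts: dropped %d of %d samples below depth %d (%s)",
            sum(!keep), length(keep), depth,
            paste(head(rownames(m)[!keep], 5), collapse = ", "))
  }
  m <- m[keep, , drop = FALSE]
  exact <- rowSums(m) == depth
  set.seed(seed)
  if (any(!exact)) {
    # rrarefy's "observed counts" heuristic misfires on high-depth tables
    m[!exact, ] <- suppressWarnings(
      vegan::rrarefy(m[!exact, , drop = FALSE], depth))
  }
  if (nrow(m) < 2) abort("fewer than 2 samples survive rarefaction.")
  as_count_tbl(m)
}

#' Alpha diversity per sample
#'
#' Observed richness, Shannon entropy (natural log), Pielou evenness
#' J = H / ln(richness) (undefined at richness <= 1), and — when a tree is
#' supplied — Faith phylogenetic diversity, the total branch length of the
#' minimal subtree spanning the observed tips (including the path to the
#' root by default).
#'
#' @param counts Count tibble (normally rarefied).
#' @param tree Optional rooted `phylo` whose tips cover all taxa with
#'   nonzero counts.
#' @param include_root Include the root path in Faith PD (default TRUE).
#' @return A tibble: sample_id, richness, shannon, pielou, and `faith_pd`
#'   when a tree is given.
#' @export
alpha_diversity <- function(counts, tree = NULL, include_root = TRUE) {
  m <- as_count_matrix(counts)
  p <- rel_abund_matrix(m)
  richness <- rowSums(m > 0)
  H <- vegan::diversity(m, index = "shannon", base = exp(1))
  out <- tibble(sample_id = rownames(m),
                richness = as.numeric(richness),
                shannon = as.numeric(H),
                pielou = ifelse(richness > 1, H / log(richness), NA_real_))
  if (!is.null(tree)) {
    observed <- colnames(m)[colSums(m) > 0]
    missing <- setdiff(observed, tree$tip.label)
    if (length(missing)) {
      abort(sprintf("taxa absent from the tree: %s",
                    paste(head(missing, 5), collapse = ", ")))
    }
    pdt <- picante::pd(m, tree, include.root = include_root)
    out$faith_pd <- pdt$PD[match(out$sample_id, rownames(pdt))]
  }
  out
}

#' Bray-Curtis dissimilarity
#'
#' d(a, b) = sum |a_i - b_i| / sum (a_i + b_i) on the counts.
#'
#' @param counts Count tibble with at least 2 samples; all-zero samples are
#'   an error.
#' @return A `dist` object labelled by sample ids.
#' @export
bray_curtis <- function(counts) {
  m <- as_count_matrix(counts)
  rel_abund_matrix(m)  # errors on all-zero samples
  vegan::vegdist(m, method = "bray")
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centres the squared dissimilarity matrix and eigen-decomposes it.
#' Negative eigenvalues are reported as-is, never corrected; the proportion
#' explained is computed over the positive eigenvalues.
#'
#' @param d A `dist` (e.g. from [bray_curtis()]).
#' @param k Number of axes to return (default 2); truncated with a warning
#'   when it exceeds the available rank.
#' @return A list of class `rhizo_pcoa`: `coordinates` (tibble, sample_id +
#'   axes), `eigenvalues`, `prop_explained`.
#' @export
pcoa_ordination <- function(d, k = 2) {
  if (k < 1) abort("`k` must be >= 1.")
  n <- attr(d, "Size")
  ids <- attr(d, "Labels") %||% as.character(seq_len(n))
  kk <- min(k, n - 1)
  if (kk < k) warn(sprintf("k truncated from %d to %d (n - 1).", k, kk))
  sc <- suppressWarnings(cmdscale(d, k = kk, eig = TRUE))
  pts <- sc$points
  if (ncol(pts) < kk) {
    warn(sprintf("only %d non-degenerate axes available; k truncated.", ncol(pts)))
  }
  eig <- sc$eig
  pos <- sum(eig[eig > 0])
  coords <- as_tibble(pts, .name_repair = ~ paste0("axis", seq_along(.x)))
  coords <- bind_cols(tibble(sample_id = ids), coords)
  structure(list(coordinates = coords, eigenvalues = eig,
                 prop_explained = ifelse(eig > 0, eig / pos, 0)),
            class = "rhizo_pcoa")
}

#' PERMANOVA on a dissimilarity matrix
#'
#' Anderson's pseudo-F from the within/between sum-of-squares partition of
#' the distance matrix, with a permutation p-value
#' p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm). When `strata` is given
#' (e.g. study id in a multi-study design) permutations are restricted
#' within strata.
#'
#' @param d A `dist`.
#' @param groups Group label per sample (>= 2 groups, each >= 2 samples).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @param strata Optional blocking factor restricting permutations.
#' @return A one-row tibble: `pseudo_f`, `r2`, `p_value`, `n_perm`.
#' @export
permanova_test <- function(d, groups, n_perm = 999, seed = 1L, strata = NULL) {
  n <- attr(d, "Size")
  groups <- as.factor(groups)
  if (length(groups) != n) abort("`groups` length must match the matrix.")
  tab <- table(groups)
  if (length(tab) < 2) abort("need at least 2 groups.")
  if (any(tab < 2)) {
    abort(sprintf("group '%s' has fewer than 2 samples.",
                  names(tab)[which(tab < 2)[1]]))
  }
  df <- data.frame(group = groups)
  set.seed(seed)
  fit <- vegan::adonis2(d ~ group, data = df, permutations = n_perm,
                        strata = strata)
  tibble(pseudo_f = fit$F[1], r2 = fit$R2[1],
         p_value = fit$`Pr(>F)`[1], n_perm = n_perm)
}
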