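# Compositional differential abundance between compartments: centred
# log-ratio transforms of Dirichlet Monte-Carlo instances, per-instance
# rank-sum tests averaged across instances, Benjamini-Hochberg correction,
# and a standardized effect size (median cross-group difference scaled by
# the maximum within-group dispersion).

#' Centred log-ratio transform
#'
#' clr_i = ln(x_i) - mean_j ln(x_j). Rows of a matrix are transformed
#' independently.
#'
#' @param x Strictly positive numeric vector or matrix (rows =
#'   compositions).
#' @return Same shape as `x`; each composition sums to 0.
#' @export
clr_transform <- function(x) {
  if (any(x <= 0)) abort("clr_transform: all entries must be strictly positive.")
  if (is.matrix(x)) {
    lx <- log(x)
    lx - rowMeans(lx)
  } else {
    lx <- log(x)
    lx - mean(lx)
  }
}

#' Dirichlet Monte-Carlo CLR instances of a count table
#'
#' For every sample, draws `n_mc` compositions from
#' Dirichlet(counts + prior) and CLR-transforms each; the prior resolves
#' zero counts.
#'
#' @param counts Count tibble.
#' @param n_mc Number of Monte-Carlo instances (default 128).
#' @param seed Integer seed.
#' @param prior Per-taxon Dirichlet prior (default 0.5).
#' @return A 3-d array (sample x taxon x instance) of CLR values, class
#'   `clr_instances`.
#' @export
dirichlet_instances <- function(counts, n_mc = 128, seed = 1L, prior = 0.5) {
  if (n_mc < 1) abort("`n_mc` must be >= 1.")
  m <- as_count_matrix(counts)
  n_s <- nrow(m); n_t <- ncol(m)
  out <- array(NA_real_, dim = c(n_s, n_t, n_mc),
               dimnames = list(rownames(m), colnames(m), NULL))
  set.seed(seed)
  for (s in seq_len(n_s)) {
    shape <- m[s, ] + prior
    g <- matrix(stats::rgamma(n_mc * n_t, shape = rep(shape, each = n_mc)),
                nrow = n_mc, ncol = n_t)
    # CLR is invariant to the Dirichlet normalisation, so log the gammas
    lg <- log(g)
    out[s, , ] <- t(lg - rowMeans(lg))
  }
  structure(out, class = c("clr_instances", "array"))
}

# Vectorised two-sided Wilcoxon rank-sum p-values (normal approximation
# with tie correction and continuity correction, as stats::wilcox.test
# with exact = FALSE). `x` is samples x taxa; idx1/idx2 index the groups.
rank_sum_p <- function(x, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  sub <- x[c(idx1, idx2), , drop = FALSE]
  r <- apply(sub, 2, rank)
  w <- colSums(r[seq_len(n1), , drop = FALSE]) - n1 * (n1 + 1) / 2
  nt <- n1 + n2
  tie_term <- apply(r, 2, function(col) {
    tt <- table(col)
    sum(tt^3 - tt)
  })
  sigma2 <- (n1 * n2 / 12) * ((nt + 1) - tie_term / (nt * (nt - 1)))
  z <- w - n1 * n2 / 2
  corr <- sign(z) * 0.5
  z <- (z - corr) / sqrt(pmax(sigma2, .Machine$double.eps))
  p <- 2 * pmin(pnorm(z), pnorm(z, lower.tail = FALSE))
  pmin(p, 1)
}

# Vectorised Welch t-test p-values per taxon.
welch_p <- function(x, idx1, idx2) {
  x1 <- x[idx1, , drop = FALSE]; x2 <- x[idx2, , drop = FALSE]
  n1 <- nrow(x1); n2 <- nrow(x2)
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- apply(x1, 2, var); v2 <- apply(x2, 2, var)
  se2 <- v1 / n1 + v2 / n2
  se2 <- pmax(se2, .Machine$double.eps)
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  df[!is.finite(df)] <- n1 + n2 - 2
  2 * pt(abs(tstat), df, lower.tail = FALSE)
}

#' Test differential abundance between two groups
#'
#' Per Monte-Carlo instance, a two-sided Wilcoxon rank-sum test (or Welch t
#' with `test = "t"`) is run per taxon on the CLR values; the per-taxon p is
#' the arithmetic mean over instances, corrected across taxa by
#' Benjamini-Hochberg. The effect size is the median over instances of the
#' difference of a random cross-group pair of CLR values divided by the
#' larger of the two within-group random-pair dispersions.
#'
#' @param instances `clr_instances` array from [dirichlet_instances()].
#' @param groups Group label per sample (two groups, each >= 2 samples).
#' @param treatment,control Which labels play numerator and denominator;
#'   positive differences mean enrichment in `treatment`.
#' @param fdr_threshold Significance threshold on the BH-adjusted q
#'   (default 0.05).
#' @param test "wilcoxon" (default) or "t".
#' @param seed Seed for the effect-size pair sampling.
#' @return A tibble: taxon_id, median_diff (CLR units, natural log),
#'   effect, p, q, enriched_in.
#' @export
test_differential <- function(instances, groups,
                              treatment = "rhizosphere", control = "bulk",
                              fdr_threshold = 0.05,
                              test = c("wilcoxon", "t"), seed = 1L) {
  test <- match.arg(test)
  stopifnot(inherits(instances, "clr_instances"))
  ids <- dimnames(instances)[[1]]
  taxa <- dimnames(instances)[[2]]
  groups <- as.character(groups)
  if (length(groups) != length(ids)) abort("`groups` length must match samples.")
  idx_t <- which(groups == treatment)
  idx_c <- which(groups == control)
  if (length(idx_t) < 2 || length(idx_c) < 2) {
    abort("each group needs at least 2 samples.")
  }
  n_mc <- dim(instances)[3]
  n_taxa <- length(taxa)
  p_sum <- numeric(n_taxa)
  diff_inst <- matrix(NA_real_, n_mc, n_taxa)
  eff_inst <- matrix(NA_real_, n_mc, n_taxa)
  set.seed(seed)
  for (i in seq_len(n_mc)) {
    x <- instances[, , i]
    p_sum <- p_sum + if (test == "wilcoxon") rank_sum_p(x, idx_t, idx_c)
                     else welch_p(x, idx_t, idx_c)
    diff_inst[i, ] <- apply(x[idx_t, , drop = FALSE], 2, median) -
      apply(x[idx_c, , drop = FALSE], 2, median)
    # random pairs for the standardized effect
    jt <- sample(idx_t, 1); jc <- sample(idx_c, 1)
    t2 <- sample(idx_t, 2); c2 <- sample(idx_c, 2)
    btw <- x[jt, ] - x[jc, ]
    win <- pmax(abs(x[t2[1], ] - x[t2[2], ]), abs(x[c2[1], ] - x[c2[2], ]))
    eff_inst[i, ] <- ifelse(btw == 0, 0,
                            btw / pmax(win, .Machine$double.eps))
  }
  p <- p_sum / n_mc
  q <- p.adjust(p, method = "BH")
  med_diff <- apply(diff_inst, 2, median)
  effect <- apply(eff_inst, 2, median)
  enriched <- ifelse(q < fdr_threshold,
                     ifelse(med_diff > 0, treatment, control), "none")
  tibble(taxon_id = taxa, median_diff = med_diff, effect = effect,
         p = p, q = q, enriched_in = enriched)
}

#' Differential abundance from counts in one call
#'
#' Convenience wrapper: [dirichlet_instances()] then [test_differential()].
#'
#' @inheritParams dirichlet_instances
#' @inheritParams test_differential
#' @return See [test_differential()].
#' @export
diff_abundance <- function(counts, groups, n_mc = 128, seed = 1L,
                           treatment = "rhizosphere", control = "bulk",
                           fdr_threshold = 0.05, test = "wilcoxon") {
  inst <- dirichlet_instances(counts, n_mc = n_mc, seed = seed)
  test_differential(inst, groups, treatment = treatment, control = control,
                    fdr_threshold = fdr_threshold, test = test,
                    seed = derive_seed(seed, 17L))
}

#' Aggregate a count table to a taxonomic rank
#'
#' Counts are summed over taxa sharing the rank label; taxa with an empty
#' or missing label are pooled as "Unassigned". Column sums are preserved.
#'
#' @param counts Count tibble.
#' @param taxonomy Taxonomy tibble covering the count taxa.
#' @param rank One of Kingdom, Phylum, Class, Order, Family, Genus, Species.
#' @return A count tibble whose columns are rank labels.
#' @export
aggregate_taxa <- function(counts, taxonomy, rank = "Phylum") {
  if (!rank %in% TAXONOMIC_RANKS) {
    abort(sprintf("unknown rank '%s'; expected one of %s.", rank,
                  paste(TAXONOMIC_RANKS, collapse = ", ")))
  }
  taxonomy <- validate_taxonomy(taxonomy)
  if (!rank %in% names(taxonomy)) {
    abort(sprintf("taxonomy has no '%s' column.", rank))
  }
  m <- as_count_matrix(counts)
  lab <- taxonomy[[rank]][match(colnames(m), taxonomy$taxon_id)]
  lab[is.na(lab) | lab == ""] <- "Unassigned"
  agg <- t(rowsum(t(m), group = lab))
  as_count_tbl(agg)
}
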