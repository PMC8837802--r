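# Co-occurrence network construction and topology: abundance filtering,
# Spearman correlation with BH correction, a random-matrix-theory (RMT)
# correlation threshold, greedy modularity, Zi/Pi node roles, natural
# connectivity and betweenness-ordered robustness degradation.

#' Filter rare taxa and compute pairwise Spearman correlations
#'
#' Taxa whose overall mean relative abundance falls below `min_relabund`
#' (default 0.02%) are removed; Spearman rho and two-sided p (t
#' approximation) are computed for every remaining pair, with
#' Benjamini-Hochberg q across all pairs.
#'
#' @param counts Count tibble with >= 4 samples.
#' @param min_relabund Mean relative-abundance filter (default 2e-4).
#' @return A list with symmetric matrices `rho`, `p`, `q` and the retained
#'   taxon ids.
#' @export
filter_and_correlate <- function(counts, min_relabund = 0.0002) {
  m <- as_count_matrix(counts)
  if (nrow(m) < 4) abort("need at least 4 samples for correlation analysis.")
  p_rel <- rel_abund_matrix(m)
  keep <- colMeans(p_rel) >= min_relabund
  if (sum(keep) < 2) abort("fewer than 2 taxa survive the abundance filter.")
  m <- m[, keep, drop = FALSE]
  n <- nrow(m)
  rho <- cor(m, method = "spearman")
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- 0
  ut <- upper.tri(p)
  q <- p
  q[ut] <- p.adjust(p[ut], method = "BH")
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  diag(q) <- 0
  list(rho = rho, p = p, q = q, taxa = colnames(m))
}

# Unfold a spectrum: map eigenvalues through a smoothed cumulative spectral
# density so that mean spacing is 1, then return nearest-neighbour spacings.
nnsd_spacings <- function(lambda, dedup_tol = 1e-8) {
  lambda <- sort(lambda)
  lambda <- lambda[c(TRUE, diff(lambda) > dedup_tol)]  # drop degeneracies
  n <- length(lambda)
  if (n < 3) return(numeric(0))
  cdf <- (seq_len(n) - 0.5) / n
  fit <- tryCatch(smooth.spline(lambda, cdf, spar = 0.7),
                  error = function(e) NULL)
  if (is.null(fit)) return(numeric(0))
  e <- n * predict(fit, lambda)$y
  diff(sort(e))
}

# Chi-square goodness of fit of spacings against the Poisson law exp(-s),
# binned on [0, s_max]; returns the p-value (1 when untestable).
poisson_gof_p <- function(s, bins = 20, s_max = 3) {
  s <- s[is.finite(s)]
  n <- length(s)
  if (n < 10) return(1)  # too few spacings to reject anything
  br <- seq(0, s_max, length.out = bins + 1)
  obs <- tabulate(pmin(findInterval(pmin(s, s_max - 1e-12), br,
                                    rightmost.closed = TRUE), bins), bins)
  prob <- diff(1 - exp(-br))
  prob[bins] <- prob[bins] + exp(-s_max)  # fold the tail into the last bin
  expd <- n * prob
  ok <- expd > 0
  stat <- sum((obs[ok] - expd[ok])^2 / expd[ok])
  pchisq(stat, df = sum(ok) - 1, lower.tail = FALSE)
}

#' Random-matrix-theory correlation threshold
#'
#' For each candidate threshold the correlation matrix is hard-thresholded
#' (entries with |rho| below the candidate zeroed), its eigenvalue spectrum
#' unfolded with a cubic smoothing spline, and the nearest-neighbour
#' spacing distribution tested against the Poisson law exp(-s). The chosen
#' threshold is the smallest candidate whose spacings are consistent with
#' Poisson statistics (chi-square p > `p_cut`), i.e. where the
#' GOE-to-Poisson transition has occurred.
#'
#' @param rho Symmetric correlation matrix.
#' @param grid Ascending candidate thresholds in (0, 1).
#' @param p_cut Chi-square p-value above which Poisson consistency is
#'   declared (default 0.05).
#' @param bins,s_max Histogram bins and upper limit for the spacing
#'   distribution.
#' @return A list: `threshold`, `converged` (FALSE when no candidate
#'   reached Poisson consistency and the grid maximum was returned), and a
#'   tibble `scan` of per-candidate p-values.
#' @export
rmt_threshold <- function(rho, grid = seq(0.3, 0.9, by = 0.02),
                          p_cut = 0.05, bins = 20, s_max = 3) {
  if (any(grid <= 0 | grid >= 1) || is.unsorted(grid)) {
    abort("`grid` must be ascending within (0, 1).")
  }
  r <- as.matrix(rho)
  diag(r) <- 0
  pvals <- numeric(length(grid))
  for (i in seq_along(grid)) {
    rt <- r
    rt[abs(rt) < grid[i]] <- 0
    ev <- eigen(rt, symmetric = TRUE, only.values = TRUE)$values
    pvals[i] <- poisson_gof_p(nnsd_spacings(ev), bins = bins, s_max = s_max)
  }
  hit <- which(pvals > p_cut)
  converged <- length(hit) > 0
  if (!converged) {
    warn("rmt_threshold: no candidate reached Poisson consistency; returning grid maximum.")
  }
  thr <- if (converged) grid[hit[1]] else grid[length(grid)]
  list(threshold = thr, converged = converged,
       scan = tibble(candidate = grid, poisson_p = pvals))
}

#' Build the thresholded co-occurrence network
#'
#' An edge joins two taxa iff the BH-adjusted q is below `q_threshold` and
#' |rho| >= `rho_star`. Isolated nodes are dropped and reported. Edge sign
#' is kept as an attribute; topology metrics ignore it.
#'
#' @param correlations List from [filter_and_correlate()] (`rho`, `q`).
#' @param rho_star Correlation threshold (e.g. from [rmt_threshold()]).
#' @param taxonomy Optional taxonomy tibble to label nodes with phyla.
#' @param counts Optional count tibble to attach mean relative abundances.
#' @param q_threshold FDR threshold on edges (default 0.05).
#' @param quiet Suppress the dropped-isolate message.
#' @return An `igraph` graph with node attributes `name`, `phylum`,
#'   `mean_relabund` and edge attributes `rho`, `q`, `sign`.
#' @export
build_network <- function(correlations, rho_star, taxonomy = NULL,
                          counts = NULL, q_threshold = 0.05, quiet = FALSE) {
  rho <- correlations$rho; q <- correlations$q
  stopifnot(identical(dim(rho), dim(q)))
  keep <- abs(rho) >= rho_star & q < q_threshold
  diag(keep) <- FALSE
  if (!any(keep)) abort("no edge satisfies the thresholds; empty network.")
  idx <- which(keep & upper.tri(keep), arr.ind = TRUE)
  taxa <- colnames(rho)
  rho_e <- rho[idx]; q_e <- q[idx]
  edges <- tibble(from = taxa[idx[, 1]], to = taxa[idx[, 2]],
                  rho = rho_e, q = q_e,
                  sign = ifelse(rho_e >= 0, "positive", "negative"))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  isolated <- setdiff(taxa, igraph::V(g)$name)
  if (length(isolated) && !quiet) {
    log_msg("build_network: dropped %d isolated taxa.", length(isolated))
  }
  if (!is.null(taxonomy)) {
    taxonomy <- validate_taxonomy(taxonomy)
    igraph::V(g)$phylum <-
      taxonomy$Phylum[match(igraph::V(g)$name, taxonomy$taxon_id)]
  }
  if (!is.null(counts)) {
    p_rel <- rel_abund_matrix(as_count_matrix(counts))
    igraph::V(g)$mean_relabund <-
      colMeans(p_rel)[igraph::V(g)$name]
  }
  g
}

#' Greedy modularity module detection
#'
#' Agglomerative greedy maximisation of Newman's modularity
#' Q = sum_s (e_ss - a_s^2) on the unweighted graph.
#'
#' @param net An `igraph` graph.
#' @param weighted Use |rho| edge weights for the optimisation (default
#'   FALSE).
#' @return A list of class `rhizo_modules`: `membership` (tibble taxon_id,
#'   module), `modularity`, `n_modules`.
#' @export
greedy_modules <- function(net, weighted = FALSE) {
  if (igraph::vcount(net) == 0) abort("empty graph.")
  g <- igraph::simplify(net)
  w <- if (weighted && "rho" %in% igraph::edge_attr_names(g)) {
    abs(igraph::E(g)$rho)
  } else NULL
  cl <- igraph::cluster_fast_greedy(g, weights = w)
  memb <- igraph::membership(cl)
  q <- igraph::modularity(g, memb)
  if (q < 0) {
    # the trivial single-module partition has Q = 0 exactly; prefer it when
    # the greedy merge path ends below that
    memb[] <- 1L
    q <- igraph::modularity(g, memb)
  }
  structure(list(membership = tibble(taxon_id = names(memb),
                                     module = as.integer(memb)),
                 modularity = q,
                 n_modules = length(unique(memb))),
            class = "rhizo_modules")
}

# Direct Newman modularity of a partition (independent of igraph's value).
newman_modularity <- function(net, membership) {
  g <- igraph::simplify(net)
  m <- igraph::ecount(g)
  el <- igraph::as_edgelist(g)
  mod <- membership[el[, 1]] == membership[el[, 2]]
  e_ss <- tapply(rep(1, nrow(el))[mod], membership[el[, 1]][mod], sum)
  deg <- igraph::degree(g)
  a_s <- tapply(deg, membership[names(deg)], sum) / (2 * m)
  sum(unlist(e_ss)) / m - sum(a_s^2)
}

#' Within-module degree z-score and participation coefficient
#'
#' Zi is the z-score of node i's within-module degree relative to the
#' members of its module (0 when the module's degrees have zero variance);
#' Pi = 1 - sum_s (k_is / k_i)^2 over modules s. Nodes are classified as
#' module hubs (Zi > 2.5, Pi < 0.62), network hubs (Zi > 2.5, Pi > 0.62),
#' connectors (Zi < 2.5, Pi > 0.62) or peripherals; boundary equalities
#' fall to the peripheral side.
#'
#' @param net An `igraph` graph with no isolated nodes.
#' @param partition A `rhizo_modules` object or named membership vector
#'   covering every node.
#' @return A tibble: taxon_id, degree, zi, pi, category.
#' @export
node_roles <- function(net, partition) {
  memb <- if (inherits(partition, "rhizo_modules")) {
    setNames(partition$membership$module, partition$membership$taxon_id)
  } else partition
  g <- igraph::simplify(net)
  nodes <- igraph::V(g)$name
  if (!all(nodes %in% names(memb))) abort("partition does not cover all nodes.")
  deg <- igraph::degree(g)
  if (any(deg == 0)) {
    abort(sprintf("isolated node '%s' (drop isolates before role analysis).",
                  nodes[which(deg == 0)[1]]))
  }
  memb <- memb[nodes]
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  mods <- sort(unique(memb))
  # k_is: links of node i into module s
  k_is <- sapply(mods, function(s) rowSums(adj[, memb == s, drop = FALSE]))
  if (is.null(dim(k_is))) k_is <- matrix(k_is, nrow = length(nodes))
  k_own <- k_is[cbind(seq_along(nodes), match(memb, mods))]
  zi <- numeric(length(nodes))
  for (s in mods) {
    in_s <- memb == s
    ks <- k_own[in_s]
    sdk <- sd(ks)
    zi[in_s] <- if (is.na(sdk) || sdk == 0) 0 else (ks - mean(ks)) / sdk
  }
  pi <- as.numeric(1 - rowSums((k_is / deg)^2))
  zi <- as.numeric(zi)
  tibble(taxon_id = nodes, degree = as.numeric(deg), zi = zi, pi = pi,
         category = role_category(zi, pi))
}

# Four-way Zi/Pi classification; boundary equalities (Zi = 2.5, Pi = 0.62)
# fall to the peripheral side because the published definitions use strict
# inequalities in both directions.
role_category <- function(zi, pi) {
  hub <- zi > 2.5
  conn <- pi > 0.62
  ifelse(hub & conn, "network hub",
         ifelse(hub, "module hub",
                ifelse(conn, "connector", "peripheral")))
}

#' Natural connectivity of a graph
#'
#' ln of the average of exp(lambda_i) over the adjacency eigenvalues: a
#' spectral measure of path redundancy used to track robustness.
#'
#' @param net An `igraph` graph with >= 1 node.
#' @return A scalar.
#' @export
natural_connectivity <- function(net) {
  n <- igraph::vcount(net)
  if (n == 0) abort("empty graph.")
  a <- igraph::as_adjacency_matrix(igraph::simplify(net), sparse = FALSE)
  lambda <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
  lmax <- max(lambda)
  lmax + log(mean(exp(lambda - lmax)))
}

#' Betweenness-ordered robustness degradation curve
#'
#' Betweenness centrality is computed once on the intact graph; nodes are
#' then removed one at a time in the chosen order (default ascending
#' betweenness, ties broken by node id) until 80% of the nodes are gone,
#' recording natural connectivity after each removal.
#'
#' @param net An `igraph` graph with >= 5 nodes.
#' @param order "asc" (default; smallest betweenness first), "desc", or
#'   "random".
#' @param max_frac Fraction of nodes to remove (default 0.8).
#' @param seed Seed used when `order = "random"`.
#' @return A tibble: step, fraction_removed, natural_connectivity,
#'   removed (node id, NA at step 0).
#' @export
robustness_curve <- function(net, order = c("asc", "desc", "random"),
                             max_frac = 0.8, seed = 1L) {
  order <- match.arg(order)
  n <- igraph::vcount(net)
  if (n < 5) abort("robustness curve needs at least 5 nodes.")
  btw <- igraph::betweenness(net, weights = NA)
  nodes <- igraph::V(net)$name
  ord <- switch(order,
                asc = nodes[order(btw, nodes)],
                desc = nodes[order(-btw, nodes)],
                random = { set.seed(seed); sample(nodes) })
  n_remove <- floor(max_frac * n)
  out <- tibble(step = 0:n_remove,
                fraction_removed = (0:n_remove) / n,
                natural_connectivity = NA_real_,
                removed = c(NA_character_, ord[seq_len(n_remove)]))
  g <- net
  out$natural_connectivity[1] <- natural_connectivity(g)
  for (i in seq_len(n_remove)) {
    g <- igraph::delete_vertices(g, ord[i])
    out$natural_connectivity[i + 1] <- natural_connectivity(g)
  }
  out
}

#' Node and edge tables of a network
#'
#' @param net An `igraph` graph built by [build_network()].
#' @return `network_edges()`: tibble from, to, rho, q, sign.
#'   `network_nodes()`: tibble taxon_id plus any node attributes.
#' @export
network_edges <- function(net) {
  as_tibble(igraph::as_data_frame(net, what = "edges"))
}

#' @rdname network_edges
#' @export
network_nodes <- function(net) {
  df <- igraph::as_data_frame(net, what = "vertices")
  names(df)[names(df) == "name"] <- "taxon_id"
  as_tibble(df)
}
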