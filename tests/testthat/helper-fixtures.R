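# Small in-code fixtures shared across tests.

toy_counts <- function(m) {
  # m: named matrix-like list of sample rows
  mat <- do.call(rbind, m)
  colnames(mat) <- paste0("t", seq_len(ncol(mat)))
  rownames(mat) <- names(m)
  as_count_tbl(mat)
}

# metrically a star: rooted binary topology whose internal branches all
# have zero length, so every tip sits at unit distance from the root
star_tree <- function(tips) {
  stopifnot(length(tips) >= 3)
  inner <- paste0(tips[1], ":1")
  for (t in tips[-1]) inner <- paste0("(", inner, ",", t, ":1):0")
  inner <- sub(":0$", "", inner)
  ape::read.tree(text = paste0(inner, ";"))
}

small_study_set <- function(seed = 11, ...) {
  cfg <- synth_config(n_studies = 3, n_per_group = 4, n_taxa = 60,
                      depth_mean = 4000, depth_dispersion = 50,
                      seed = seed, ...)
  generate_study_set(cfg)
}

# independent naive Zi/Pi implementation used as a brute-force oracle
naive_zi_pi <- function(net, membership) {
  g <- igraph::simplify(net)
  nodes <- igraph::V(g)$name
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  memb <- membership[nodes]
  zi <- pi <- numeric(length(nodes))
  for (i in seq_along(nodes)) {
    s <- memb[i]
    members <- which(memb == s)
    k_in <- vapply(members, function(j) sum(adj[j, members]), numeric(1))
    k_i_in <- sum(adj[i, members])
    sdk <- stats::sd(k_in)
    zi[i] <- if (is.na(sdk) || sdk == 0) 0 else (k_i_in - mean(k_in)) / sdk
    k_tot <- sum(adj[i, ])
    pi[i] <- 1 - sum(vapply(unique(memb), function(ss) {
      (sum(adj[i, memb == ss]) / k_tot)^2
    }, numeric(1)))
  }
  tibble::tibble(taxon_id = nodes, zi = zi, pi = pi)
}
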