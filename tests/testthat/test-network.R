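test_that("abundance filter removes rare taxa; rho is symmetric with unit diagonal", {
  set.seed(2)
  n <- 10
  rare_col <- pmax(rpois(n, 0.5), 0)          # ~0.01% of a 10k-read sample
  common <- matrix(rpois(n * 5, 2000), n, 5)
  m <- cbind(common, rare_col)
  m[, 1] <- sort(m[, 1]); m[, 2] <- sort(m[, 2])  # a perfectly monotone pair
  colnames(m) <- paste0("t", 1:6); rownames(m) <- paste0("s", 1:n)
  res <- filter_and_correlate(as_count_tbl(m), min_relabund = 2e-4)
  expect_false("t6" %in% res$taxa)
  expect_equal(res$rho, t(res$rho))
  expect_equal(unname(diag(res$rho)), rep(1, length(res$taxa)))
  expect_equal(res$rho["t1", "t2"], 1)
})

test_that("network edges equal a brute-force scan of qualifying pairs", {
  set.seed(4)
  n_taxa <- 12
  rho <- cor(matrix(rnorm(20 * n_taxa), 20, n_taxa), method = "spearman")
  q <- matrix(runif(n_taxa^2, 0, 0.2), n_taxa, n_taxa)
  q[lower.tri(q)] <- t(q)[lower.tri(q)]; diag(q) <- 0
  dimnames(rho) <- dimnames(q) <- list(paste0("t", 1:n_taxa),
                                       paste0("t", 1:n_taxa))
  rho_star <- 0.2
  net <- suppressMessages(
    build_network(list(rho = rho, q = q), rho_star))
  got <- network_edges(net)
  want <- 0L
  for (i in 1:(n_taxa - 1)) for (j in (i + 1):n_taxa) {
    if (abs(rho[i, j]) >= rho_star && q[i, j] < 0.05) want <- want + 1L
  }
  expect_equal(nrow(got), want)
  expect_true(all(abs(got$rho) >= rho_star & got$q < 0.05))

  q1 <- q; q1[] <- 1; diag(q1) <- 0
  expect_error(build_network(list(rho = rho, q = q1), 0.1), "empty network")
})

test_that("greedy modularity: two triangles give Q = 0.5, cliques give Q = 0", {
  two_tri <- igraph::graph_from_edgelist(rbind(
    c("a", "b"), c("b", "c"), c("c", "a"),
    c("d", "e"), c("e", "f"), c("f", "d")), directed = FALSE)
  part <- greedy_modules(two_tri)
  expect_equal(part$modularity, 0.5, tolerance = 1e-12)
  expect_equal(part$n_modules, 2)
  memb <- setNames(part$membership$module, part$membership$taxon_id)
  expect_equal(rhizometa:::newman_modularity(two_tri, memb), 0.5,
               tolerance = 1e-12)

  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- letters[1:5]
  single <- setNames(rep(1, 5), letters[1:5])
  expect_equal(rhizometa:::newman_modularity(k5, single), 0, tolerance = 1e-12)
  pk5 <- greedy_modules(k5)
  expect_gte(pk5$modularity, 0)
})

test_that("modularity of the returned partition matches Newman's formula", {
  set.seed(8)
  g <- igraph::sample_gnp(25, 0.15)
  igraph::V(g)$name <- paste0("n", 1:25)
  g <- igraph::delete_vertices(g, igraph::degree(g) == 0)
  part <- greedy_modules(g)
  memb <- setNames(part$membership$module, part$membership$taxon_id)
  expect_equal(part$modularity, rhizometa:::newman_modularity(g, memb),
               tolerance = 1e-12)
})

test_that("Zi/Pi: participation identities and four-way classification", {
  # node with all links inside its module
  tri_plus <- igraph::graph_from_edgelist(rbind(
    c("a", "b"), c("b", "c"), c("c", "a"), c("c", "d"), c("d", "e")),
    directed = FALSE)
  memb <- c(a = 1, b = 1, c = 1, d = 2, e = 2)
  roles <- node_roles(tri_plus, memb)
  expect_equal(roles$pi[roles$taxon_id == "a"], 0)
  # hub with degree 4 split evenly across 4 modules
  star <- igraph::graph_from_edgelist(rbind(
    c("h", "m1"), c("h", "m2"), c("h", "m3"), c("h", "m4"),
    c("m1", "m1b"), c("m2", "m2b"), c("m3", "m3b"), c("m4", "m4b")),
    directed = FALSE)
  memb4 <- c(h = 1, m1 = 1, m2 = 2, m3 = 3, m4 = 4,
             m1b = 1, m2b = 2, m3b = 3, m4b = 4)
  r4 <- node_roles(star, memb4)
  expect_equal(r4$pi[r4$taxon_id == "h"], 0.75)

  expect_equal(rhizometa:::role_category(2.6, 0.5), "module hub")
  expect_equal(rhizometa:::role_category(2.6, 0.7), "network hub")
  expect_equal(rhizometa:::role_category(1.0, 0.7), "connector")
  expect_equal(rhizometa:::role_category(1.0, 0.5), "peripheral")
  # boundary equalities fall to the peripheral side
  expect_equal(rhizometa:::role_category(2.5, 0.62), "peripheral")
  expect_equal(rhizometa:::role_category(2.6, 0.62), "module hub")
})

test_that("Zi/Pi matches an independent naive implementation on random graphs", {
  for (s in 1:5) {
    set.seed(s)
    g <- igraph::sample_gnp(20 + s, 0.2)
    igraph::V(g)$name <- sprintf("n%02d", seq_len(igraph::vcount(g)))
    g <- igraph::delete_vertices(g, igraph::degree(g) == 0)
    part <- greedy_modules(g)
    memb <- setNames(part$membership$module, part$membership$taxon_id)
    mine <- node_roles(g, memb)
    ref <- naive_zi_pi(g, memb)
    ref <- ref[match(mine$taxon_id, ref$taxon_id), ]
    expect_equal(mine$zi, ref$zi, tolerance = 1e-12)
    expect_equal(mine$pi, ref$pi, tolerance = 1e-12)
  }
})

test_that("role categories partition the node set", {
  set.seed(12)
  g <- igraph::sample_gnp(40, 0.12)
  igraph::V(g)$name <- sprintf("n%02d", 1:40)
  g <- igraph::delete_vertices(g, igraph::degree(g) == 0)
  roles <- node_roles(g, greedy_modules(g))
  expect_equal(nrow(roles), igraph::vcount(g))
  expect_true(all(roles$category %in%
                    c("module hub", "network hub", "connector", "peripheral")))
})

test_that("natural connectivity matches eigen-decomposition oracles", {
  one <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(one)$name <- "a"
  expect_equal(natural_connectivity(one), 0)

  k3 <- igraph::make_full_graph(3)
  expect_equal(natural_connectivity(k3),
               log((exp(2) + 2 * exp(-1)) / 3), tolerance = 1e-10)

  p3 <- igraph::make_graph(~ a - b, b - c)
  expect_equal(natural_connectivity(p3),
               log((exp(sqrt(2)) + 1 + exp(-sqrt(2))) / 3), tolerance = 1e-10)
})

test_that("natural connectivity is monotone under edge addition", {
  set.seed(21)
  g <- igraph::sample_gnp(15, 0.2)
  nc0 <- natural_connectivity(g)
  missing_pairs <- which(!igraph::as_adjacency_matrix(g, sparse = FALSE) &
                           upper.tri(matrix(TRUE, 15, 15)), arr.ind = TRUE)
  add <- missing_pairs[1, ]
  g2 <- igraph::add_edges(g, c(add[1], add[2]))
  expect_gt(natural_connectivity(g2), nc0)
})

test_that("robustness curve: length, symmetry on K10, denser graphs dominate", {
  k10 <- igraph::make_full_graph(10)
  igraph::V(k10)$name <- sprintf("v%02d", 1:10)
  cur <- robustness_curve(k10)
  expect_equal(nrow(cur), floor(0.8 * 10) + 1)
  expect_equal(cur$fraction_removed[1], 0)
  expect_true(all(diff(cur$fraction_removed) > 0))
  # all-equal betweenness: curve depends only on the removal count
  expected <- vapply(0:8, function(r) {
    natural_connectivity(igraph::make_full_graph(10 - r))
  }, numeric(1))
  expect_equal(cur$natural_connectivity, expected, tolerance = 1e-10)

  # a denser graph degrades more slowly: its curve carries more total
  # connectivity, and under a common removal order it dominates pointwise
  # (each graph's own betweenness order lets the noisy tails cross)
  wins_area <- wins_ord <- 0L
  for (s in 1:10) {
    set.seed(s)
    g <- igraph::sample_gnp(20, 0.25)
    igraph::V(g)$name <- sprintf("v%02d", 1:20)
    a <- igraph::as_adjacency_matrix(g, sparse = FALSE)
    miss <- which(a == 0 & upper.tri(a), arr.ind = TRUE)
    extra <- miss[sample(nrow(miss), ceiling(0.2 * igraph::ecount(g))), ,
                  drop = FALSE]
    g2 <- igraph::add_edges(g, t(extra))
    c1 <- robustness_curve(g)$natural_connectivity
    c2 <- robustness_curve(g2)$natural_connectivity
    if (mean(c2) > mean(c1)) wins_area <- wins_area + 1L
    btw <- igraph::betweenness(g, weights = NA)
    ord <- igraph::V(g)$name[order(btw, igraph::V(g)$name)]
    ok <- TRUE; ga <- g; gb <- g2
    for (i in seq_len(16)) {
      ga <- igraph::delete_vertices(ga, ord[i])
      gb <- igraph::delete_vertices(gb, ord[i])
      if (natural_connectivity(gb) < natural_connectivity(ga) - 1e-9) {
        ok <- FALSE
      }
    }
    if (ok) wins_ord <- wins_ord + 1L
  }
  expect_gte(wins_area, 9L)
  expect_gte(wins_ord, 9L)
  expect_error(robustness_curve(igraph::make_full_graph(4)), "at least 5")
})

test_that("RMT threshold: invariant two-block input returns the smallest candidate", {
  # two perfectly correlated blocks, zero cross-correlation
  rho <- matrix(0, 10, 10)
  rho[1:5, 1:5] <- 1; rho[6:10, 6:10] <- 1
  dimnames(rho) <- list(paste0("t", 1:10), paste0("t", 1:10))
  grid <- seq(0.3, 0.9, by = 0.1)
  res <- rmt_threshold(rho, grid = grid)
  expect_equal(res$threshold, 0.3)
  expect_true(res$converged)
  expect_error(rmt_threshold(rho, grid = c(0.5, 0.2)), "ascending")
})

test_that("RMT threshold separates planted blocks from cross-block noise", {
  ok_within <- ok_cross <- 0L
  reps <- 5L
  for (s in seq_len(reps)) {
    set.seed(s)
    n <- 40; p <- 60; n_blocks <- 4
    block <- rep(1:n_blocks, each = p / n_blocks)
    f <- matrix(rnorm(n * n_blocks), n, n_blocks)
    x <- sqrt(0.8) * f[, block] + sqrt(0.2) * matrix(rnorm(n * p), n, p)
    colnames(x) <- paste0("t", 1:p)
    rho <- cor(x, method = "spearman")
    res <- rmt_threshold(rho, grid = seq(0.2, 0.9, by = 0.05))
    keep <- abs(rho) >= res$threshold
    diag(keep) <- FALSE
    same <- outer(block, block, "==")
    within_frac <- sum(keep & same) / sum(same & !diag(p) > 0)
    cross_frac <- sum(keep & !same) / sum(!same)
    if (sum(keep[upper.tri(keep)] & same[upper.tri(same)]) /
          sum(same[upper.tri(same)]) >= 0.8) ok_within <- ok_within + 1L
    if (cross_frac <= 0.05) ok_cross <- ok_cross + 1L
  }
  expect_gte(ok_within, 4L)
  expect_gte(ok_cross, 4L)
})

test_that("network build is invariant to sample ordering of the counts", {
  b <- small_study_set(seed = 51)
  res1 <- filter_and_correlate(b$counts)
  shuffled <- b$counts[sample(nrow(b$counts)), ]
  res2 <- filter_and_correlate(shuffled)
  expect_equal(res1$rho, res2$rho[res1$taxa, res1$taxa], tolerance = 1e-12)
  expect_equal(res1$q, res2$q[res1$taxa, res1$taxa], tolerance = 1e-12)
})
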