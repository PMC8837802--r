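test_that("effect record matches the direct lnRR and variance formulas", {
  # X_t = 12, X_c = 10, S_t = 2, S_c = 1, n = 5 each
  # groups constructed to exact means/SDs via scaled z-scores
  mk <- function(mean, sd, n) {
    z <- scale(seq_len(n))[, 1]
    mean + sd * z / sqrt(sum(z^2) / (n - 1))
  }
  rec <- effect_from_groups(mk(12, 2, 5), mk(10, 1, 5), "s1", "richness")
  expect_equal(rec$lnrr, log(1.2), tolerance = 1e-5)
  expect_equal(rec$lnrr, 0.18232, tolerance = 1e-4)
  expect_equal(rec$v, 4 / (5 * 144) + 1 / (5 * 100), tolerance = 1e-7)
  expect_equal(rec$v, 0.0075556, tolerance = 1e-5)

  same <- effect_from_groups(c(3, 3, 3), c(3, 3, 3))
  expect_equal(same$lnrr, 0)
  expect_equal(same$v, 0)

  single <- effect_from_groups(5, c(4, 6))
  expect_true(single$flagged)
  expect_equal(single$v, 2 / (2 * 25))  # S_t = 0 contributes nothing

  expect_warning(skip <- effect_from_groups(c(-1, 0), c(1, 2)), "skipped")
  expect_equal(nrow(skip), 0)
  expect_error(effect_from_groups(numeric(), c(1, 2)), "non-empty")
})

test_that("swapping treatment and control negates every lnRR", {
  set.seed(2)
  a <- rexp(6) + 1; b <- rexp(6) + 1
  fwd <- effect_from_groups(a, b)
  rev <- effect_from_groups(b, a)
  expect_equal(rev$lnrr, -fwd$lnrr, tolerance = 1e-12)
  expect_equal(rev$v, fwd$v, tolerance = 1e-12)
})

test_that("pooling: homogeneous case, percent change, and scale invariance", {
  rec <- tibble::tibble(study_id = paste0("s", 1:5), variable = "x",
                        lnrr = rep(0.3, 5), v = rep(0.02, 5))
  pooled <- pool_effects(rec, n_boot = 99, seed = 1)
  expect_equal(pooled$mean_lnrr, 0.3, tolerance = 1e-12)
  expect_equal(pooled$tau2, 0)

  rec2 <- tibble::tibble(study_id = paste0("s", 1:4), variable = "x",
                         lnrr = rep(log(2), 4), v = rep(0.01, 4))
  p2 <- pool_effects(rec2, n_boot = 99, seed = 1)
  expect_equal(p2$pct_change, 100, tolerance = 1e-9)
  # percent-change round trip
  expect_equal(log(1 + p2$pct_change / 100), p2$mean_lnrr, tolerance = 1e-12)

  # pooled mean invariant to study order and common scaling of the means
  set.seed(9)
  y <- rnorm(8, 0.1, 0.2); v <- runif(8, 0.005, 0.05)
  r1 <- tibble::tibble(study_id = paste0("s", 1:8), variable = "x",
                       lnrr = y, v = v)
  r2 <- r1[sample(8), ]
  expect_equal(pool_effects(r1, n_boot = 49, seed = 3)$mean_lnrr,
               pool_effects(r2, n_boot = 49, seed = 3)$mean_lnrr,
               tolerance = 1e-12)
  # multiplying X_t and X_c by a constant leaves lnRR and v unchanged
  a <- rexp(5) + 1; b <- rexp(5) + 1
  expect_equal(effect_from_groups(3 * a, 3 * b)$lnrr,
               effect_from_groups(a, b)$lnrr, tolerance = 1e-12)
  expect_equal(effect_from_groups(3 * a, 3 * b)$v,
               effect_from_groups(a, b)$v, tolerance = 1e-12)
})

test_that("degenerate all-identical records give a point CI, flagged", {
  rec <- tibble::tibble(study_id = paste0("s", 1:3), variable = "x",
                        lnrr = rep(0.2, 3), v = 0)
  pooled <- pool_effects(rec, n_boot = 19, seed = 1)
  expect_true(pooled$degenerate)
  expect_equal(pooled$ci_low, pooled$ci_high)
  expect_error(pool_effects(rec[1, ]), ">= 2 studies")
})

test_that("bootstrap CIs are bit-identical under a fixed seed", {
  rec <- simulate_lnrr_studies(k = 15, true_lnrr = 0.1, tau2 = 0.02, seed = 8)
  p1 <- pool_effects(rec, n_boot = 199, seed = 5)
  p2 <- pool_effects(rec, n_boot = 199, seed = 5)
  expect_identical(p1$ci_low, p2$ci_low)
  expect_identical(p1$ci_high, p2$ci_high)
})

test_that("DL pooling agrees with metafor as an independent oracle", {
  skip_if_not_installed("metafor")
  rec <- simulate_lnrr_studies(k = 25, true_lnrr = -0.05, tau2 = 0.01,
                               seed = 12)
  pooled <- pool_effects(rec, n_boot = 19, seed = 1)
  ref <- metafor::rma(yi = rec$lnrr, vi = rec$v, method = "DL")
  expect_equal(pooled$mean_lnrr, as.numeric(ref$beta), tolerance = 1e-8)
  expect_equal(pooled$tau2, ref$tau2, tolerance = 1e-8)
})

test_that("subgroup analysis drops small subgroups and partitions Q exactly", {
  set.seed(3)
  rec <- simulate_lnrr_studies(k = 31, true_lnrr = 0.05, tau2 = 0.02, seed = 6)
  rec$eco <- c(rep("cropland", 12), rep("forest", 10), rep("grassland", 9))
  expect_message(
    res <- subgroup_analysis(rec, "eco", min_k = 10, n_boot = 49, seed = 2),
    "grassland")
  expect_setequal(unique(res$summaries$group), c("cropland", "forest"))
  het <- res$heterogeneity
  expect_equal(het$q_t, het$q_w + het$q_b, tolerance = 1e-9)
  expect_true(all(c(het$q_t, het$q_w, het$q_b) >= 0))
  expect_equal(het$df_b, 1)

  rec$solo <- c(rep("a", 9), rep("b", 9), rep("c", 13))
  expect_warning(suppressMessages(
    subgroup_analysis(rec, "solo", min_k = 10)), "fewer than 2 subgroups")
})

test_that("Egger: constructed symmetric funnel gives a zero intercept", {
  v <- c(0.01, 0.01, 0.04, 0.04, 0.09, 0.09)
  mu <- 0.2; d <- c(0.05, 0.1, 0.15)
  y <- mu + c(d[1], -d[1], d[2], -d[2], d[3], -d[3])
  rec <- tibble::tibble(study_id = paste0("s", 1:6), variable = "x",
                        lnrr = y, v = v)
  res <- egger_test(rec)
  expect_equal(res$intercept, 0, tolerance = 1e-10)
  rec$v[1] <- 0
  expect_warning(res2 <- egger_test(rec), "v = 0")
  expect_equal(res2$k, 5)
  expect_error(suppressWarnings(egger_test(rec[1:3, ])), ">= 3")
})

test_that("Egger agrees with metafor's classic regression test", {
  skip_if_not_installed("metafor")
  rec <- simulate_lnrr_studies(k = 20, true_lnrr = 0.1, tau2 = 0.01, seed = 3)
  mine <- egger_test(rec)
  ref <- metafor::regtest(x = rec$lnrr, vi = rec$v, model = "lm",
                          predictor = "sei")
  expect_equal(mine$p, ref$pval, tolerance = 1e-6)
})

test_that("trim-and-fill: symmetric sets give k0 = 0; imputations mirror exactly", {
  v <- rep(c(0.01, 0.04, 0.09), 2)
  y <- 0.1 + c(0.05, 0.1, 0.15, -0.05, -0.1, -0.15)
  rec <- tibble::tibble(study_id = paste0("s", 1:6), variable = "x",
                        lnrr = y, v = v)
  res <- suppressWarnings(trim_and_fill(rec, side = "left"))
  expect_equal(res$k0, 0)
  expect_equal(res$adjusted_mean, res$unadjusted_mean, tolerance = 1e-12)

  # one-sided censoring: delete the most negative effects
  set.seed(14)
  rec2 <- simulate_lnrr_studies(k = 40, true_lnrr = 0, tau2 = 0.02,
                                n_per_group = 4, cv = 0.3, seed = 14)
  cens <- rec2[rank(rec2$lnrr) > 6, ]   # drop the 6 lowest
  res2 <- trim_and_fill(cens, side = "left")
  expect_gt(res2$k0, 0)
  expect_lt(res2$adjusted_mean, res2$unadjusted_mean)
  # imputed records are exact mirrors through the trimmed centre
  if (res2$k0 > 0) {
    yy <- cens$lnrr
    trimmed <- sort(yy, decreasing = TRUE)[seq_len(res2$k0)]
    centre <- (res2$filled$lnrr + sort(trimmed, decreasing = TRUE)) / 2
    expect_equal(stats::var(centre), 0, tolerance = 1e-12)
  }
})

test_that("trim-and-fill k0 agrees with metafor on a censored fixture", {
  skip_if_not_installed("metafor")
  set.seed(22)
  rec <- simulate_lnrr_studies(k = 40, true_lnrr = 0, tau2 = 0.02,
                               n_per_group = 4, cv = 0.3, seed = 22)
  cens <- rec[rank(rec$lnrr) > 5, ]
  mine <- trim_and_fill(cens, side = "left")
  ref <- metafor::trimfill(metafor::rma(yi = cens$lnrr, vi = cens$v,
                                        method = "DL"),
                           side = "left", estimator = "L0")
  expect_equal(mine$k0, as.integer(ref$k0))
})

test_that("predictor importance: bounds, duplication invariance, signal recovery", {
  set.seed(31)
  n <- 60
  rec <- tibble::tibble(
    study_id = paste0("s", 1:n), variable = "x",
    a = rnorm(n), b = rnorm(n), c = rnorm(n),
    v = runif(n, 0.005, 0.02))
  rec$lnrr <- 0.5 * rec$a + rnorm(n, 0, sqrt(rec$v))
  imp <- predictor_importance(rec, c("a", "b", "c"))
  expect_true(all(imp$importance >= 0 & imp$importance <= 1))
  expect_gt(imp$importance[imp$predictor == "a"], 0.8)
  expect_lt(max(imp$importance[imp$predictor != "a"]), 0.8)

  dup <- dplyr::bind_rows(rec, rec)
  imp2 <- predictor_importance(dup, c("a", "b", "c"))
  expect_equal(order(imp$importance), order(imp2$importance))

  rec$a2 <- rec$a
  expect_error(predictor_importance(rec, c("a", "a2", "b")), "collinear")
  expect_error(predictor_importance(rec, letters[1:7]), "at most 6")
})

test_that("effects_from_samples builds one record per study and variable", {
  b <- small_study_set(seed = 71)
  rare <- rarefy_counts(b$counts, depth = 1500, seed = 1, quiet = TRUE)
  alpha <- alpha_diversity(rare)
  rec <- effects_from_samples(alpha[, c("sample_id", "richness", "shannon")],
                              b$metadata)
  expect_equal(nrow(rec), 2 * length(unique(b$metadata$study_id)))
  expect_setequal(unique(rec$variable), c("richness", "shannon"))
  expect_true(all(rec$v >= 0))
})
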