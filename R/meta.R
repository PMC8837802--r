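# Random-effects log response ratio (lnRR) meta-analysis: per-study effect
# records, DerSimonian-Laird pooling with bootstrap CIs, percent-change
# conversion, categorical heterogeneity partitioning (Q_T = Q_W + Q_B),
# Egger regression, Duval-Tweedie trim-and-fill, and all-subsets
# AICc-weight predictor importance.

#' One study-level effect record from two groups of sample values
#'
#' lnRR = ln(X_t / X_c) with X the group means (rhizosphere = treatment,
#' bulk = control); its variance is v = S_t^2 / (n_t X_t^2) +
#' S_c^2 / (n_c X_c^2) with sample SDs. A group of size 1 contributes
#' S = 0 and is flagged; a non-positive group mean makes lnRR undefined, so
#' the record is skipped with a warning (zero rows returned).
#'
#' @param rhizo,bulk Numeric sample values of the variable in each
#'   compartment.
#' @param study_id,variable Identifiers carried into the record.
#' @return A tibble with 0 or 1 rows: study_id, variable, x_t, x_c, s_t,
#'   s_c, n_t, n_c, lnrr, v, flagged.
#' @export
effect_from_groups <- function(rhizo, bulk, study_id = NA_character_,
                               variable = NA_character_) {
  rhizo <- rhizo[!is.na(rhizo)]; bulk <- bulk[!is.na(bulk)]
  if (!length(rhizo) || !length(bulk)) abort("both groups must be non-empty.")
  x_t <- mean(rhizo); x_c <- mean(bulk)
  if (x_t <= 0 || x_c <= 0) {
    warn(sprintf("effect_from_groups: non-positive mean for %s/%s; record skipped.",
                 study_id, variable))
    return(tibble(study_id = character(), variable = character(),
                  x_t = numeric(), x_c = numeric(), s_t = numeric(),
                  s_c = numeric(), n_t = integer(), n_c = integer(),
                  lnrr = numeric(), v = numeric(), flagged = logical()))
  }
  n_t <- length(rhizo); n_c <- length(bulk)
  s_t <- if (n_t > 1) sd(rhizo) else 0
  s_c <- if (n_c > 1) sd(bulk) else 0
  flagged <- n_t == 1 || n_c == 1
  tibble(study_id = as.character(study_id), variable = as.character(variable),
         x_t = x_t, x_c = x_c, s_t = s_t, s_c = s_c,
         n_t = n_t, n_c = n_c,
         lnrr = log(x_t / x_c),
         v = s_t^2 / (n_t * x_t^2) + s_c^2 / (n_c * x_c^2),
         flagged = flagged)
}

#' Effect records for every study and variable in a per-sample table
#'
#' @param data Tibble with `sample_id` and one column per variable.
#' @param metadata Metadata tibble (sample_id, study_id, compartment).
#' @param variables Variable columns to use (default: all non-id columns).
#' @return A tibble of effect records, one row per study x variable.
#' @export
effects_from_samples <- function(data, metadata, variables = NULL) {
  metadata <- validate_metadata(metadata)
  variables <- variables %||% setdiff(names(data), "sample_id")
  joined <- dplyr::inner_join(data, metadata, by = "sample_id")
  out <- list()
  for (v in variables) {
    recs <- joined |>
      group_by(.data$study_id) |>
      dplyr::group_map(function(g, key) {
        effect_from_groups(g[[v]][g$compartment == "rhizosphere"],
                           g[[v]][g$compartment == "bulk"],
                           study_id = key$study_id, variable = v)
      })
    out[[v]] <- bind_rows(recs)
  }
  bind_rows(out)
}

# DerSimonian-Laird between-study variance, floored at 0.
dl_tau2 <- function(y, v) {
  k <- length(y)
  w0 <- 1 / pmax(v, 1e-12)
  ybar <- sum(w0 * y) / sum(w0)
  q <- sum(w0 * (y - ybar)^2)
  cc <- sum(w0) - sum(w0^2) / sum(w0)
  max(0, (q - (k - 1)) / cc)
}

# Vectorised DL pooled means for a matrix of bootstrap resamples
# (rows = resamples).
dl_pool_rows <- function(y_mat, v_mat) {
  k <- ncol(y_mat)
  w0 <- 1 / pmax(v_mat, 1e-12)
  sw <- rowSums(w0)
  ybar <- rowSums(w0 * y_mat) / sw
  q <- rowSums(w0 * (y_mat - ybar)^2)
  cc <- sw - rowSums(w0^2) / sw
  tau2 <- pmax(0, (q - (k - 1)) / cc)
  w <- 1 / (v_mat + tau2)
  rowSums(w * y_mat) / rowSums(w)
}

#' Random-effects pooling of effect records with bootstrap CIs
#'
#' Between-study variance by DerSimonian-Laird (floored at 0); pooled mean
#' with weights w_i = 1 / (v_i + tau2); 95% CI from `n_boot` nonparametric
#' bootstrap resamples of studies (percentile method, tau2 re-estimated per
#' resample). The pooled effect is also expressed as a percent change,
#' (exp(mean) - 1) * 100, with the CI bounds converted the same way.
#' Records are pooled separately per `variable`.
#'
#' @param records Effect-record tibble (>= 2 studies per variable).
#' @param n_boot Bootstrap iterations (default 999).
#' @param seed Integer seed for the resampling.
#' @param group Optional label stored in the `group` column (default
#'   "overall").
#' @return A `meta_pool` tibble: variable, group, k, mean_lnrr, tau2,
#'   ci_low, ci_high, pct_change, pct_low, pct_high, significant,
#'   degenerate.
#' @export
pool_effects <- function(records, n_boot = 999, seed = 1L, group = "overall") {
  if (!nrow(records)) abort("no effect records to pool.")
  vars <- unique(records$variable)
  rows <- vector("list", length(vars))
  for (j in seq_along(vars)) {
    rec <- records[records$variable == vars[j], ]
    y <- rec$lnrr; v <- rec$v
    k <- length(y)
    if (k < 2) abort(sprintf("variable '%s': need >= 2 studies.", vars[j]))
    tau2 <- dl_tau2(y, v)
    w <- 1 / (v + tau2)
    mu <- sum(w * y) / sum(w)
    degenerate <- all(v == 0) && var(y) == 0
    if (degenerate) {
      ci <- c(mu, mu)
    } else {
      set.seed(derive_seed(seed, j))
      idx <- matrix(sample.int(k, n_boot * k, replace = TRUE), n_boot, k)
      mu_b <- dl_pool_rows(matrix(y[idx], n_boot, k),
                           matrix(v[idx], n_boot, k))
      ci <- unname(quantile(mu_b, c(0.025, 0.975)))
    }
    rows[[j]] <- tibble(
      variable = vars[j], group = group, k = k, mean_lnrr = mu, tau2 = tau2,
      ci_low = ci[1], ci_high = ci[2],
      pct_change = (exp(mu) - 1) * 100,
      pct_low = (exp(ci[1]) - 1) * 100, pct_high = (exp(ci[2]) - 1) * 100,
      significant = ci[1] > 0 | ci[2] < 0,
      degenerate = degenerate)
  }
  out <- bind_rows(rows)
  class(out) <- c("meta_pool", class(out))
  attr(out, "n_boot") <- n_boot
  attr(out, "seed") <- seed
  out
}

#' Subgroup meta-analysis with heterogeneity partitioning
#'
#' Pools each subgroup separately (subgroups with fewer than `min_k`
#' studies are dropped and reported) and partitions the total
#' heterogeneity Q_T into within-group Q_W and between-group Q_B using the
#' random-effects weights w_i = 1 / (v_i + tau2) with tau2 estimated on all
#' surviving records. Q_B is tested against chi-square with
#' (groups - 1) df.
#'
#' @param records Effect-record tibble for one or more variables.
#' @param category Name of the column in `records` holding the subgroup
#'   label.
#' @param min_k Minimum studies per subgroup (default 10, dropped below).
#' @param n_boot,seed Bootstrap settings passed to [pool_effects()].
#' @return A list: `summaries` (a `meta_pool` tibble with one row per
#'   variable x subgroup) and `heterogeneity` (tibble variable, q_t, q_w,
#'   q_b, df_b, p_qb, groups_used).
#' @export
subgroup_analysis <- function(records, category, min_k = 10,
                              n_boot = 999, seed = 1L) {
  if (!category %in% names(records)) {
    abort(sprintf("records have no '%s' column.", category))
  }
  summaries <- list(); het <- list()
  for (v in unique(records$variable)) {
    rec <- records[records$variable == v, ]
    sizes <- table(rec[[category]])
    keep_groups <- names(sizes)[sizes >= min_k]
    dropped <- setdiff(names(sizes), keep_groups)
    if (length(dropped)) {
      log_msg("subgroup_analysis [%s]: dropped subgroup(s) with k < %d: %s",
              v, min_k, paste(dropped, collapse = ", "))
    }
    if (length(keep_groups) < 2) {
      warn(sprintf("subgroup_analysis [%s]: fewer than 2 subgroups survive; partition skipped.", v))
      next
    }
    rec <- rec[rec[[category]] %in% keep_groups, ]
    for (g in keep_groups) {
      summaries[[paste(v, g)]] <-
        pool_effects(rec[rec[[category]] == g, ], n_boot = n_boot,
                     seed = derive_seed(seed, match(g, keep_groups)),
                     group = g)
    }
    y <- rec$lnrr; vv <- rec$v
    tau2 <- dl_tau2(y, vv)
    w <- 1 / (vv + tau2)
    grand <- sum(w * y) / sum(w)
    gl <- rec[[category]]
    q_w <- 0; q_b <- 0
    for (g in keep_groups) {
      in_g <- gl == g
      mg <- sum(w[in_g] * y[in_g]) / sum(w[in_g])
      q_w <- q_w + sum(w[in_g] * (y[in_g] - mg)^2)
      q_b <- q_b + sum(w[in_g]) * (mg - grand)^2
    }
    q_t <- sum(w * (y - grand)^2)
    df_b <- length(keep_groups) - 1
    het[[v]] <- tibble(variable = v, q_t = q_t, q_w = q_w, q_b = q_b,
                       df_b = df_b,
                       p_qb = pchisq(q_b, df_b, lower.tail = FALSE),
                       groups_used = length(keep_groups))
  }
  summaries <- bind_rows(summaries)
  if (nrow(summaries)) class(summaries) <- c("meta_pool", class(summaries))
  list(summaries = summaries, heterogeneity = bind_rows(het))
}

#' Egger's regression test for funnel-plot asymmetry
#'
#' Regresses the standardized effect lnRR / sqrt(v) on the precision
#' 1 / sqrt(v); the intercept's t-test (df = k - 2) indicates small-study
#' asymmetry. Records with v = 0 are excluded with a warning.
#'
#' @param records Effect-record tibble for a single variable (k >= 3).
#' @return A one-row tibble: intercept, se, p, k.
#' @export
egger_test <- function(records) {
  zero_v <- records$v == 0
  if (any(zero_v)) {
    warn(sprintf("egger_test: excluded %d record(s) with v = 0.", sum(zero_v)))
    records <- records[!zero_v, ]
  }
  k <- nrow(records)
  if (k < 3) abort("egger_test: need >= 3 records with positive variance.")
  z <- records$lnrr / sqrt(records$v)
  prec <- 1 / sqrt(records$v)
  fit <- lm(z ~ prec)
  est <- summary(fit)$coefficients
  tibble(intercept = est[1, 1], se = est[1, 2], p = est[1, 4], k = k)
}

# DL pooled mean of (y, v).
dl_mean <- function(y, v) {
  tau2 <- dl_tau2(y, v)
  w <- 1 / (v + tau2)
  sum(w * y) / sum(w)
}

#' Duval-Tweedie trim-and-fill publication-bias correction
#'
#' Iterative rank-based (L0) estimate of the number of studies missing on
#' one funnel side; the estimated k0 most extreme studies on the observed
#' side are trimmed, the pooled centre re-estimated, and on convergence k0
#' mirror-image studies are imputed and the full set re-pooled
#' (DerSimonian-Laird throughout). The side is chosen from the sign of
#' Egger's intercept unless forced.
#'
#' @param records Effect-record tibble for one variable (k >= 3).
#' @param side Where the missing studies lie: "auto" (default; from
#'   Egger's intercept sign), "left" or "right".
#' @param max_iter Iteration cap (default 50; non-convergence is flagged).
#' @return A list of class `bias_diagnostics`: `k0`, `side`,
#'   `adjusted_mean`, `unadjusted_mean`, `converged`, `egger` (tibble from
#'   [egger_test()]), `filled` (tibble of imputed records) and `funnel`
#'   (tibble effect, precision, imputed).
#' @export
trim_and_fill <- function(records, side = c("auto", "left", "right"),
                          max_iter = 50) {
  side <- match.arg(side)
  if (nrow(records) < 3) abort("trim_and_fill: need >= 3 records.")
  egger <- egger_test(records)
  if (side == "auto") {
    # positive intercept: small studies skew positive, so the missing
    # counterparts sit on the left
    side <- if (egger$intercept > 0) "left" else "right"
  }
  y <- records$lnrr; v <- records$v
  # Missing studies on the left leave a surplus of extreme effects on the
  # right, which is the side the canonical algorithm trims; mirror the data
  # when the missing side is the right instead.
  flip <- side == "right"
  yy <- if (flip) -y else y
  k <- length(yy)
  k0 <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    keep <- seq_len(k)
    if (k0 > 0) {
      drop <- order(yy, decreasing = TRUE)[seq_len(min(k0, k - 2))]
      keep <- setdiff(keep, drop)
    }
    mu <- dl_mean(yy[keep], v[keep])
    yc <- yy - mu
    r <- rank(abs(yc))
    t_n <- sum(r[yc > 0])
    l0 <- (4 * t_n - k * (k + 1)) / (2 * k - 1)
    k0_new <- max(0L, as.integer(round(l0)))
    if (k0_new == k0) { converged <- TRUE; break }
    k0 <- k0_new
  }
  trimmed_idx <- if (k0 > 0) order(yy, decreasing = TRUE)[seq_len(min(k0, k - 2))]
                 else integer()
  mu_trim <- dl_mean(yy[setdiff(seq_len(k), trimmed_idx)],
                     v[setdiff(seq_len(k), trimmed_idx)])
  if (k0 > 0) {
    y_fill <- 2 * mu_trim - yy[trimmed_idx]
    v_fill <- v[trimmed_idx]
    y_all <- c(yy, y_fill); v_all <- c(v, v_fill)
  } else {
    y_fill <- numeric(); v_fill <- numeric()
    y_all <- yy; v_all <- v
  }
  adj <- dl_mean(y_all, v_all)
  unadj <- dl_mean(yy, v)
  if (flip) { adj <- -adj; unadj <- -unadj; y_fill <- -y_fill }
  funnel <- tibble(effect = c(y, y_fill),
                   precision = 1 / sqrt(pmax(c(v, v_fill), 1e-12)),
                   imputed = c(rep(FALSE, k), rep(TRUE, length(y_fill))))
  structure(list(k0 = k0, side = side, adjusted_mean = adj,
                 unadjusted_mean = unadj, converged = converged,
                 egger = egger,
                 filled = tibble(lnrr = y_fill, v = v_fill),
                 funnel = funnel),
            class = "bias_diagnostics")
}

#' All-subsets predictor importance via Akaike weights
#'
#' Fits every subset of up to 6 candidate predictors by variance-weighted
#' least squares (weights 1 / (v + tau2)), converts AICc values to Akaike
#' weights, and scores each predictor by the summed weight of the models
#' containing it. Predictors at or above `cutoff` (default 0.8) are flagged
#' important.
#'
#' @param records Effect-record tibble for one variable, with predictor
#'   columns; incomplete cases are dropped.
#' @param predictors Character vector (<= 6) of predictor column names.
#' @param cutoff Importance cutoff (default 0.8).
#' @return A tibble: predictor, importance, important.
#' @export
predictor_importance <- function(records, predictors, cutoff = 0.8) {
  if (length(predictors) > 6) abort("at most 6 predictors (exhaustive 2^6 model space).")
  miss <- setdiff(predictors, names(records))
  if (length(miss)) abort(sprintf("missing predictor column(s): %s",
                                  paste(miss, collapse = ", ")))
  dat <- records[, c("lnrr", "v", predictors)]
  dat <- dat[complete.cases(dat), ]
  n <- nrow(dat)
  if (n < length(predictors) + 3) abort("too few complete cases.")
  mm_full <- model.matrix(
    stats::reformulate(predictors), data = dat)
  if (kappa(scale(mm_full[, -1, drop = FALSE], scale = TRUE)) > 1e8) {
    cm <- abs(cor(mm_full[, -1, drop = FALSE]))
    diag(cm) <- 0
    worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    abort(sprintf("collinear predictors: %s and %s.",
                  colnames(cm)[worst[1]], colnames(cm)[worst[2]]))
  }
  tau2 <- dl_tau2(dat$lnrr, dat$v)
  w <- 1 / (dat$v + tau2)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), length(predictors)))
  aicc <- numeric(nrow(subsets))
  for (i in seq_len(nrow(subsets))) {
    inc <- predictors[unlist(subsets[i, ])]
    f <- if (length(inc)) stats::reformulate(inc, response = "lnrr")
         else lnrr ~ 1
    fit <- lm(f, data = dat, weights = w)
    p_n <- length(coef(fit)) + 1  # + residual variance
    ll <- as.numeric(logLik(fit))
    aicc[i] <- -2 * ll + 2 * p_n + 2 * p_n * (p_n + 1) / max(n - p_n - 1, 1)
  }
  d <- aicc - min(aicc)
  aw <- exp(-d / 2); aw <- aw / sum(aw)
  importance <- vapply(seq_along(predictors), function(j) {
    sum(aw[unlist(subsets[, j])])
  }, numeric(1))
  tibble(predictor = predictors, importance = importance,
         important = importance >= cutoff)
}
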