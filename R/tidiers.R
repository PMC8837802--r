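# broom-style tidiers for the fitted-result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a pooled meta-analysis
#'
#' @param x A `meta_pool` tibble from [pool_effects()].
#' @param ... Unused.
#' @return A tibble with broom-style columns: term (variable), group,
#'   estimate (mean lnRR), conf.low, conf.high, and the percent-change
#'   scale.
#' @method tidy meta_pool
#' @export
tidy.meta_pool <- function(x, ...) {
  tibble(term = x$variable, group = x$group, k = x$k,
         estimate = x$mean_lnrr, conf.low = x$ci_low, conf.high = x$ci_high,
         tau2 = x$tau2, pct.change = x$pct_change,
         significant = x$significant)
}

#' @rdname tidy.meta_pool
#' @method glance meta_pool
#' @export
glance.meta_pool <- function(x, ...) {
  tibble(n_variables = length(unique(x$variable)),
         n_groups = length(unique(x$group)),
         n_boot = attr(x, "n_boot") %||% NA_integer_)
}

#' Tidy publication-bias diagnostics
#'
#' @param x A `bias_diagnostics` object from [trim_and_fill()].
#' @param ... Unused.
#' @return One-row tibble: k0, side, adjusted and unadjusted pooled means,
#'   Egger intercept / se / p, converged.
#' @method tidy bias_diagnostics
#' @export
tidy.bias_diagnostics <- function(x, ...) {
  tibble(k0 = x$k0, side = x$side,
         adjusted_mean = x$adjusted_mean,
         unadjusted_mean = x$unadjusted_mean,
         egger_intercept = x$egger$intercept,
         egger_se = x$egger$se, egger_p = x$egger$p,
         converged = x$converged)
}

#' Tidy a module partition
#'
#' @param x A `rhizo_modules` object from [greedy_modules()].
#' @param ... Unused.
#' @return The membership tibble (taxon_id, module).
#' @method tidy rhizo_modules
#' @export
tidy.rhizo_modules <- function(x, ...) x$membership

#' @rdname tidy.rhizo_modules
#' @method glance rhizo_modules
#' @export
glance.rhizo_modules <- function(x, ...) {
  tibble(modularity = x$modularity, n_modules = x$n_modules)
}

#' Tidy a PCoA ordination
#'
#' @param x A `rhizo_pcoa` object from [pcoa_ordination()].
#' @param ... Unused.
#' @return The coordinate tibble.
#' @method tidy rhizo_pcoa
#' @export
tidy.rhizo_pcoa <- function(x, ...) x$coordinates

#' @rdname tidy.rhizo_pcoa
#' @method glance rhizo_pcoa
#' @export
glance.rhizo_pcoa <- function(x, ...) {
  tibble(n_axes = ncol(x$coordinates) - 1,
         negative_eigenvalues = sum(x$eigenvalues < 0),
         prop_axis1 = x$prop_explained[1],
         prop_axis2 = if (length(x$prop_explained) > 1) x$prop_explained[2]
                      else NA_real_)
}

#' @export
print.rhizo_modules <- function(x, ...) {
  cat(sprintf("Module partition: %d modules, Q = %.4f, %d nodes\n",
              x$n_modules, x$modularity, nrow(x$membership)))
  invisible(x)
}

#' @export
print.bias_diagnostics <- function(x, ...) {
  cat(sprintf(
    "Trim-and-fill: k0 = %d missing on the %s, pooled lnRR %.4f -> %.4f (Egger p = %.3g)\n",
    x$k0, x$side, x$unadjusted_mean, x$adjusted_mean, x$egger$p))
  invisible(x)
}
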