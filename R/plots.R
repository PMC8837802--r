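# ggplot2 diagnostics for each result type.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_hline
#'   geom_vline geom_errorbarh labs theme_minimal geom_col coord_flip
#'   geom_errorbar facet_wrap
#' @export
ggplot2::autoplot

#' Forest-style plot of pooled effects
#'
#' Percent change with 95% bootstrap CI per variable (and subgroup).
#'
#' @param object A `meta_pool` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot meta_pool
#' @export
autoplot.meta_pool <- function(object, ...) {
  ggplot(object, aes(x = .data$pct_change, y = .data$variable,
                     colour = .data$significant)) +
    geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    geom_point() +
    geom_errorbarh(aes(xmin = .data$pct_low, xmax = .data$pct_high),
                   height = 0.2) +
    facet_wrap(~ group) +
    labs(x = "Rhizosphere effect (% change vs bulk soil)", y = NULL,
         colour = "CI excludes 0") +
    theme_minimal()
}

#' Plot a robustness degradation curve
#'
#' @param curve Tibble from [robustness_curve()], optionally with a
#'   `network` column to compare several curves.
#' @return A ggplot of natural connectivity vs fraction of nodes removed.
#' @export
plot_robustness <- function(curve) {
  p <- ggplot(curve, aes(x = .data$fraction_removed,
                         y = .data$natural_connectivity))
  if ("network" %in% names(curve)) {
    p <- p + geom_line(aes(colour = .data$network))
  } else {
    p <- p + geom_line()
  }
  p + labs(x = "Fraction of nodes removed", y = "Natural connectivity") +
    theme_minimal()
}

#' Zi-Pi node role plot
#'
#' Scatter of within-module degree z-score against participation
#' coefficient with the hub/connector threshold lines (2.5, 0.62).
#'
#' @param roles Tibble from [node_roles()].
#' @return A ggplot.
#' @export
plot_zi_pi <- function(roles) {
  ggplot(roles, aes(x = .data$pi, y = .data$zi, colour = .data$category)) +
    geom_point() +
    geom_hline(yintercept = 2.5, linetype = 2, colour = "grey50") +
    geom_vline(xintercept = 0.62, linetype = 2, colour = "grey50") +
    labs(x = "Participation coefficient (Pi)",
         y = "Within-module degree z-score (Zi)", colour = "Role") +
    theme_minimal()
}

#' Ordination plot
#'
#' @param object A `rhizo_pcoa` object.
#' @param metadata Optional metadata tibble; points are coloured by
#'   compartment when present.
#' @param ... Unused.
#' @return A ggplot of the first two axes.
#' @method autoplot rhizo_pcoa
#' @export
autoplot.rhizo_pcoa <- function(object, metadata = NULL, ...) {
  df <- object$coordinates
  if (!is.null(metadata)) {
    df <- left_join(df, metadata, by = "sample_id")
  }
  p <- ggplot(df, aes(x = .data$axis1, y = .data$axis2))
  p <- if (!is.null(metadata) && "compartment" %in% names(df)) {
    p + geom_point(aes(colour = .data$compartment))
  } else {
    p + geom_point()
  }
  p + labs(x = sprintf("PCoA 1 (%.1f%%)", 100 * object$prop_explained[1]),
           y = sprintf("PCoA 2 (%.1f%%)", 100 * object$prop_explained[2])) +
    theme_minimal()
}

#' Funnel plot of a meta-analysis with trim-and-fill imputations
#'
#' @param diagnostics A `bias_diagnostics` object from [trim_and_fill()].
#' @return A ggplot of effect vs precision; imputed studies are hollow.
#' @export
plot_funnel <- function(diagnostics) {
  ggplot(diagnostics$funnel,
         aes(x = .data$effect, y = .data$precision,
             shape = .data$imputed)) +
    geom_point() +
    geom_vline(xintercept = diagnostics$adjusted_mean, linetype = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1)) +
    labs(x = "lnRR", y = "Precision (1 / SE)", shape = "Imputed") +
    theme_minimal()
}
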