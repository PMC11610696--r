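## ggplot2 views of the three result types: correlation heatmap (Ward
## ordered), forest plot of pooled effects, and the effect-class matrix.

#' Correlation heatmap ordered by Ward clustering
#'
#' @param object An `avg_correlations` object.
#' @param order Optional indicator ordering (e.g. from
#'   [ward_cluster_order()]); computed internally when omitted.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.avg_correlations <- function(object, order = NULL, ...) {
  ord <- order %||% ward_cluster_order(object)$order
  df <- .mat_to_tbl(object$mean, "mean_rho")
  df <- df[df$indicator %in% ord & df$indicator2 %in% ord, ]
  df$indicator <- factor(df$indicator, levels = ord)
  df$indicator2 <- factor(df$indicator2, levels = ord)
  ggplot2::ggplot(df, ggplot2::aes(.data$indicator, .data$indicator2,
                                   fill = .data$mean_rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1),
                                  name = "mean Spearman") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Forest plot of pooled indicator responses
#'
#' @param object A `benthic_meta` object.
#' @param subgroups Subgroup labels to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.benthic_meta <- function(object, subgroups = "all", ...) {
  df <- object$pooled[object$pooled$subgroup %in% subgroups, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$estimate, .data$indicator)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lb,
                                         xmax = .data$ci_ub),
                            height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant),
                        size = 2) +
    ggplot2::facet_wrap(~subgroup) +
    ggplot2::labs(x = "pooled ln response ratio", y = NULL) +
    ggplot2::theme_minimal()
}

#' Effect-class matrix plot
#'
#' @param object An `effect_matrix` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.effect_matrix <- function(object, ...) {
  df <- object$trends
  df$indicator <- factor(df$indicator, levels = rev(.indicator_levels))
  ggplot2::ggplot(df, ggplot2::aes(.data$gradient_id, .data$indicator,
                                   fill = .data$effect_class)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(
      decline = "#b2182b", increase = "#2166ac",
      no_effect = "grey85", not_evaluated = "white"), name = NULL) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
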