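#' Plot a squeal comparison
#'
#' A parameter-by-animal overview of the adjusted one-sided p-values:
#' points at `-log10(p_adj)` with the FDR level marked, faceted by animal.
#'
#' @param object A `squeal_comparison` from [compare_phases()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot squeal_comparison
#' @export
autoplot.squeal_comparison <- function(object, ...) {
  res <- tidy(object)
  res$parameter <- factor(res$parameter, levels = aperiodic_parameters())
  ggplot2::ggplot(
    res,
    ggplot2::aes(
      x = .data$parameter, y = -log10(pmax(.data$p_adj, 1e-16)),
      shape = .data$direction, colour = .data$significant
    )
  ) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_hline(
      yintercept = -log10(object$alpha), linetype = "dashed"
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$pig_id)) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "firebrick", `FALSE` = "grey40")
    ) +
    ggplot2::labs(
      x = NULL, y = expression(-log[10](p[adj])),
      colour = "significant", shape = "expected direction",
      title = "Pre/post parameter shifts per animal (BY-corrected)"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Boxplots of parameter values by phase
#'
#' Per-animal pre/post boxplots for a chosen set of parameters — the
#' standard way to eyeball which parameters separate the phases before
#' looking at p-values.
#'
#' @param features A feature table from [extract_features()].
#' @param parameters Which parameter columns to plot (default: the
#'   frequency-location family).
#' @return A ggplot object.
#' @export
plot_parameter_boxplots <- function(features,
                                    parameters = c(
                                      "PF", "Q50", "Q50_2", "Q50_10",
                                      "Q50_min", "Q50W", "Q25"
                                    )) {
  stopifnot(is.data.frame(features))
  long <- tidyr::pivot_longer(
    features[, c("pig_id", "phase", intersect(parameters, names(features)))],
    cols = -c("pig_id", "phase"),
    names_to = "parameter", values_to = "value"
  )
  long$phase <- factor(long$phase, levels = c("pre", "post"))
  long$parameter <- factor(long$parameter, levels = parameters)
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$parameter, y = .data$value, fill = .data$phase)
  ) +
    ggplot2::geom_boxplot(position = ggplot2::position_dodge(width = 0.8)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$pig_id), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "parameter value", fill = "phase") +
    ggplot2::theme_minimal()
}
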