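#' Volcano plot of a differential test
#'
#' @param object A `te_diff` fit.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.te_diff <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$log2fc, -log10(.data$pvalue),
                                  colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(
      values = c(up = "#d95f02", down = "#1b9e77", ns = "grey60")) +
    ggplot2::labs(x = "log2 fold change (exposed vs control)",
                  y = "-log10 p", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Dot plot of enrichment ratios
#'
#' @param enrichment Enrichment tibble from [subfamily_enrichment()] or
#'   [class_enrichment_shared()].
#' @param top Show at most this many units, by ratio.
#' @return A ggplot.
#' @export
plot_enrichment <- function(enrichment, top = 20) {
  d <- enrichment |>
    arrange(dplyr::desc(.data$ratio)) |>
    head(top) |>
    mutate(name = factor(.data$name, levels = rev(.data$name)))
  ggplot2::ggplot(d, ggplot2::aes(.data$ratio, .data$name,
                                  size = .data$count_in_set)) +
    ggplot2::geom_point(colour = "#7570b3") +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "fold enrichment over genome background", y = NULL,
                  size = "copies in set") +
    ggplot2::theme_minimal()
}

#' Per-column conservation profiles of motif-bearing vs motif-lacking copies
#'
#' @param groups Result of [motif_presence_groups()].
#' @param core_region Optional 0-based half-open consensus interval to shade.
#' @return A ggplot.
#' @export
plot_conservation <- function(groups, core_region = NULL) {
  g <- ggplot2::ggplot(groups$profiles,
                       ggplot2::aes(.data$column, .data$identity,
                                    colour = .data$group)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "consensus position", y = "identity to consensus",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(core_region)) {
    g <- g + ggplot2::annotate("rect", xmin = core_region[1] + 1,
                               xmax = core_region[2], ymin = -Inf, ymax = Inf,
                               alpha = 0.12, fill = "#e7298a")
  }
  g
}

#' Paired per-subfamily methylation contrast
#'
#' @param contrast Result of [methylation_contrast()].
#' @return A ggplot.
#' @export
plot_methylation_contrast <- function(contrast) {
  d <- contrast$per_subfamily |>
    tidyr::pivot_longer(c("mean_control", "mean_exposed"),
                        names_to = "condition", values_to = "methylation") |>
    mutate(condition = sub("mean_", "", .data$condition))
  ggplot2::ggplot(d, ggplot2::aes(.data$condition, .data$methylation)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$subfamily),
                       alpha = 0.4, colour = "grey50") +
    ggplot2::geom_boxplot(width = 0.25, outlier.shape = NA, fill = NA) +
    ggplot2::labs(x = NULL, y = "mean TE methylation") +
    ggplot2::theme_minimal()
}
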