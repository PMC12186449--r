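# ggplot2 views of the main result types.

#' Plot a normalised copy-number bin track with segments
#'
#' Bins are drawn as points along the genome (faceted by chromosome) with
#' segment means overlaid as horizontal lines, coloured by copy state when
#' segments are classified.
#'
#' @param track Normalised bin tibble.
#' @param segments Optional segment tibble (classified or not).
#' @return A ggplot object.
#' @export
plot_cnv_track <- function(track, segments = NULL) {
  p <- ggplot2::ggplot(track[is.na(track$dropped), ],
                       ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                    y = .data$log2)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5, colour = "grey40") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "log2 ratio") +
    ggplot2::theme_minimal()
  if (!is.null(segments)) {
    mapping <- if ("state" %in% names(segments)) {
      ggplot2::aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                   y = .data$mean_log2, yend = .data$mean_log2,
                   colour = .data$state)
    } else {
      ggplot2::aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                   y = .data$mean_log2, yend = .data$mean_log2)
    }
    p <- p + ggplot2::geom_segment(data = segments, mapping = mapping,
                                   linewidth = 1.2, inherit.aes = FALSE)
    if ("state" %in% names(segments)) {
      p <- p + ggplot2::scale_colour_manual(values = c(
        deletion = "#08306b", loss = "#4292c6", neutral = "grey60",
        gain = "#ef6548", amplification = "#990000"), drop = FALSE)
    }
  }
  p
}

#' Plot the beta-value distribution
#'
#' Histogram of beta values, optionally split by imputation status — the
#' standard check that imputed values preserve the bimodal shape of CpG
#' methylation.
#'
#' @param beta Long beta tibble (`beta`, optionally `imputed`).
#' @param by_imputed Facet by the `imputed` flag when present.
#' @return A ggplot object.
#' @export
plot_beta_distribution <- function(beta, by_imputed = TRUE) {
  d <- beta[!is.na(beta$beta), ]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$beta)) +
    ggplot2::geom_histogram(bins = 60, fill = "#4292c6", colour = NA) +
    ggplot2::labs(x = "beta value", y = "CpGs") +
    ggplot2::theme_minimal()
  if (by_imputed && "imputed" %in% names(d) && any(d$imputed)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(
      ifelse(d$imputed, "imputed", "observed")), scales = "free_y")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot method for cohort imputation results
#'
#' Per-sample held-out RMSE as a dot plot.
#'
#' @param object A `methyl_imputation` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot methyl_imputation
#' @export
autoplot.methyl_imputation <- function(object, ...) {
  ggplot2::ggplot(object$report,
                  ggplot2::aes(x = .data$rmse, y = .data$sample)) +
    ggplot2::geom_point(colour = "#ef6548", size = 2) +
    ggplot2::labs(x = "held-out RMSE", y = NULL) +
    ggplot2::theme_minimal()
}
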