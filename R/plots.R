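#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Manhattan plot of adjusted anomaly p-values
#'
#' @param pvals A [score_pvalues()] tibble (or anything [manhattan_table()]
#'   accepts).
#' @param alpha Threshold drawn as a horizontal line (default `5e-8`).
#' @return A ggplot object.
#' @export
plot_manhattan <- function(pvals, alpha = 5e-8) {
  tab <- manhattan_table(pvals, alpha)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$center_position / 1e6,
                                    y = .data$neg_log10_p,
                                    colour = .data$significant)) +
    ggplot2::geom_point(size = 0.4, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(alpha), colour = "red",
                        linetype = "dashed") +
    ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "orange")) +
    ggplot2::labs(x = "Window centre position (Mb)",
                  y = expression(-log[10](italic(p)[adj]))) +
    ggplot2::theme_minimal()
}

#' Plot an MLG diversity image
#'
#' Greyscale raster of the image matrix: dark = homozygous major (0),
#' bright = homozygous minor (2), intermediate = heterozygous.  Rows
#' (MLG ranks) are drawn top to bottom in ascending mean genotype value.
#'
#' @param img A [diversity_image()].
#' @return A ggplot object.
#' @export
plot_diversity_image <- function(img) {
  stopifnot(inherits(img, "diversity_image"))
  df <- tidyr::expand_grid(row = seq_len(nrow(img)), snp = seq_len(ncol(img)))
  df$value <- as.vector(unclass(img))[(df$snp - 1L) * nrow(img) + df$row]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$snp, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 2), name = "mean\nminor count") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "SNP", y = "MLG (sorted)",
                  title = attr(img, "label")) +
    ggplot2::theme_minimal()
}

#' @rdname plot_manhattan
#' @param object An [mlg_scan()] object.
#' @param ... Unused.
#' @export
autoplot.mlg_scan <- function(object, ...) {
  tab <- tidy(object)
  tab$neg_log10_p <- -log10(tab$p_adjusted)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$center_position / 1e6,
                                    y = .data$neg_log10_p,
                                    colour = .data$significant)) +
    ggplot2::geom_point(size = 0.4, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(object$config$alpha),
                        colour = "red", linetype = "dashed") +
    ggplot2::facet_grid(method ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "orange")) +
    ggplot2::labs(x = "Window centre position (Mb)",
                  y = expression(-log[10](italic(p)[adj]))) +
    ggplot2::theme_minimal()
}
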