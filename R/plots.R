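# ggplot2 views of profiles, domainograms, K curves and Hi-C matrices.

#' Plot a 4C contact profile
#'
#' Signal density along each chromosome, with the viewpoint marked and called
#' BRICKs overlaid as shaded intervals.
#'
#' @param profile A `fourc_profile`.
#' @param bricks Optional `bricks` tibble to overlay.
#' @param log_y Log10-scale the density axis.
#' @return A ggplot object.
#' @export
plot_profile <- function(profile, bricks = NULL, log_y = FALSE) {
  df <- profile[!profile$masked, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                        y = .data$density)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "signal density")
  vp <- attr(profile, "viewpoint")
  if (!is.null(vp)) {
    p <- p + ggplot2::geom_vline(
      data = tibble(chrom = vp$chrom, x = (vp$start + vp$end) / 2),
      ggplot2::aes(xintercept = .data$x), colour = "red", linetype = 2)
  }
  if (!is.null(bricks) && nrow(bricks) > 0) {
    p <- p + ggplot2::geom_rect(
      data = bricks, inherit.aes = FALSE, alpha = 0.25, fill = "steelblue",
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf))
  }
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot a domainogram
#'
#' Multi-scale heat map of window -log10 p-values by start position and
#' window width.
#'
#' @param domainogram A `domainogram` tibble.
#' @return A ggplot object.
#' @export
plot_domainogram <- function(domainogram) {
  df <- as_tibble(domainogram)
  df$score <- pmin(-log10(pmax(df$p, 1e-300)), 300)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$width,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::scale_fill_viridis_c(name = "-log10 p") +
    ggplot2::labs(x = "fragment (unmasked rank)", y = "window width")
}

#' Plot a Knet curve
#'
#' @param object A `knet_result`.
#' @param ... Unused.
#' @return A ggplot of K(s) against the shortest-path distance threshold.
#' @export
autoplot.knet_result <- function(object, ...) {
  ggplot2::ggplot(object$k, ggplot2::aes(x = .data$s, y = .data$k)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "shortest-path distance s", y = "K(s)",
                  title = sprintf("AUK = %.3f%s", object$auk,
                                  if (!is.na(object$p_value))
                                    sprintf(", permutation p = %.3g", object$p_value)
                                  else ""))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a Hi-C contact matrix
#'
#' @param m Symmetric matrix.
#' @param log_scale Log10 the fill scale.
#' @return A ggplot heat map.
#' @export
plot_hic_matrix <- function(m, log_scale = TRUE) {
  df <- as_tibble(expand.grid(i = seq_len(nrow(m)), j = seq_len(ncol(m))))
  df$value <- m[cbind(df$i, df$j)]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(na.value = "grey80",
                                  trans = if (log_scale) "log10" else "identity") +
    ggplot2::labs(x = "bin", y = "bin")
  p
}
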