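#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.narnea_result <- function(x, ...) {
  out <- x
  class(out) <- class(tibble::tibble())
  out
}

#' @export
glance.narnea_result <- function(x, ...) {
  tibble::tibble(
    n_regulons = nrow(x),
    n_sig_raw = sum(x$p < 0.05, na.rm = TRUE),
    n_sig_bh = sum(x$p_bh < 0.05, na.rm = TRUE),
    n_sig_bonf = sum(x$p_bonf < 0.05, na.rm = TRUE),
    median_abs_nes = median(abs(x$nes), na.rm = TRUE)
  )
}

#' Differential-activity volcano plot
#'
#' Plots `|NES|` (evidence) against the PES effect size for every regulon,
#' highlighting the ones significant after BH adjustment.
#'
#' @param object A [narnea()] result.
#' @param threshold BH significance threshold to highlight (default 0.05).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.narnea_result <- function(object, threshold = 0.05, ...) {
  df <- tidy(object)
  df$significant <- df$p_bh < threshold
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pes, y = abs(.data$nes),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                                 name = paste0("FDR < ", threshold)) +
    ggplot2::labs(x = "Proportional Enrichment Score",
                  y = "|Normalized Enrichment Score|") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.narnea_result
#' @export
plot_volcano <- function(object, threshold = 0.05) {
  autoplot.narnea_result(object, threshold = threshold)
}

#' Residual map of a 3x3 agreement analysis
#'
#' Tile plot of the adjusted standardized residuals with observed and
#' expected counts printed per cell.
#'
#' @param object A [contingency_analysis()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.narnea_contingency <- function(object, ...) {
  df <- tidy(object)
  df$label <- sprintf("Obs %d\nExp %.1f", df$observed, df$expected)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_gradient2(low = "steelblue", high = "firebrick",
                                  mid = "white", name = "residual z") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Diagnostic plot of an APMI null model
#'
#' Histogram of the null MI draws with the body/tail junction and the
#' fitted tail on the log10 survival scale.
#'
#' @param null An [fit_mi_null()] model.
#' @return A ggplot object.
#' @export
plot_mi_null <- function(null) {
  stopifnot(inherits(null, "mi_null"))
  grid <- seq(0, max(null$body) * 1.1, length.out = 300)
  df <- tibble::tibble(mi = grid, p = p_mi(null, grid))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mi, y = log10(.data$p))) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = null$q95, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "mutual information (nats)",
                  y = "log10 null tail probability") +
    ggplot2::theme_minimal()
}
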