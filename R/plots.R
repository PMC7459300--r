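#' Plot a clonal repeat spectrum
#'
#' Normalized number of clonotypes against clone size, on a log10 x axis.
#'
#' @param object A [repeat_spectrum()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot repeat_spectrum
#' @export
autoplot.repeat_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$size,
                                       y = .data$norm_clonotypes)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "cells per clonotype",
                  y = "normalized number of clonotypes") +
    ggplot2::theme_minimal()
}

#' Plot a CDR3 sequence-composition logo matrix
#'
#' Stacked per-position residue frequencies colored by hydropathy class
#' (hydrophilic / neutral / hydrophobic), the information a sequence logo
#' conveys without glyph scaling.
#'
#' @param object A [composition_logo()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot logo_matrix
#' @export
autoplot.logo_matrix <- function(object, ...) {
  ggplot2::ggplot(object$tidy,
                  ggplot2::aes(x = factor(.data$position), y = .data$freq,
                               fill = .data$hydropathy,
                               label = .data$residue)) +
    ggplot2::geom_col(color = "grey30", linewidth = 0.1) +
    ggplot2::scale_fill_manual(values = c(hydrophilic = "#2166ac",
                                          neutral = "#1b7837",
                                          hydrophobic = "grey10")) +
    ggplot2::labs(x = "CDR3 position", y = "relative frequency",
                  title = sprintf("modal length %d (%d sequences)",
                                  object$modal_length, object$n_seqs)) +
    ggplot2::theme_minimal()
}

#' Plot CDR3 length distributions
#'
#' @param hist Tibble from [cdr3_length_hist()].
#' @return A ggplot object.
#' @export
plot_cdr3_lengths <- function(hist) {
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$length, y = .data$n,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "CDR3 length (aa)", y = "number of cells") +
    ggplot2::theme_minimal()
}

#' Plot per-cluster Shannon equitability
#'
#' @param eq Tibble from [cluster_equitability()].
#' @return A ggplot object.
#' @export
plot_equitability <- function(eq) {
  ggplot2::ggplot(eq, ggplot2::aes(x = .data$cluster, y = .data$equitability,
                                   group = 1)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "cluster", y = "Shannon equitability") +
    ggplot2::theme_minimal()
}

#' Plot the null distribution of an overlap test
#'
#' @param object An [overlap_test()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot overlap_test
#' @export
autoplot.overlap_test <- function(object, ...) {
  nd <- tibble::tibble(
    k = seq(max(0, floor(object$null_mean - 5 * object$null_sd)),
            max(object$observed, ceiling(object$null_mean +
                                           5 * object$null_sd)))
  )
  ggplot2::ggplot(nd, ggplot2::aes(x = .data$k)) +
    ggplot2::geom_vline(xintercept = object$null_mean, linetype = 2) +
    ggplot2::geom_vline(xintercept = object$observed, color = "red") +
    ggplot2::annotate("text", x = object$observed, y = 0.5,
                      label = sprintf("observed k = %d (p = %.3g)",
                                      object$observed, object$p_empirical),
                      hjust = -0.05) +
    ggplot2::labs(x = "overlap under the null (mean dashed)", y = NULL) +
    ggplot2::theme_minimal()
}
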