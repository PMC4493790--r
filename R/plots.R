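#' Plot amplification curves of a plate
#'
#' Baseline-uncorrected fluorescence against cycle, one line per well,
#' facetted by sample and coloured by assay. Log-scaling the y axis shows
#' the exponential phase as a straight segment.
#'
#' @param plate Long-format plate tibble ([read_plate()] /
#'   [simulate_plate()]).
#' @param log_y Log10-scale the fluorescence axis (default `TRUE`).
#' @returns A ggplot object.
#' @export
plot_amplification <- function(plate, log_y = TRUE) {
  p <- ggplot2::ggplot(plate,
                       ggplot2::aes(x = .data$cycle, y = .data$fluorescence,
                                    group = .data$well,
                                    colour = .data$assay)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(ggplot2::vars(.data$sample, .data$locus)) +
    ggplot2::labs(x = "cycle", y = "fluorescence", colour = "assay") +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot dosage scores per sample and locus
#'
#' Presence scores (out of 10) as a tile map; calls without a score
#' (inconclusive / repeat without scores) are shown hollow.
#'
#' @param calls Dosage call table from [call_dosage()].
#' @returns A ggplot object.
#' @export
plot_dosage <- function(calls) {
  ggplot2::ggplot(calls,
                  ggplot2::aes(x = .data$locus, y = .data$sample,
                               fill = .data$presence_score)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$presence_score), .data$status,
                     sprintf("%.1f", .data$presence_score))), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8",
                                 limits = c(0, 10), na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "presence\nscore") +
    ggplot2::theme_minimal()
}

#' @rdname plot_amplification
#' @param object,... Autoplot interface: a plate tibble.
#' @export
autoplot.tedose_plate <- function(object, ...) plot_amplification(object, ...)

#' Plot a fitted amplification reaction
#'
#' Corrected log10 fluorescence with the selected window of linearity and
#' the fitted exponential slope overlaid.
#'
#' @param object A `tedose_fit` from [fit_reaction()].
#' @param ... Unused.
#' @returns A ggplot object.
#' @export
autoplot.tedose_fit <- function(object, ...) {
  corrected <- object$fluorescence - object$baseline
  d <- tibble(cycle = seq_along(corrected), corrected = corrected) |>
    dplyr::filter(.data$corrected > 0)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$cycle, log10(.data$corrected))) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "cycle", y = "log10 corrected fluorescence") +
    ggplot2::theme_minimal()
  if (object$amplified) {
    w <- dplyr::filter(d, .data$cycle >= object$window_start,
                       .data$cycle <= object$window_end)
    fitline <- stats::lm(log10(corrected) ~ cycle, data = w)
    p <- p +
      ggplot2::geom_point(data = w, colour = "#d95f02", size = 2.5) +
      ggplot2::geom_abline(intercept = stats::coef(fitline)[1],
                           slope = stats::coef(fitline)[2],
                           colour = "#d95f02")
  }
  p
}

#' Plot an ultrametric dosage-profile dendrogram
#'
#' Thin wrapper over [ape::plot.phylo()] showing bootstrap support as node
#' labels when present.
#'
#' @param x A `tedose_dendrogram` from [upgma()] or [bootstrap_support()].
#' @param ... Passed to [ape::plot.phylo()].
#' @export
plot.tedose_dendrogram <- function(x, ...) {
  class(x) <- "phylo"
  ape::plot.phylo(x, ...)
  if (!is.null(x$node.label)) ape::nodelabels(x$node.label, frame = "none",
                                              adj = c(1.1, -0.5), cex = 0.7)
  invisible(x)
}
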