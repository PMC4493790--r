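#' Tidy a fitted amplification reaction
#'
#' @param x A `tedose_fit` from [fit_reaction()].
#' @param ... Unused.
#' @returns One row per cycle with the raw and baseline-corrected signal
#'   and whether the cycle lies in the fitted window of linearity.
#' @export
tidy.tedose_fit <- function(x, ...) {
  corrected <- x$fluorescence - x$baseline
  logc <- rep(NA_real_, length(corrected))
  logc[corrected > 0] <- log10(corrected[corrected > 0])
  tibble(
    cycle = seq_along(x$fluorescence),
    fluorescence = x$fluorescence,
    corrected = corrected,
    log10_corrected = logc,
    in_window = x$amplified &
      dplyr::between(seq_along(x$fluorescence), x$window_start, x$window_end)
  )
}

#' Summarise a fitted amplification reaction in one row
#'
#' @param x A `tedose_fit` from [fit_reaction()].
#' @param ... Unused.
#' @returns A one-row tibble with `baseline`, `efficiency_fold`,
#'   `efficiency_pct`, `window_start`, `window_end`, `r2`, `ct`,
#'   `amplified`.
#' @export
glance.tedose_fit <- function(x, ...) {
  tibble(
    baseline = x$baseline,
    efficiency_fold = x$efficiency_fold,
    efficiency_pct = x$efficiency_pct,
    window_start = x$window_start,
    window_end = x$window_end,
    r2 = x$r2,
    ct = x$ct,
    amplified = x$amplified
  )
}

#' Tidy a dosage-profile dendrogram
#'
#' @param x A `tedose_dendrogram` from [upgma()] or [bootstrap_support()].
#' @param ... Unused.
#' @returns One row per internal node: `node`, `height` (half the merge
#'   distance), `n_leaves` in the clade, and percent bootstrap `support`
#'   when computed (`NA` for the root and for plain [upgma()] trees).
#' @export
tidy.tedose_dendrogram <- function(x, ...) {
  sup <- attr(x, "support")
  if (!is.null(sup)) return(sup)
  merges <- attr(x, "merges")
  tibble(
    node = attr(x, "clade_nodes"),
    height = merges$height,
    n_leaves = vapply(attr(x, "clades"), length, 0L),
    support = NA_real_
  )
}

#' Summarise a dosage-profile dendrogram in one row
#'
#' @param x A `tedose_dendrogram`.
#' @param ... Unused.
#' @returns A one-row tibble: `n_samples`, `n_nodes`, tree `depth` (root
#'   height) and `mean_support` over supported internal nodes.
#' @export
glance.tedose_dendrogram <- function(x, ...) {
  td <- tidy(x)
  tibble(
    n_samples = length(x$tip.label),
    n_nodes = nrow(td),
    depth = max(td$height),
    mean_support = if (all(is.na(td$support))) NA_real_
                   else mean(td$support, na.rm = TRUE)
  )
}
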