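#' Estimate the baseline fluorescence of one amplification curve
#'
#' The baseline is the mean fluorescence over the ground phase, cycles
#' `3..ground_cycles`; cycles 1-2 are excluded because they commonly carry
#' instrument settling artifacts. Subtracting the baseline from the raw
#' readings yields the corrected signal used for the log-linear fit and Ct
#' calling; corrected values that are not strictly positive are unusable for
#' the log transform and are dropped by [find_linear_window()].
#'
#' @param fluorescence Numeric vector of raw readings, one per cycle
#'   starting at cycle 1.
#' @param ground_cycles Last cycle of the ground phase (default 10); must
#'   leave at least 4 further cycles for the exponential-phase fit.
#' @returns The baseline fluorescence (scalar).
#' @export
#' @examples
#' estimate_baseline(rep(5, 40))            # flat signal -> 5
#' estimate_baseline(c(rep(2, 10), 2 + 0.5 * 1.9^(1:30)), ground_cycles = 8)
estimate_baseline <- function(fluorescence, ground_cycles = 10) {
  stopifnot(is.numeric(fluorescence), ground_cycles >= 3)
  if (length(fluorescence) < ground_cycles + 4) {
    abort("curve shorter than ground_cycles + 4 cycles",
          class = "tedose_malformed_input")
  }
  if (!all(is.finite(fluorescence))) {
    abort("non-finite fluorescence readings", class = "tedose_malformed_input")
  }
  mean(fluorescence[3:ground_cycles])
}

#' Find the window of linearity of a log-fluorescence curve
#'
#' Searches all contiguous windows of 4-6 consecutive cycles among the
#' usable points (strictly positive corrected fluorescence) for the window
#' maximizing the linear-fit R-squared of log10 fluorescence on cycle,
#' subject to a positive slope. Ties on R-squared are broken by the larger
#' slope, then by the earliest start cycle. This is the slope-of-the-
#' exponential-portion principle used for per-reaction efficiency
#' estimation.
#'
#' @param cycle Integer cycles of the usable points.
#' @param log_fluor `log10` corrected fluorescence at those cycles.
#' @returns A list with `start`, `end`, `slope`, `r2`, or `NULL` when no
#'   window with a positive slope exists (a non-amplifying signal, flagged
#'   rather than raised).
#' @export
find_linear_window <- function(cycle, log_fluor) {
  stopifnot(length(cycle) == length(log_fluor))
  keep <- is.finite(log_fluor)
  cycle <- as.integer(cycle[keep])
  log_fluor <- log_fluor[keep]
  if (length(cycle) < 4) return(NULL)
  ord <- order(cycle)
  cycle <- cycle[ord]
  log_fluor <- log_fluor[ord]

  best <- NULL
  tol <- 1e-12
  n <- length(cycle)
  for (i in seq_len(n)) {
    for (len in 4:6) {
      j <- i + len - 1L
      if (j > n) break
      # window must be consecutive cycles
      if (cycle[j] - cycle[i] != len - 1L) next
      x <- cycle[i:j]
      y <- log_fluor[i:j]
      xb <- mean(x); yb <- mean(y)
      sxx <- sum((x - xb)^2)
      sxy <- sum((x - xb) * (y - yb))
      syy <- sum((y - yb)^2)
      if (syy <= 0) next
      slope <- sxy / sxx
      if (slope <= 0) next
      r2 <- sxy^2 / (sxx * syy)
      cand <- list(start = x[1], end = x[len], slope = slope, r2 = r2)
      if (is.null(best) ||
          r2 > best$r2 + tol ||
          (abs(r2 - best$r2) <= tol && slope > best$slope + tol)) {
        best <- cand
      }
    }
  }
  best
}

#' Fit one amplification reaction
#'
#' Full per-well analysis of a raw fluorescence curve: baseline estimation,
#' window-of-linearity search on the log10 corrected signal, amplification
#' efficiency from the fitted slope (`efficiency_fold = 10^slope`, percent
#' efficiency `(fold - 1) * 100`), and fractional Ct at a fluorescence
#' threshold. A reaction is called amplified only when a positive-slope
#' window with R-squared at least `min_r2` exists; otherwise efficiency and
#' Ct are absent.
#'
#' @param fluorescence Numeric vector of raw readings, cycle 1 onward.
#' @param ground_cycles Ground-phase end cycle for [estimate_baseline()].
#' @param threshold Ct threshold in baseline-corrected fluorescence units
#'   (default 1.0; the method is insensitive to the choice within the
#'   exponential phase).
#' @param min_r2 Minimum acceptable window R-squared (default 0.99) below
#'   which the reaction is flagged not amplified.
#' @returns An object of class `tedose_fit`: a list with `baseline`,
#'   `slope`, `efficiency_fold`, `efficiency_pct`, `window_start`,
#'   `window_end`, `r2`, `ct`, `ct_reliable`, `amplified`, and the input
#'   curve. Has [tidy()] and [glance()] methods.
#' @export
#' @examples
#' curve <- simulate_curve(efficiency_fold = 2, ct = 24, seed = 1)
#' fit <- fit_reaction(curve)
#' glance(fit)
fit_reaction <- function(fluorescence, ground_cycles = 10, threshold = 1.0,
                         min_r2 = 0.99) {
  baseline <- estimate_baseline(fluorescence, ground_cycles)
  corrected <- fluorescence - baseline
  cycles <- seq_along(fluorescence)
  usable <- corrected > 0
  win <- find_linear_window(cycles[usable], log10(corrected[usable]))

  amplified <- !is.null(win) && win$r2 >= min_r2
  ct <- NA_real_
  ct_reliable <- NA
  if (amplified) {
    ct <- call_ct(fluorescence, threshold, baseline)
    ct_reliable <- if (is.na(ct)) NA else attr(ct, "reliable") %||% TRUE
    ct <- as.numeric(ct)
  }
  structure(
    list(
      baseline = baseline,
      slope = if (amplified) win$slope else NA_real_,
      efficiency_fold = if (amplified) 10^win$slope else NA_real_,
      efficiency_pct = if (amplified) (10^win$slope - 1) * 100 else NA_real_,
      window_start = if (amplified) win$start else NA_integer_,
      window_end = if (amplified) win$end else NA_integer_,
      r2 = if (is.null(win)) NA_real_ else win$r2,
      ct = ct,
      ct_reliable = ct_reliable,
      amplified = amplified,
      threshold = threshold,
      fluorescence = fluorescence
    ),
    class = "tedose_fit"
  )
}

#' @export
print.tedose_fit <- function(x, ...) {
  cat("qPCR reaction fit\n")
  if (x$amplified) {
    cat(sprintf("  efficiency: %.1f%% (fold %.3f), window %d-%d, R2 %.4f\n",
                x$efficiency_pct, x$efficiency_fold,
                x$window_start, x$window_end, x$r2))
    cat(sprintf("  baseline %.3f, Ct %.2f at threshold %.2f\n",
                x$baseline, x$ct, x$threshold))
  } else {
    cat("  not amplified\n")
  }
  invisible(x)
}

#' Call the fractional Ct of a curve at a fluorescence threshold
#'
#' Ct is the fractional cycle at which the baseline-corrected fluorescence
#' first crosses `threshold`, by linear interpolation of log10 fluorescence
#' between the bracketing cycles. Returns `NA` when the threshold is never
#' crossed. A crossing already at cycle 1 has no bracketing cycle; the Ct is
#' returned but flagged unreliable via the `"reliable"` attribute.
#'
#' @param fluorescence Raw readings, cycle 1 onward.
#' @param threshold Threshold in corrected fluorescence units (> 0).
#' @param baseline Baseline to subtract (see [estimate_baseline()]).
#' @returns Fractional cycle (scalar) with attribute `reliable`, or
#'   `NA_real_`.
#' @export
#' @examples
#' f <- 0.01 * 2^(1:30)
#' call_ct(f, threshold = 0.64, baseline = 0)  # 0.01 * 2^6 = 0.64 -> Ct 6
call_ct <- function(fluorescence, threshold, baseline) {
  stopifnot(threshold > 0)
  corrected <- fluorescence - baseline
  idx <- which(corrected >= threshold)
  if (length(idx) == 0) return(NA_real_)
  c2 <- idx[1]
  if (c2 == 1L) {
    return(structure(1.0, reliable = FALSE))
  }
  lo <- corrected[c2 - 1]
  hi <- corrected[c2]
  ct <- if (lo > 0) {
    (c2 - 1) + (log10(threshold) - log10(lo)) / (log10(hi) - log10(lo))
  } else {
    (c2 - 1) + (threshold - lo) / (hi - lo)
  }
  structure(ct, reliable = TRUE)
}

#' Analyse every well of a plate
#'
#' Maps [fit_reaction()] over all wells of a long-format plate table and
#' returns the per-well reaction results that feed dosage calling.
#'
#' @param plate Plate tibble as returned by [read_plate()] or
#'   [simulate_plate()].
#' @inheritParams fit_reaction
#' @returns A tibble with one row per well: `sample`, `locus`, `assay`,
#'   `well`, `baseline`, `efficiency_fold`, `efficiency_pct`, `ct`, `r2`,
#'   `amplified`, `window_start`, `window_end`.
#' @export
#' @examples
#' plate <- simulate_plate(plate_scenario(dosage = c(S1 = 6), seed = 1))
#' estimate_reactions(plate)
estimate_reactions <- function(plate, ground_cycles = 10, threshold = 1.0,
                               min_r2 = 0.99) {
  plate <- validate_plate(plate)
  plate |>
    dplyr::arrange(.data$sample, .data$locus, .data$assay, .data$well,
                   .data$cycle) |>
    dplyr::group_by(.data$sample, .data$locus, .data$assay, .data$well) |>
    dplyr::group_modify(function(d, key) {
      fit <- fit_reaction(d$fluorescence, ground_cycles = ground_cycles,
                          threshold = threshold, min_r2 = min_r2)
      tibble(
        baseline = fit$baseline,
        efficiency_fold = fit$efficiency_fold,
        efficiency_pct = fit$efficiency_pct,
        ct = fit$ct,
        r2 = fit$r2,
        amplified = fit$amplified,
        window_start = fit$window_start,
        window_end = fit$window_end
      )
    }) |>
    dplyr::ungroup()
}
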