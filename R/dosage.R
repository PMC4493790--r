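#' Replicate quality-control thresholds
#'
#' Container for the QC rules applied to a set of replicate reactions:
#' per-reaction efficiency must fall in the `[eff_min_pct, eff_max_pct]`
#' band (default 90-110%), at least `min_valid` reactions must survive
#' (default 3 of the nominal 5 replicates), and the replicate Ct spreads
#' are gated by the cross-assay rule of [cross_assay_gate()] using
#' `max_ct_spread` (default 0.5 cycles) and `max_total_spread` (default
#' 0.75 cycles).
#'
#' @param eff_min_pct,eff_max_pct Efficiency acceptance band in percent.
#' @param min_valid Minimum number of in-band replicates per assay.
#' @param max_ct_spread Maximum max-minus-min Ct spread within one assay.
#' @param max_total_spread Maximum summed spread over presence + absence.
#' @returns A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(eff_min_pct = 90, eff_max_pct = 110, min_valid = 3,
                          max_ct_spread = 0.5, max_total_spread = 0.75) {
  stopifnot(eff_min_pct < eff_max_pct, min_valid >= 2,
            max_ct_spread > 0, max_total_spread > 0)
  structure(
    list(eff_min_pct = eff_min_pct, eff_max_pct = eff_max_pct,
         min_valid = min_valid, max_ct_spread = max_ct_spread,
         max_total_spread = max_total_spread),
    class = "qc_thresholds"
  )
}

#' Quality-control one set of replicate reactions
#'
#' Applies the single-assay rules to the replicates of one sample x locus x
#' assay: reactions outside the efficiency band are removed; if fewer than
#' `min_valid` amplified reactions remain (but at least one replicate
#' amplified) the set needs repeating; if no replicate amplified at all the
#' set is non-amplifying. A Ct spread above `max_ct_spread` also flags
#' `repeat_needed`, provisionally: the final decision for spread failures is
#' taken jointly with the converse assay by [cross_assay_gate()].
#'
#' @param reactions Tibble of reaction results for one replicate set
#'   (columns `efficiency_pct`, `ct`, `amplified`; see
#'   [estimate_reactions()]).
#' @param thresholds A [qc_thresholds()] object.
#' @returns A list with `accepted` (tibble of surviving reactions), `flag`
#'   (`"pass"`, `"repeat_needed"` or `"not_amplified"`) and `ct_spread`
#'   (max - min Ct over the accepted reactions, 0 when fewer than two).
#' @export
qc_replicates <- function(reactions, thresholds = qc_thresholds()) {
  stopifnot(all(c("efficiency_pct", "ct", "amplified") %in% names(reactions)))
  if (nrow(reactions) == 0 || !any(reactions$amplified)) {
    return(list(accepted = reactions[0, ], flag = "not_amplified",
                ct_spread = 0))
  }
  accepted <- reactions |>
    dplyr::filter(.data$amplified,
                  .data$efficiency_pct >= thresholds$eff_min_pct,
                  .data$efficiency_pct <= thresholds$eff_max_pct)
  spread <- if (nrow(accepted) >= 2) diff(range(accepted$ct)) else 0
  flag <- if (nrow(accepted) < thresholds$min_valid) {
    "repeat_needed"
  } else if (spread > thresholds$max_ct_spread) {
    "repeat_needed"
  } else {
    "pass"
  }
  list(accepted = accepted, flag = flag, ct_spread = spread)
}

#' Cross-assay Ct spread gate
#'
#' The spread rule is a conjunction: a sample x locus is repeated only when
#' one assay's replicate Ct spread exceeds `max_ct_spread` AND the summed
#' spread over the presence and absence assays exceeds `max_total_spread`.
#' A single assay slightly over the per-assay limit therefore passes as long
#' as the other assay is tight.
#'
#' @param presence_spread,absence_spread Max - min Ct over the accepted
#'   replicates of each assay (cycles, >= 0).
#' @param thresholds A [qc_thresholds()] object.
#' @returns `"pass"` or `"repeat_needed"`.
#' @export
#' @examples
#' cross_assay_gate(0.6, 0.10)  # total 0.70 <= 0.75 -> pass
#' cross_assay_gate(0.6, 0.30)  # total 0.90 > 0.75  -> repeat_needed
#' cross_assay_gate(0.4, 0.40)  # neither spread > 0.5 -> pass
cross_assay_gate <- function(presence_spread, absence_spread,
                             thresholds = qc_thresholds()) {
  stopifnot(presence_spread >= 0, absence_spread >= 0)
  over_one <- max(presence_spread, absence_spread) > thresholds$max_ct_spread
  over_total <- presence_spread + absence_spread > thresholds$max_total_spread
  if (over_one && over_total) "repeat_needed" else "pass"
}

#' Efficiency-corrected presence:absence ratio
#'
#' The relative number of alleles carrying the insertion versus alleles
#' without it: `ratio = E^(Ct_absence - Ct_presence)`, where `E` is the
#' average amplification efficiency (fold per cycle) over all accepted
#' reactions of both assays and the Cts are the per-assay replicate means.
#' A ratio above 1 means more presence template (lower presence Ct).
#'
#' @param avg_eff_fold Average efficiency as fold amplification per cycle
#'   (must exceed 1; 2.0 is 100% efficiency).
#' @param avg_ct_absent,avg_ct_present Mean Ct of the absence and presence
#'   assays.
#' @returns The ratio (scalar, >= 0).
#' @export
#' @examples
#' compute_ratio(2.0, 25.0, 24.0)   # 2: twice as many presence alleles
#' compute_ratio(1.95, 26.3, 24.9)  # 1.95^1.4
compute_ratio <- function(avg_eff_fold, avg_ct_absent, avg_ct_present) {
  if (any(avg_eff_fold <= 1)) {
    abort("average efficiency fold must exceed 1",
          class = "tedose_invalid_efficiency")
  }
  avg_eff_fold^(avg_ct_absent - avg_ct_present)
}

#' Transform a presence:absence ratio to scores out of 10
#'
#' The ratio `R` is mapped to the share of the ten dosage units carried by
#' the presence allele: `presence = 10 R / (1 + R)`, `absence = 10 -
#' presence`. This is the proportion-of-total-copies mapping, the one
#' consistent with scoring a one-sided amplification as 10 versus 0. Scores
#' are reported to one decimal place.
#'
#' @param ratio Presence:absence ratio(s), >= 0; `Inf` maps to 10.
#' @param digits Decimal places for reporting (default 1; `NULL` for
#'   unrounded scores).
#' @returns A tibble with columns `presence_score` and `absence_score`.
#' @export
#' @examples
#' to_decile(1)  # 5 / 5
#' to_decile(4)  # 8 / 2
to_decile <- function(ratio, digits = 1) {
  if (any(ratio < 0, na.rm = TRUE)) {
    abort("ratio must be non-negative", class = "tedose_invalid_input")
  }
  p <- ifelse(is.infinite(ratio), 10, 10 * ratio / (1 + ratio))
  if (!is.null(digits)) p <- round(p, digits)
  tibble(presence_score = p, absence_score = 10 - p)
}

qc_side <- function(reactions, assay, thresholds) {
  side <- reactions |> dplyr::filter(.data$assay == .env$assay)
  qc_replicates(side, thresholds)
}

call_one <- function(reactions, thresholds) {
  pres <- qc_side(reactions, "presence", thresholds)
  abse <- qc_side(reactions, "absence", thresholds)

  out <- tibble(
    ratio = NA_real_, presence_score = NA_real_, absence_score = NA_real_,
    avg_efficiency_fold = NA_real_, avg_efficiency_pct = NA_real_,
    ct_presence = NA_real_, ct_absence = NA_real_, status = NA_character_
  )

  if (pres$flag == "not_amplified" && abse$flag == "not_amplified") {
    out$status <- "inconclusive"
    return(out)
  }

  one_sided <- function(res, which) {
    if (nrow(res$accepted) < thresholds$min_valid) {
      out$status <- "repeat_needed"
      return(out)
    }
    gate <- cross_assay_gate(
      if (which == "presence") res$ct_spread else 0,
      if (which == "absence") res$ct_spread else 0,
      thresholds
    )
    out$presence_score <- if (which == "presence") 10 else 0
    out$absence_score <- 10 - out$presence_score
    out$avg_efficiency_fold <- mean(res$accepted$efficiency_fold)
    out$avg_efficiency_pct <- (out$avg_efficiency_fold - 1) * 100
    if (which == "presence") out$ct_presence <- mean(res$accepted$ct)
    if (which == "absence") out$ct_absence <- mean(res$accepted$ct)
    out$status <- if (gate == "repeat_needed") "repeat_needed"
                  else paste0(which, "_only")
    out
  }
  if (abse$flag == "not_amplified") return(one_sided(pres, "presence"))
  if (pres$flag == "not_amplified") return(one_sided(abse, "absence"))

  # both assays amplified
  if (nrow(pres$accepted) < thresholds$min_valid ||
      nrow(abse$accepted) < thresholds$min_valid) {
    out$status <- "repeat_needed"
    return(out)
  }
  gate <- cross_assay_gate(pres$ct_spread, abse$ct_spread, thresholds)

  accepted <- dplyr::bind_rows(pres$accepted, abse$accepted)
  avg_eff <- mean(accepted$efficiency_fold)
  ct_p <- mean(pres$accepted$ct)
  ct_a <- mean(abse$accepted$ct)
  ratio <- compute_ratio(avg_eff, ct_a, ct_p)
  scores <- to_decile(ratio)

  out$ratio <- ratio
  out$presence_score <- scores$presence_score
  out$absence_score <- scores$absence_score
  out$avg_efficiency_fold <- avg_eff
  out$avg_efficiency_pct <- (avg_eff - 1) * 100
  out$ct_presence <- ct_p
  out$ct_absence <- ct_a
  out$status <- if (gate == "repeat_needed") "repeat_needed" else "ok"
  out
}

#' Call allele dosage for every sample x locus of a reaction table
#'
#' The full dosage pipeline: per-assay replicate QC, the cross-assay Ct
#' spread gate, efficiency averaging over all accepted reactions of both
#' assays, the efficiency-corrected Ct ratio, and the out-of-10 transform.
#' One-sided amplification (one assay non-amplifying across all replicates,
#' the converse passing QC) scores the amplifying assay 10; both assays
#' non-amplifying gives status `inconclusive` (in the wet-lab protocol such
#' templates are re-checked with a microsatellite control PCR, outside the
#' scope of this package). Calls failing the spread gate keep their scores
#' but are flagged `repeat_needed` so that no sample is silently dropped.
#'
#' @param reactions Per-well reaction table from [estimate_reactions()].
#' @param thresholds A [qc_thresholds()] object.
#' @returns A tibble with one row per sample x locus: `sample`, `locus`,
#'   `ratio`, `presence_score`, `absence_score`, `avg_efficiency_fold`,
#'   `avg_efficiency_pct`, `ct_presence`, `ct_absence`, `status` (one of
#'   `ok`, `presence_only`, `absence_only`, `repeat_needed`,
#'   `inconclusive`).
#' @export
#' @examples
#' plate <- simulate_plate(plate_scenario(dosage = c(S1 = 6), seed = 1))
#' plate |> estimate_reactions() |> call_dosage()
call_dosage <- function(reactions, thresholds = qc_thresholds()) {
  needed <- c("sample", "locus", "assay", "efficiency_fold",
              "efficiency_pct", "ct", "amplified")
  missing <- setdiff(needed, names(reactions))
  if (length(missing) > 0) {
    abort(paste0("reaction table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "tedose_malformed_input")
  }
  reactions |>
    dplyr::group_by(.data$sample, .data$locus) |>
    dplyr::group_modify(~ call_one(.x, thresholds)) |>
    dplyr::ungroup()
}
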