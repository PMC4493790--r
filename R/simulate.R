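#' Describe a synthetic qPCR plate
#'
#' A scenario bundles the ground truth and noise model for a simulated
#' qPCR-RBIP plate. Each sample x locus has a true allele dosage `d` out of
#' 10 (d presence alleles, 10 - d absence alleles); each assay's Ct follows
#' the template copy number so that `Ct_absence - Ct_presence =
#' log_E(d / (10 - d))` by construction, the relationship inverted by the
#' ratio equation. Replicate noise enters as Gaussian jitter on the per-well
#' Ct and on the per-well amplification efficiency; optional multiplicative
#' noise can be added to the fluorescence readings themselves. A 10-fold
#' template dilution (`template_scale`) shifts both assays' Cts equally and
#' must leave dosage scores unchanged; `plate_offset_ct` emulates a
#' machine/plate offset by shifting the presence assay's Ct.
#'
#' @param dosage Named numeric vector of true dosages in `[0, 10]` (names =
#'   sample ids), or a data frame with columns `sample`, `locus`, `dosage`.
#' @param locus Locus id used when `dosage` is a vector (default `"L1"`).
#' @param replicates Replicates per reaction (default 5, the assay design).
#' @param efficiency_fold True amplification efficiency as fold per cycle
#'   (default 2.0 = 100%).
#' @param ct_noise_sd Replicate Ct jitter, cycles (default 0.15).
#' @param efficiency_noise_sd_pct Replicate efficiency jitter, percentage
#'   points (default 2.0).
#' @param fluor_noise_pct Multiplicative fluorescence reading noise, percent
#'   of signal (default 0: replicate variation is carried by the Ct and
#'   efficiency jitter).
#' @param baseline Ground-phase fluorescence (default 2.0).
#' @param plateau Plateau height above baseline (default 100; the default
#'   Ct threshold of 1.0 then sits at 1% of plateau, well inside the
#'   exponential phase).
#' @param cycles Number of PCR cycles (default 40).
#' @param base_ct Ct (at threshold `ct_threshold`) of a balanced assay with
#'   5 of 10 allele copies (default 24).
#' @param ct_threshold Threshold defining the true Cts (default 1.0
#'   corrected units).
#' @param template_scale Template concentration multiplier (default 1).
#' @param plate_offset_ct Constant Ct offset applied to the presence assay
#'   (default 0).
#' @param seed Integer seed; simulation is fully deterministic given the
#'   scenario.
#' @returns A list of class `plate_scenario`.
#' @export
plate_scenario <- function(dosage, locus = "L1", replicates = 5,
                           efficiency_fold = 2.0, ct_noise_sd = 0.15,
                           efficiency_noise_sd_pct = 2.0,
                           fluor_noise_pct = 0, baseline = 2.0,
                           plateau = 100, cycles = 40, base_ct = 24,
                           ct_threshold = 1.0, template_scale = 1,
                           plate_offset_ct = 0, seed = 1) {
  if (is.data.frame(dosage)) {
    stopifnot(all(c("sample", "locus", "dosage") %in% names(dosage)))
    truth <- as_tibble(dosage[c("sample", "locus", "dosage")])
  } else {
    if (is.null(names(dosage))) {
      names(dosage) <- paste0("S", seq_along(dosage))
    }
    truth <- tibble(sample = names(dosage), locus = locus,
                    dosage = as.numeric(dosage))
  }
  if (any(truth$dosage < 0 | truth$dosage > 10)) {
    abort("true dosage must lie in [0, 10]", class = "tedose_configuration")
  }
  stopifnot(replicates >= 1, efficiency_fold > 1, cycles >= 25,
            plateau > 0, template_scale > 0)
  structure(
    list(truth = truth, replicates = replicates,
         efficiency_fold = efficiency_fold, ct_noise_sd = ct_noise_sd,
         efficiency_noise_sd_pct = efficiency_noise_sd_pct,
         fluor_noise_pct = fluor_noise_pct, baseline = baseline,
         plateau = plateau, cycles = cycles, base_ct = base_ct,
         ct_threshold = ct_threshold, template_scale = template_scale,
         plate_offset_ct = plate_offset_ct, seed = as.integer(seed)),
    class = "plate_scenario"
  )
}

#' Simulate one amplification curve
#'
#' Generates a sigmoid TaqMan-style curve `F(c) = baseline + plateau /
#' (1 + exp(-(c - c_mid)/s))` with `s = 1/ln(E)`, so the exponential phase
#' amplifies by `E`-fold per cycle. The midpoint is placed so that the
#' baseline-corrected signal crosses `ct_threshold` exactly at the requested
#' `ct`. Optional multiplicative Gaussian noise is applied to every reading.
#'
#' @param cycles Number of cycles.
#' @param efficiency_fold Fold amplification per cycle (> 1).
#' @param ct True fractional Ct at `ct_threshold`; `NA` yields a flat,
#'   non-amplifying well (baseline plus noise only).
#' @param ct_threshold Threshold (corrected units) defining `ct`.
#' @param baseline,plateau Curve geometry (see [plate_scenario()]).
#' @param noise_pct Multiplicative reading noise, percent of the reading.
#' @param seed Optional seed (omit to use the current RNG stream).
#' @returns Numeric vector of raw fluorescence, cycle 1 onward.
#' @export
#' @examples
#' f <- simulate_curve(efficiency_fold = 2, ct = 24)
#' fit_reaction(f)
simulate_curve <- function(cycles = 40, efficiency_fold = 2.0, ct = 24,
                           ct_threshold = 1.0, baseline = 2.0, plateau = 100,
                           noise_pct = 0, seed = NULL) {
  gen <- function() {
    cc <- seq_len(cycles)
    if (is.na(ct)) {
      signal <- rep(0, cycles)
    } else {
      stopifnot(efficiency_fold > 1, ct_threshold > 0,
                ct_threshold < plateau)
      s <- 1 / log(efficiency_fold)
      sig <- ct_threshold / plateau
      # exact logistic inversion: corrected(ct) == ct_threshold
      c_mid <- ct - s * log(sig / (1 - sig))
      signal <- plateau / (1 + exp(-(cc - c_mid) / s))
    }
    if (noise_pct > 0) {
      # reporter noise scales with the accumulated signal
      signal <- signal * (1 + rnorm(cycles, 0, noise_pct / 100))
    }
    baseline + signal
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate a full qPCR-RBIP plate
#'
#' Expands a [plate_scenario()] into per-well amplification curves in the
#' same long CSV dialect the plate reader consumes. For each sample x locus,
#' the presence assay sees `d * template_scale` template units and the
#' absence assay `(10 - d) * template_scale`; an assay with zero template is
#' generated as a flat non-amplifying well. Deterministic given the
#' scenario seed.
#'
#' @param scenario A [plate_scenario()].
#' @returns A tibble with columns `sample`, `locus`, `assay`, `well`,
#'   `cycle`, `fluorescence`, carrying the truth table as attribute
#'   `"truth"`.
#' @export
#' @examples
#' plate <- simulate_plate(plate_scenario(dosage = c(A = 8), seed = 42))
#' dplyr::count(plate, assay)
simulate_plate <- function(scenario) {
  stopifnot(inherits(scenario, "plate_scenario"))
  scn <- scenario
  s_unit <- 1 / log(scn$efficiency_fold)
  # Ct of a single template unit; 5 units (balanced assay) sit at base_ct
  ct0 <- scn$base_ct + log(5) * s_unit

  wells <- tidyr::expand_grid(
    scn$truth,
    assay = c("presence", "absence"),
    rep = seq_len(scn$replicates)
  ) |>
    dplyr::mutate(
      copies = ifelse(.data$assay == "presence", .data$dosage,
                      10 - .data$dosage) * scn$template_scale,
      well = paste(.data$sample, .data$locus,
                   substr(.data$assay, 1, 1), .data$rep, sep = ".")
    )

  withr::with_seed(scn$seed, {
    curves <- purrr::pmap(
      list(wells$copies, wells$assay),
      function(copies, assay) {
        if (copies <= 0) {
          ct <- NA_real_
          eff <- scn$efficiency_fold
        } else {
          eff_pct <- (scn$efficiency_fold - 1) * 100 +
            rnorm(1, 0, scn$efficiency_noise_sd_pct)
          eff <- 1 + eff_pct / 100
          ct <- ct0 - log(copies) / log(eff) +
            rnorm(1, 0, scn$ct_noise_sd) +
            if (assay == "presence") scn$plate_offset_ct else 0
        }
        simulate_curve(
          cycles = scn$cycles, efficiency_fold = eff, ct = ct,
          ct_threshold = scn$ct_threshold, baseline = scn$baseline,
          plateau = scn$plateau, noise_pct = scn$fluor_noise_pct
        )
      }
    )
    out <- wells |>
      dplyr::mutate(fluor = curves) |>
      dplyr::select("sample", "locus", "assay", "well", "fluor") |>
      tidyr::unnest_longer(fluor, values_to = "fluorescence",
                           indices_to = "cycle") |>
      dplyr::mutate(cycle = as.integer(.data$cycle)) |>
      dplyr::select("sample", "locus", "assay", "well", "cycle",
                    "fluorescence")
    attr(out, "truth") <- scn$truth
    class(out) <- c("tedose_plate", class(out))
    out
  })
}

#' Describe a synthetic pair of LTRs of known age
#'
#' The two LTRs of an LTR retrotransposon are identical at insertion time
#' and diverge independently afterwards; a pair of age `T` therefore
#' accumulates an expected `2 r T` substitutions per site between its
#' copies. The simulator draws a random ancestral LTR and mutates each copy
#' independently, with per-site substitution probability `rate *
#' age_years`, transitions and transversions in ratio `titv` and the two
#' transversion types equally likely.
#'
#' @param n_pairs Number of element pairs to simulate.
#' @param length LTR length in bp (default 400; low-copy LTR
#'   retrotransposons of the size class this mirrors carry LTRs of roughly
#'   240-450 bp).
#' @param age_years True insertion age in years.
#' @param rate Substitution rate per site per year (default 1.3e-8).
#' @param titv Transition:transversion ratio (default 2, a typical plant
#'   nuclear value).
#' @param seed Integer seed.
#' @returns A list of class `ltr_scenario`.
#' @export
ltr_scenario <- function(n_pairs = 1, length = 400, age_years = 3e5,
                         rate = 1.3e-8, titv = 2, seed = 1) {
  stopifnot(n_pairs >= 1, length >= 1, age_years >= 0, rate > 0, titv > 0)
  if (2 * rate * age_years >= 0.75) {
    abort("expected divergence 2*rate*age must stay below 0.75 (saturation)",
          class = "tedose_configuration")
  }
  structure(
    list(n_pairs = n_pairs, length = as.integer(length),
         age_years = age_years, rate = rate, titv = titv,
         seed = as.integer(seed)),
    class = "ltr_scenario"
  )
}

TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSIONS <- list(A = c("C", "T"), G = c("C", "T"),
                      C = c("A", "G"), T = c("A", "G"))

mutate_copy <- function(anc, p_sub, titv) {
  n <- length(anc)
  hit <- runif(n) < p_sub
  if (!any(hit)) return(anc)
  out <- anc
  is_ti <- runif(sum(hit)) < titv / (titv + 1)
  idx <- which(hit)
  for (k in seq_along(idx)) {
    i <- idx[k]
    out[i] <- if (is_ti[k]) TRANSITION[[anc[i]]]
              else sample(TRANSVERSIONS[[anc[i]]], 1)
  }
  out
}

#' Simulate LTR pairs of known insertion age
#'
#' @param scenario An [ltr_scenario()].
#' @returns A tibble with columns `element`, `ltr5`, `ltr3` (uppercase DNA
#'   strings of equal length, already aligned: the simulator introduces
#'   substitutions only).
#' @export
#' @examples
#' pairs <- simulate_ltr_pairs(ltr_scenario(age_years = 0, seed = 1))
#' identical(pairs$ltr5, pairs$ltr3)
simulate_ltr_pairs <- function(scenario) {
  stopifnot(inherits(scenario, "ltr_scenario"))
  scn <- scenario
  p_sub <- scn$rate * scn$age_years
  withr::with_seed(scn$seed, {
    purrr::map_dfr(seq_len(scn$n_pairs), function(i) {
      anc <- sample(c("A", "C", "G", "T"), scn$length, replace = TRUE)
      tibble(
        element = sprintf("element_%03d", i),
        ltr5 = paste(mutate_copy(anc, p_sub, scn$titv), collapse = ""),
        ltr3 = paste(mutate_copy(anc, p_sub, scn$titv), collapse = "")
      )
    })
  })
}

#' Reproducibility study on synthetic plates
#'
#' Emulates the wet-lab reproducibility design on synthetic truth: the same
#' scenario is simulated `n_plates` times with independent noise (seeds
#' `seed + 1 .. seed + n_plates`), each plate is run through the full
#' amplification and dosage pipeline, and the per-dosage accuracy and
#' cross-plate replicate agreement are summarised.
#'
#' @param scenario A [plate_scenario()].
#' @param n_plates Number of simulated plates (>= 2).
#' @param ct_threshold Ct threshold passed to [estimate_reactions()]
#'   (default the scenario's `ct_threshold`).
#' @param thresholds QC thresholds for [call_dosage()].
#' @returns A tibble with one row per true dosage level: `dosage`,
#'   `n_calls` (scored calls), `bias`, `rmse` of the presence score, and
#'   the cross-plate absolute score differences `diff_mean`, `diff_min`,
#'   `diff_max` over all plate pairs of the same sample x locus. Per-plate
#'   scores are attached as attribute `"scores"`.
#' @export
run_recovery_study <- function(scenario, n_plates,
                               ct_threshold = scenario$ct_threshold,
                               thresholds = qc_thresholds()) {
  stopifnot(inherits(scenario, "plate_scenario"), n_plates >= 2)
  scores <- purrr::map_dfr(seq_len(n_plates), function(p) {
    scn <- scenario
    scn$seed <- scenario$seed + p
    plate <- simulate_plate(scn)
    calls <- plate |>
      estimate_reactions(threshold = ct_threshold) |>
      call_dosage(thresholds = thresholds)
    calls |>
      dplyr::left_join(scenario$truth, by = c("sample", "locus")) |>
      dplyr::mutate(plate = p)
  })

  pair_diffs <- function(x) {
    if (length(x) < 2) return(numeric(0))
    d <- abs(outer(x, x, "-"))
    d[upper.tri(d)]
  }
  summary <- scores |>
    dplyr::filter(!is.na(.data$presence_score)) |>
    dplyr::group_by(.data$dosage) |>
    dplyr::summarise(
      n_calls = dplyr::n(),
      bias = mean(.data$presence_score - .data$dosage),
      rmse = sqrt(mean((.data$presence_score - .data$dosage)^2)),
      diffs = list(unlist(purrr::map(
        split(.data$presence_score, paste(.data$sample, .data$locus)),
        pair_diffs
      ))),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      diff_mean = purrr::map_dbl(.data$diffs, ~ mean(.x)),
      diff_min = purrr::map_dbl(.data$diffs, ~ min(.x)),
      diff_max = purrr::map_dbl(.data$diffs, ~ max(.x))
    ) |>
    dplyr::select(-"diffs")
  attr(summary, "scores") <- scores
  summary
}
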