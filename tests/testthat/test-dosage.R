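mk_reactions <- function(eff_pct, ct = NULL, amplified = NULL,
                         sample = "S", locus = "L", assay = "presence") {
  n <- length(eff_pct)
  tibble::tibble(
    sample = sample, locus = locus, assay = assay,
    efficiency_pct = eff_pct,
    efficiency_fold = 1 + eff_pct / 100,
    ct = ct %||% rep(24, n),
    amplified = amplified %||% rep(TRUE, n)
  )
}

test_that("replicate QC removes out-of-band efficiencies and counts survivors", {
  # 90/110 band: 89 and 111 are out, three survive
  r <- qc_replicates(mk_reactions(c(95, 101, 104, 89, 111)))
  expect_equal(nrow(r$accepted), 3)
  expect_equal(r$flag, "pass")

  # all five outside the band but amplified: too few -> repeat
  r <- qc_replicates(mk_reactions(c(89, 111, 85, 120, 115)))
  expect_equal(nrow(r$accepted), 0)
  expect_equal(r$flag, "repeat_needed")

  # nothing amplified at all
  r <- qc_replicates(mk_reactions(rep(NA_real_, 5), ct = rep(NA_real_, 5),
                                  amplified = rep(FALSE, 5)))
  expect_equal(r$flag, "not_amplified")

  # Ct spread above 0.5 flags a provisional repeat
  r <- qc_replicates(mk_reactions(c(100, 100, 100), ct = c(24.0, 24.3, 24.6)))
  expect_equal(r$ct_spread, 0.6, tolerance = 1e-12)
  expect_equal(r$flag, "repeat_needed")
})

test_that("cross-assay gate is the conjunction of spread and total rules", {
  expect_equal(cross_assay_gate(0.6, 0.10), "pass")           # total 0.70
  expect_equal(cross_assay_gate(0.6, 0.30), "repeat_needed")  # total 0.90
  expect_equal(cross_assay_gate(0.4, 0.40), "pass")           # no spread > 0.5
  expect_equal(cross_assay_gate(0.0, 0.0), "pass")
  expect_equal(cross_assay_gate(0.8, 0.0), "repeat_needed")   # 0.8 > both
})

test_that("ratio equation and decile transform match hand values", {
  expect_equal(compute_ratio(2.0, 25.0, 24.0), 2.0)
  expect_equal(compute_ratio(2.0, 24.0, 24.0), 1.0)
  expect_equal(compute_ratio(1.95, 26.3, 24.9), 1.95^1.4)
  expect_error(compute_ratio(1.0, 25, 24), class = "tedose_invalid_efficiency")

  expect_equal(to_decile(1.0)$presence_score, 5.0)
  expect_equal(to_decile(1.0)$absence_score, 5.0)
  expect_equal(to_decile(4.0)$presence_score, 8.0)
  expect_equal(to_decile(Inf)$presence_score, 10)
  expect_error(to_decile(-0.1), class = "tedose_invalid_input")
})

test_that("decile scores conserve the total of 10 and grow with delta-Ct", {
  ratios <- 2^seq(-3, 3, by = 0.5)  # delta-Ct grid at efficiency 2
  sc <- to_decile(ratios)
  expect_true(all(abs(sc$presence_score + sc$absence_score - 10) < 1e-9))
  expect_true(all(diff(sc$presence_score) > 0))
})

test_that("full dosage pipeline recovers noiseless truth and edge patterns", {
  scn <- plate_scenario(dosage = c(S1 = 6, S2 = 0, S3 = 10),
                        ct_noise_sd = 0, efficiency_noise_sd_pct = 0,
                        seed = 21)
  calls <- simulate_plate(scn) |> estimate_reactions() |> call_dosage()

  s1 <- dplyr::filter(calls, sample == "S1")
  expect_equal(s1$status, "ok")
  expect_equal(s1$presence_score, 6.0, tolerance = 0.1 / 6)

  s2 <- dplyr::filter(calls, sample == "S2")  # absence-only amplification
  expect_equal(s2$status, "absence_only")
  expect_equal(s2$presence_score, 0)
  expect_equal(s2$absence_score, 10)

  s3 <- dplyr::filter(calls, sample == "S3")  # presence-only amplification
  expect_equal(s3$status, "presence_only")
  expect_equal(s3$presence_score, 10)
})

test_that("both assays failing yields an inconclusive call", {
  rx <- dplyr::bind_rows(
    mk_reactions(rep(NA_real_, 5), ct = rep(NA_real_, 5),
                 amplified = rep(FALSE, 5), assay = "presence"),
    mk_reactions(rep(NA_real_, 5), ct = rep(NA_real_, 5),
                 amplified = rep(FALSE, 5), assay = "absence")
  )
  calls <- call_dosage(rx)
  expect_equal(calls$status, "inconclusive")
  expect_true(is.na(calls$presence_score))
})

test_that("spread-gate failures are reported, not dropped", {
  rx <- dplyr::bind_rows(
    mk_reactions(c(100, 100, 100), ct = c(24.0, 24.4, 24.8), assay = "presence"),
    mk_reactions(c(100, 100, 100), ct = c(25.0, 25.2, 25.4), assay = "absence")
  )
  calls <- call_dosage(rx)  # spreads 0.8 + 0.4: conjunction holds
  expect_equal(calls$status, "repeat_needed")
  expect_false(is.na(calls$presence_score))
  expect_equal(calls$presence_score + calls$absence_score, 10)

  rx2 <- dplyr::bind_rows(
    mk_reactions(c(100, 100, 100), ct = c(24.0, 24.4, 24.6), assay = "presence"),
    mk_reactions(c(100, 100, 100), ct = c(25.0, 25.1, 25.1), assay = "absence")
  )
  expect_equal(call_dosage(rx2)$status, "ok")  # 0.6 + 0.1 <= 0.75
})

test_that("a malformed reaction table is rejected", {
  expect_error(call_dosage(tibble::tibble(sample = "S", locus = "L")),
               class = "tedose_malformed_input")
})

test_that("scores are invariant to a 10-fold template dilution", {
  score_at <- function(scale) {
    scn <- plate_scenario(dosage = c(S = 6), ct_noise_sd = 0,
                          efficiency_noise_sd_pct = 0,
                          template_scale = scale, seed = 13)
    calls <- simulate_plate(scn) |> estimate_reactions() |> call_dosage()
    calls$presence_score
  }
  expect_equal(score_at(10), score_at(1), tolerance = 0.1 / 6)
})

test_that("stochastic plates recover dosage on average", {
  scn <- plate_scenario(dosage = c(D2 = 2, D5 = 5, D8 = 8), seed = 500)
  res <- run_recovery_study(scn, n_plates = 40)
  expect_true(all(abs(res$bias) < 0.3))
  sc <- attr(res, "scores")
  scored <- dplyr::filter(sc, !is.na(presence_score))
  expect_true(all(abs(scored$presence_score + scored$absence_score - 10) < 1e-9))
})
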