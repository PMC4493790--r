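---
title: "Estimating retrotransposon allele dosage from qPCR-RBIP assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating retrotransposon allele dosage from qPCR-RBIP assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tedose)
```

## The measurement model

A retrotransposon insertion site in a polyploid genome is interrogated by
two TaqMan qPCR reactions run on the same genomic DNA dilution: a
*presence* assay anchored in the element's LTR and the flank, and an
*absence* assay spanning the empty site. If a fraction of the
homo(eo)logous alleles carries the insertion, the two assays see different
template copy numbers, and under ideal exponential amplification

$$N_c = N_0 \, E^{\,c}$$

the cycle threshold difference measures their ratio:

$$R = E_{avg}^{\,(Ct_{absence} - Ct_{presence})},$$

where $E_{avg}$ is the mean per-cycle fold amplification over all accepted
replicates of both assays. $R$ is then expressed as a dosage out of 10
allele units,

$$\text{presence score} = \frac{10R}{1+R}, \qquad
  \text{absence score} = 10 - \text{presence score}.$$

This mapping is the share of total allele copies carried by the occupied
site. It is the only increasing mapping of $R$ onto $[0, 10]$ that is
consistent with the boundary rule used for one-sided amplification: when
one assay fails to amplify in all replicates while the converse assay
amplifies, the amplifying assay is scored 10 (so $R = \infty$ must map to
10 and $R = 0$ to 0). The method is deliberately *relative*: without
knowing genome size or total allele count, absolute copy numbers are not
identifiable, and none are estimated.

Assumptions worth keeping in mind: both assays amplify with comparable
efficiency from the same dilution (the shared $E_{avg}$); the Ct threshold
sits inside the exponential phase of both reactions; and PCR inhibitors or
probe differences affect both assays equally.

## Per-reaction efficiency: the window of linearity

Efficiency is estimated per reaction rather than assumed. For each well:

1. **Baseline**: the mean fluorescence of cycles 3 to `ground_cycles`
   (default 10). Cycles 1–2 are excluded because instrument settling
   commonly distorts them. Corrected readings that are not strictly
   positive cannot be log-transformed and are dropped.
2. **Window of linearity**: among all windows of 4–6 *consecutive* cycles
   with usable points, the window maximising the $R^2$ of the linear fit
   of $\log_{10}$ corrected fluorescence on cycle, subject to positive
   slope. Ties on $R^2$ (within $10^{-12}$) prefer the larger slope, then
   the earliest start cycle — the earliest-start rule keeps the window out
   of the plateau bend when a noiseless curve makes several windows
   equally linear.
3. **Efficiency**: $E = 10^{\text{slope}}$ (fold per cycle; 2.0 is "100%"
   efficiency, percent efficiency is $(E-1)\times 100$). A reaction with
   no positive-slope window, or a best window with $R^2 < 0.99$, is
   flagged `amplified = FALSE` and contributes neither efficiency nor Ct.
4. **Ct**: the fractional cycle at which corrected fluorescence first
   crosses the threshold, interpolated linearly in $\log_{10}$
   fluorescence between the bracketing cycles. A crossing at cycle 1 has
   no bracket and is flagged unreliable. The default threshold is 1.0
   corrected units (1% of the default synthetic plateau); because the
   dosage statistic depends only on $\Delta Ct$, any threshold inside the
   exponential phase gives the same calls, and 0.5/1.0/1.5 are compared in
   the test suite.

The window search is validated against an exhaustive `lm()` enumeration of
every admissible window; the two must agree exactly.

## Replicate QC

Each sample × locus runs nominally five replicates per assay. The rules:

* replicates with efficiency outside 90–110% are removed;
* fewer than `min_valid = 3` surviving replicates (while at least one
  replicate amplified) → `repeat_needed`;
* the Ct spread rule is a *conjunction across assays*: a repeat is needed
  only when one assay's spread (max − min over accepted replicates)
  exceeds 0.5 cycles **and** the two assays' spreads sum to more than
  0.75 cycles. A single assay marginally over 0.5 passes if the other is
  tight. Read literally from the protocol's sentence structure, this is an
  AND, and the package's truth-table tests pin exactly that reading.

`repeat_needed` is terminal in software — re-running a plate is a lab act —
so such calls keep their (advisory) scores and are surfaced with the flag
rather than dropped. Both assays failing entirely yields `inconclusive`
(the wet-lab follow-up, a microsatellite control PCR on the template, is
out of scope). Scores are reported to one decimal place.

## Profiles, distance and clustering

Dosage calls across several insertion loci form a per-sample TE profile.
For distance computation each locus is encoded as a cumulative band
ladder: with `bin_width = 1`, ten indicators of which a score of 6
switches on the first six. This keeps near-identical profiles (replicate
runs of one cultivar) at small but nonzero distances, which a single
presence/absence bit per locus cannot express; `bin_width` is
configurable. Profiles are compared with the Nei–Li (Dice) distance
$D = 1 - 2n_{ab}/(n_a + n_b)$ — a semimetric (the triangle inequality can
fail), undefined between two all-zero profiles, which are excluded with a
warning.

Clustering is textbook UPGMA: merge the closest pair, place the node at
half the merge distance, update distances as size-weighted arithmetic
means. Ties on the minimum are broken by the lowest (row, column) index
pair so results are exactly reproducible; the implementation is tested for
equality of merge heights and clades against a from-scratch oracle that
recomputes every cluster distance as the plain mean over original-matrix
entries. Bootstrap support resamples *loci* with replacement, re-encodes
and re-clusters, and reports the percentage of replicates containing each
clade of the reference tree (Felsenstein-style counting on the rooted
tree; the root clade is trivial and left unannotated). With a single locus
support is undefined and reported `NA`. Inside bootstrap replicates a
resample can zero out a profile; there the Dice distance falls back to 0
between two empty profiles and 1 against non-empty ones, so replicates
remain comparable.

## Dating insertions from LTR divergence

The two LTRs of an element are identical upon insertion; each then
accumulates substitutions independently, so divergence between them grows
at $2r$ per year and

$$T = \frac{k}{2r}, \qquad r = 1.3\times10^{-8}
  \text{ substitutions site}^{-1}\text{yr}^{-1} \text{ by default},$$

the rate commonly applied to grass LTR retrotransposons. Divergence $k$ is
the Kimura two-parameter distance, with transitions $P$ and transversions
$Q$ counted over columns where both sequences have an unambiguous base
(gap/`N` columns removed pairwise — the two-sequence analogue of complete
deletion):

$$k = -\tfrac12\ln(1 - 2P - Q) - \tfrac14\ln(1 - 2Q).$$

Saturation ($1-2P-Q \le 0$ or $1-2Q \le 0$) raises an explicit error
rather than returning a clamped value: a silently clamped distance would
propagate into a misleading finite age. Unaligned pairs are aligned with
an affine-gap Needleman–Wunsch (match +1, mismatch −1, gap open −5, gap
extend −1; a length-$L$ gap costs open + $(L-1)\cdot$extend), validated
against brute-force enumeration on short strings.

At realistic LTR lengths and young ages the binomial sampling error
dominates: a 400-bp pair at 0.3 Myr expects only ~3 substitutions, so
individual ages scatter widely (the tests assert a median within
0.15–0.45 Myr over 200 simulated pairs). Ages of single young elements
should be read as order-of-magnitude estimates.

## What the simulator emulates — and what it does not

`simulate_plate()` generates per-well sigmoid curves

$$F(c) = \text{baseline} + \frac{\text{plateau}}{1 + e^{-(c - c_{mid})/s}},
  \qquad s = 1/\ln E,$$

whose early phase is exponential with fold $E$ per cycle. The midpoint is
placed by exact logistic inversion so the corrected signal crosses the
scenario's Ct threshold exactly at the target Ct; with the defaults
(plateau 100, baseline 2, threshold 1.0, Ct ≈ 24, 40 cycles) this leaves
well over eight clean exponential cycles between the noise floor and the
plateau bend. Presence and absence assays of a sample with dosage $d$
receive $d$ and $10-d$ template units, so
$Ct_{absence} - Ct_{presence} = \log_E\!\big(d/(10-d)\big)$ holds by
construction and a template dilution shifts both assays equally. Dosage 0
or 10 makes the corresponding assay a flat baseline-only well, the
cleanest "failed to amplify in all replicates" case.

Replicate noise enters as Gaussian jitter on the per-well Ct (default sd
0.15 cycles) and on the per-well percent efficiency (default sd 2
percentage points) — the two dominant sources of replicate scatter in this
assay design. Optional multiplicative reading noise (`fluor_noise_pct`)
scales with the accumulated reporter signal, as fluorophore noise does;
it is off by default so that the default scenario isolates
replicate-level variation. Cross-machine/plate effects are emulated only
as a constant Ct offset on the presence assay (`plate_offset_ct`) — no
optics, ramp-rate or dye-deconvolution modelling, no melt curves, no
inhibitor kinetics. Passing the closed-loop tests therefore demonstrates
correctness of the estimators under this generative model, not robustness
to every instrument artifact in real exports.

The LTR simulator draws a uniform-random ancestral sequence and mutates
each copy once per site with probability $r\,T$ (transitions:transversions
in ratio `titv`, default 2, a typical plant nuclear value). It introduces
no indels and no multiple hits; at the sub-percent divergences of interest
the distinction from a full continuous-time model is negligible relative
to sampling noise.

## Numerical choices and degenerate inputs

* Log base 10 throughout the fitting (any base is equivalent; 10 matches
  common reporting). Minimum window $R^2$ 0.99.
* Tie tolerance $10^{-12}$ in the window search; index-order tie-breaks in
  UPGMA; traceback preference substitution > gap-in-second > gap-in-first
  in the aligner. All three make results bit-reproducible.
* Ratio computation requires $E_{avg} > 1$; a non-positive-slope "curve"
  cannot reach it because such wells are flagged unamplified earlier.
* Signed zero from $-\tfrac12\ln 1$ is normalised so identical LTRs report
  exactly `k = 0`, `T = 0`.
* All simulations are seeded; identical scenario + seed gives
  bit-identical plates.

## Problem sizes used by the test suite

The suite validates dosage recovery on 200 simulated plates of nine
samples (dosages 1–9) at the default noise model, cross-plate
reproducibility on 50 plates, threshold comparisons (0.5/1.0/1.5) on 20
plates of three samples, oracle equivalence on 100 random distance
matrices (≤ 8 samples), 20 noisy curves and 10 short alignment pairs, and
replicate-profile closeness over 200 two-plate simulations of a
three-locus cultivar profile. These sizes give stable averages for every
asserted tolerance while keeping a full run around three minutes.

## Known limitations

* Dosage is relative to 10 allele units by convention; true ploidy at a
  locus may differ, and scores should be compared across samples, not
  read as absolute copy counts.
* The decile mapping concentrates resolution near balanced dosages; at
  $R \gg 1$ the score saturates and small Ct errors translate into large
  ratio errors (though tiny score errors).
* Bootstrap support over as few as three loci is weak by construction —
  with so few resampling units most clades cannot be strongly supported,
  which is precisely the behaviour the profile tests assert.
* The aligner is quadratic-time pure R: fine for LTRs (hundreds of bp),
  not intended for multi-kb sequences.
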