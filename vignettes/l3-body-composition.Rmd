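---
title: "L3 body composition: methods, phantom design and simulation choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{L3 body composition: methods, phantom design and simulation choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(l3compo)
```

## The measurement model

A single axial CT slice at the third lumbar vertebra is the standard
single-slice proxy for whole-body composition. Each pixel carries a
calibrated Hounsfield unit (HU; water 0, air −1000), and tissue classes
occupy characteristic HU ranges, so cross-sectional areas of fat and muscle
compartments can be measured by counting pixels inside inclusive HU
windows. The package uses one fat window (−190…−30 HU) applied within three
spatial compartments (subcutaneous ring, visceral cavity, muscle wall —
yielding SFA, VFA and IMFA; TFA is their sum) and five muscle radiodensity
windows (−29…−1, 0…34, 35…100, 101…150, 151…199) applied within the muscle
wall, whose union −29…199 defines total muscle area (TMA). Lower muscle
radiodensity indicates fat infiltration (myosteatosis); area loss indicates
sarcopenia.

Three conventions matter and are fixed throughout:

* **Integer HU.** HU are rounded to integers once at ingest (ties away from
  zero). The printed windows abut at integer boundaries (−30|−29, −1|0,
  34|35, 100|101, 150|151), so with integer HU the five muscle windows tile
  −29…199 exactly and TMA ≡ VLDM+LDMA+NDMA+HDMA+VHDMA holds identically,
  not approximately. A pixel at exactly −30 HU is fat; at −29 it is
  very-low-density muscle.
* **Height normalization.** Areas (cm²) are divided by squared height (m²),
  the standard skeletal-muscle-index convention; analyses run on cm²/m².
* **Dates.** ISO-8601 only; the "at least one year" follow-up rule is
  evaluated as ≥ 365 days.

## Compartment separation

The HU windows identify tissue but not compartment: subcutaneous, visceral
and intermuscular fat share one window and must be separated spatially. In
the clinical workflow this is a manual region-of-interest step; no
published algorithmic description exists, so the rule implemented here is
the package's own construction and is validated only against phantoms:

1. body mask: HU > −500, morphological closing (disc radius 3 px), hole
   fill, largest 8-connected component (drops the scanner table and arms);
2. muscle-wall candidates: body pixels in the total-muscle window
   (−29…199 HU), closed with a disc of radius 5 px (bridging myosteatotic
   speckle, which is fat-dense and would otherwise punch holes in the
   wall);
3. wall: the candidate components that reach into the body rind (depth
   ≤ 40% of the maximum body depth) — interior soft-tissue organs form
   separate components and are discarded;
4. visceral region: the hole-fill of the wall minus the wall;
   subcutaneous region: the remaining body.

All morphology is 8-connected; ties in "largest component" are broken by
the lowest label, so segmentation is deterministic. Degenerate anatomy
(no muscle-band pixels, or a wall enclosing no interior) produces an
explicit warning and empty visceral areas rather than an error.

## Phantom design

Phantoms are nested ellipses (subcutaneous fat ring, muscle wall, visceral
cavity with fat background and soft-tissue organ blobs), with myosteatotic
fat speckle inside the wall. Ground truth is computed from the **rasterized
masks** — pixel count × pixel area — not from continuous ellipse areas, so
at zero noise the segmentation must recover every measure exactly (the test
suite asserts pixel identity, and does recover it).

Design choices that make exact recovery and calibrated noisy recovery
possible:

* **Layout vs noise seeds.** `layout_seed` fixes speckle and organ
  placement; `seed` drives only the additive Gaussian HU noise. The same
  spec therefore always yields identical masks and truth, with
  exchangeable noise fields across seeds.
* **Clearances.** Speckle blobs are seeded in the morphologically eroded
  wall interior, so their holes never touch the wall boundary and the
  radius-5 closing restores the wall exactly. Organ blobs are confined to
  the cavity core (deeper than the rind-adjacency band, and beyond the
  closing diameter from the wall), so they can neither join the wall
  component nor be bridged into it.
* **Balanced muscle spectrum.** Wall pixels are painted with a balanced
  discrete-uniform HU spectrum over −15…175: every HU value is represented
  equally (up to one pixel), then shuffled. All five muscle bands carry
  non-zero truth; because the density is equal on both sides of every
  interior band edge, Gaussian-noise crossings cancel in expectation, and
  because the spectrum is balanced rather than i.i.d., the realized density
  near band edges does not fluctuate between layouts. The support endpoints
  were chosen by flux analysis: the bottom (−15) sits 14.5 HU above the fat
  cut at −29.5, exactly mirroring the 14.5-HU depth of the very-low-density
  support below the −0.5 band edge, so the two truncation fluxes cancel;
  the top (175) leaves 24.5 HU to the muscle-window ceiling at 199.5, making
  the out-of-window leak negligible. With noise sd 10 the residual expected
  biases are ≲1.5% per measure (largest for IMFA, which receives the small
  fat-ward leak), and the acceptance property — every measure's mean
  recovery over 25 noise seeds within 2% of truth — holds with margin.
  Single-seed errors on the smallest bands (a few hundred pixels) fluctuate
  by several percent; the 25-seed mean is the calibrated quantity.

What the phantoms do **not** emulate: real anatomy beyond ring topology,
3-D volumes, scanner artifacts (beam hardening, metal), contrast phases, or
the manual fascia tracing of the clinical protocol. Passing phantom tests
therefore demonstrates that the banding arithmetic and the morphological
separation are correct on their stated geometry — not that the separation
rule matches a radiologist on difficult anatomy.

## Measurement processing

* **Reliability gate.** Duplicate-rater measurements are compared per
  measure by Spearman's ρ (average-rank ties) on the height-normalized
  values, pooling both timepoints; a measure is retained iff ρ > 0.85,
  read strictly. Constant value lists have undefined ρ and are dropped with
  an explicit reason. Because both raters share each patient's height,
  gating on normalized or raw values is equivalent for a rank statistic.
* **Averaging.** Retained measures are the arithmetic mean of the two
  raters; normalization and averaging commute (equal heights), which the
  suite asserts.
* **Deltas.** Follow-up change is final − initial (gain positive) per
  measure, only for second CTs ≥ 365 days after diagnosis; earlier
  follow-ups are excluded with a reason, and reversed chronology is an
  error.
* **Missingness filter.** Variables (never patients) with
  strictly more than 40% missing values are dropped and reported.
* **TMA bookkeeping.** When a muscle band is dropped by the gate (the
  default simulation degrades HDMA, mirroring the reference study's removal
  of high-density muscle), TMA is *not* recomputed as the sum of retained
  bands: it remains its own banded measure, reproducing the reference
  cohort's bookkeeping in which printed TMA slightly exceeds the sum of the
  retained bands.

## The statistical battery

* **Routing.** Continuous variables: Shapiro–Wilk per group at α = 0.05;
  all groups compatible with normality → t-test (two groups) or one-way
  ANOVA; otherwise Mann–Whitney U or Kruskal–Wallis. Categorical variables:
  χ². Groups with fewer than three values force the nonparametric route
  with a warning.
* **Coincidence networks.** Continuous variables are median-dichotomized
  (strictly above the median is "high"; both levels become category
  indicators; already-logical columns pass through, making the operation
  idempotent; constant variables are rejected). For each category pair the
  adjusted standardized residual of the joint-presence cell,
  d = (O − E)/√(E(1 − pᵣ)(1 − p꜀)), is ~N(0,1) under independence. An edge
  requires d above a z-threshold with one-sided p < α. The default
  threshold is the one-sided 1.645 rather than the two-sided 1.96:
  co-occurrence is a directional hypothesis, and reference analyses of this
  kind report residuals between ~1.7 and ~4.6 as significant at p < 0.05,
  which is consistent only with the one-sided convention. The threshold is
  a parameter, so the two-sided convention is one argument away.
* **Multiple testing.** None by default, matching the descriptive practice
  of the reference analyses; Benjamini–Hochberg is available via
  `p_adjust = "BH"`.
* **Adjusted models.** One logistic model per measure:
  `outcome ~ measure + age + metastasis + ECOG + LDH + albumin + urea`,
  complete cases, Wald 95% CIs. ECOG enters as an ordinal numeric (0–3)
  and metastasis as one binary covariate — the simplest encodings, chosen
  because nothing in the source protocol indicates otherwise. Tumor-cause
  models exclude deaths from other causes (survivors vs tumor-cause
  deaths). Perfect separation is detected (non-convergence, exploding or
  aliased coefficients) and refit with a hand-implemented Firth/Jeffreys
  penalized Newton–Raphson, labelled `method = "firth"` in the output. An
  events-per-parameter warning fires below 10, which genuinely triggers at
  the reference cohort's size — those models are reported but
  under-powered, as in the source setting.

## Cohort simulation

The generator targets the reference 98-patient GEP-NET cohort summary:
marginal means/SDs for age, sex, height, BMI, ECOG, grade, metastasis,
albumin, LDH, urea, glucose and fibrinogen, baseline composition marginals,
33.7% overall mortality, and 62% follow-up availability with intervals
uniform on 1–8 years. Simplifications worth knowing: marginals are
independent truncated normals (real composition measures are correlated,
and the simulated TMA variance — a sum of independent bands — is therefore
larger than the printed TMA SD); biochemical skew (LDH, chromogranin A) is
only partially modelled; missingness is MCAR at configured per-variable
rates, including a 50%-missing chromogranin A column placed to exercise
the >40% filter.

Outcome structure: mortality is logistic in the **latent** follow-up
changes plus the six confounders. The intercept is solved numerically so
the expected death proportion equals the target (centering by the mean
linear predictor alone is biased toward 0.5 at this predictor spread). The
default planted effects are +0.389 per cm²/m² on ΔLDMA and −0.15 on ΔNDMA:
the ratio is chosen so that, under the default delta variances,
cov(ΔTMA, linear predictor) = 0.389·var(ΔLDMA) − 0.15·var(ΔNDMA) = 0 — the
simulated world in which myosteatotic remodelling drives mortality while
total muscle change carries no signal, which is exactly the dissociation
the reference analysis reports.

Measurement error: two rater versions of every measure, independent
Gaussian noise of sd = marginal SD / 3.5 per measure (inter-rater Spearman
≈ 0.9, comfortably above the 0.85 gate at cohort sizes), with totals formed
from the noisy components so every record satisfies additivity. HDMA is
degraded by default to ρ ≈ 0.6 so the gate has a real casualty. A scalar
`rater_noise_sd` in cm²/m² is accepted, but a single absolute sd cannot put
measures whose SDs span 0.1–60 cm²/m² all near ρ = 0.9, hence the
proportional default.

Parameter-recovery checks run with `rater_noise_sd = 0`: with the default
noise, rater-averaged deltas carry classical measurement error and the
fitted coefficient is attenuated by var(Δ)/(var(Δ)+τ²) ≈ 0.83 for ΔNDMA — a
real errors-in-variables phenomenon, not an estimator defect, so estimator
consistency is assessed on noise-free measurements and the attenuated runs
are still directionally significant at n = 2,000.

## Problem sizes and numerical details

The test suite and acceptance script use: 25 noise seeds for phantom
recovery on the default 256×256 phantom; 100 random grids for the
band-partition/brute-force identity; 1,000 random 2×2 tables for the
Haberman formula identity (agreement to 1e−12) and 10,000 for its null
calibration; 50 independent cohorts of n = 2,000 with 10 binary variables
for network error control; 25 cohorts of n = 2,000 for planted-effect
recovery and for null CI coverage. These sizes make every stochastic check
stable to well inside its asserted band on a single CPU in a few minutes.

Floating-point: band areas are integer pixel counts times pixel area;
identities that mix summation orders (e.g. TMA versus the sum of five band
areas) are asserted at 1e−12, far below one pixel area. Random number
streams are isolated (`layout_seed` vs `seed`; generators save and restore
the global RNG state), so generation never perturbs a caller's stream.

## Known limitations

* The compartment-separation rule is validated on ring phantoms only; real
  abdominal anatomy (fascia breaks, hernias, contrast-filled bowel against
  the wall) can defeat it, and no claim is made otherwise.
* The simulator's independent marginals understate the strong correlations
  between real composition measures; cohort-level statistics exercised on
  it validate the machinery, not clinical effect sizes.
* Cause-of-death proportions among deaths (70% tumor / 15% toxicity / 15%
  other) are a stand-in: the reference setting defines the categories but
  not their rates.
* Only single-slice 2-D inputs are supported; L3 level selection, 3-D
  segmentation and time-to-event modelling are out of scope.
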