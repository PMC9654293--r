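# l3compo

Body-composition analysis of a single axial CT slice at the third lumbar
vertebra (L3), for clinical researchers studying sarcopenia, myosteatosis
and fat distribution as prognostic markers — e.g. in gastroenteropancreatic
neuroendocrine tumors (GEP-NETs), where changes in muscle quality during
follow-up have been linked to mortality.

The single L3 slice is the standard proxy for whole-body composition.
Tissues are quantified by Hounsfield-unit (HU) windows applied within
spatial compartments:

| Measure | HU window | Compartment |
|---|---|---|
| SFA (subcutaneous fat) | −190 … −30 | subcutaneous ring |
| VFA (visceral fat) | −190 … −30 | visceral cavity |
| IMFA (intermuscular fat) | −190 … −30 | muscle wall |
| TFA (total fat) | — | SFA + VFA + IMFA |
| VLDM / LDMA / NDMA / HDMA / VHDMA | −29…−1 / 0…34 / 35…100 / 101…150 / 151…199 | muscle wall |
| TMA (total muscle) | −29 … 199 | muscle wall |

The five muscle windows tile −29…199 exactly, so TMA is the sum of its
bands by construction. Areas (cm²) are normalized by squared height
(cm²/m²), duplicate-rater measurements are gated by Spearman reliability
(retained iff ρ > 0.85) and averaged, and follow-up change Δ = final −
initial is computed for patients whose second CT is ≥ 1 year after
diagnosis.

The cohort layer implements the statistical battery of such studies:

- group comparisons routed by Shapiro–Wilk normality (t / ANOVA vs
  Mann–Whitney / Kruskal–Wallis; χ² for categorical variables);
- Spearman correlation matrices (pairwise-complete, t-approximation
  p-values);
- coincidence networks over median-dichotomized categories, with edges
  weighted by the adjusted standardized (Haberman) residual of the
  joint-presence cell, d = (O − E)/√(E(1 − pᵣ)(1 − p꜀)), ~N(0,1) under
  independence;
- confounder-adjusted logistic regression of mortality,
  `outcome ~ measure + age + metastasis + ECOG + LDH + albumin + urea`,
  reporting OR = exp(β) per cm²/m² with Wald 95% CIs (Firth-penalized
  fallback under separation), for overall and tumor-cause mortality.

Because real patient cohorts of this kind are not redistributable, the
package ships first-class synthetic ground truth: CT ring phantoms whose
compartment areas are known exactly from the rasterized masks (so zero-noise
recovery is pixel-exact), and cohort simulations with published-cohort-like
marginals and planted mortality effects.

## Worked example

```r
library(l3compo)

ph  <- generate_phantom(phantom_spec(tissue_hu_sd = 10, seed = 1))
rec <- measure_slice(ph$slice, height_m = 1.70)
rbind(truth = ph$truth, recovered = rec$area_cm2)
#>             SFA    VFA IMFA    TFA VLDM  LDMA  NDMA  HDMA VHDMA   TMA body_area
#> truth     88.24 106.47 8.95 203.66 5.40 12.58 23.10 17.50  8.75 67.33    358.16
#> recovered 88.24 106.47 9.08 203.79 5.59 12.20 23.22 17.61  8.58 67.20    358.16
```

Every measure of a phantom with realistic HU noise (sd 10) is recovered to
within a few percent; with `tissue_hu_sd = 0` the recovery is exact. On the
cohort side (the `analysis/` drivers run this end to end on a simulated
98-patient cohort):

```
reliability gate: dropped HDMA (rho 0.59); retained rho range 0.89-0.94
missingness filter: dropped chromogranin_a (48% missing)
adjusted odds ratios per cm2/m2 of follow-up change (overall mortality):
  delta_LDMA       OR 1.650 [1.244, 2.189] p = 0.001
  delta_NDMA       OR 0.707 [0.568, 0.880] p = 0.002
  delta_TMA        OR 1.000 [0.912, 1.097] p = 0.994
```

Low-density muscle gain is a mortality risk factor and normal-density
muscle gain is protective, while total muscle change carries no signal —
the dissociation the simulator plants (myosteatosis, not muscle quantity,
drives outcome) and the analysis recovers.

## Analysis workflow

Numbered drivers under `analysis/` run the study end to end, writing tables
under `results/`:

```sh
Rscript analysis/01_phantom_validation.R   # segmentation vs known truth
Rscript analysis/02_simulate_cohort.R      # 98-patient synthetic cohort
Rscript analysis/03_quantify.R             # gate, normalize, deltas, filter
Rscript analysis/04_cohort_analysis.R      # tests, network, adjusted ORs
```

`run_pipeline(run_config(...))` performs the same sequence programmatically
with one seed and a machine-readable run report.

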