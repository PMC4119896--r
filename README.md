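# canimpact

Agreement between 3D and 2D severity indexes for impacted maxillary canines.

## The problem

Maxillary canines are, after third molars, the teeth most often found
impacted, and orthodontists use prognostic indexes to anticipate how long and
how difficult their treatment will be. The classical indexes are measured on
a panoramic radiograph (OPG), a 2D projection subject to magnification and
angular distortion in the anterior maxilla; the KPG index is a newer 3D
alternative measured on CBCT landmarks. `canimpact` implements both families
of measures and the full statistical apparatus needed to compare them, for
biostatisticians and orthodontic researchers who want a tested, reproducible
version of that comparison — including a synthetic-data generator, so the
whole pipeline runs without any radiographic images.

## What it computes

**KPG index (3D).** Six subscores, each an integer 0–5, for the cusp tip (C)
and root apex (R) on the mesiodistal (x), vertical (y) and bucco-palatal (z)
axes:

    KPG = C_x + R_x + C_y + R_y + C_z + R_z  ∈ [0, 30]

Each subscore counts the zone boundaries strictly exceeded by the landmark's
displacement from its ideal position. Totals are banded as easy (0–9),
moderate (10–14), difficult (15–19) and extremely difficult (20–30); a
modified scheme shrinks easy to 0–6, and a dichotomous scheme splits at
14/15 into easy-moderate vs difficult–very difficult for comparison with the
2D indexes. The millimetre zone boundaries are configurable
(`zone_thresholds()`) because the original instrument defines them only
graphically.

**Panoramic measures (2D).** Stewart's distance — the perpendicular distance
from the cusp tip to the occlusal line, with ≥ 14 mm predicting longer
treatment; Ericson–Kurol sectors — the cusp tip's mesiodistal sector 1–5
relative to the incisors, with sectors 1–2 (distal to the lateral incisor
midline) predicting easier treatment; and the α-angle of the canine long
axis to the inter-incisor midline, with ≈ 1 extra week of traction per 5°
(Crescini's rule; no accepted dichotomising cut-off, so it is never
cross-tabulated).

**Statistics.** Cohen's κ = (p_o − p_e)/(1 − p_e) for intrarater
reliability; tie-corrected Kendall's W for interrater concordance; the phi
coefficient φ = (ad − bc)/√(r₁r₂c₁c₂) and χ² tests with and without the
Yates continuity correction on 2×2 tables; sensitivity, specificity,
predictive values and likelihood ratios against a designated reference
standard; and the Bloch–Kraemer sample-size formula for detecting a kappa
above a null value.

## Worked example

Recompute the diagnostic accuracy of the KPG dichotomy against Stewart's
measurement from the packaged 105-canine contingency table:

```r
library(canimpact)
tb <- read_table_2x2(system.file("extdata", "table1.json", package = "canimpact"))
tb
#> 2x2 table: KPG (rows) x Stewart (cols), N = 105
#>         shorter longer
#> shorter      66     12
#> longer       12     15
diagnostics(tb, positive_label = "shorter", reference = "cols")
#> Diagnostic accuracy (reference: Stewart, positive: 'shorter')
#>   sensitivity  0.846
#>   specificity  0.556
#>   ppv          0.846
#>   npv          0.556
#>   lr_positive  1.904
#>   lr_negative  0.277
phi_coefficient(tb)   # 0.402
```

With Stewart's classification as the reference standard, the KPG dichotomy
recovers 84.6% of the shorter-treatment canines (sensitivity) but only 55.6%
of the longer-treatment ones (specificity); φ = 0.402 is a moderate
association.

The same analysis end-to-end on synthetic data:

```r
cohort <- generate_cases(simulation_config(n_cases = 105, seed = 2026))
cohort
#> Synthetic canine cohort: 105 canines from 84 patients (21 bilateral), seed 2026
run_study(cohort)
#> Comparison report over 105 canines (seed 2026, config 4452407f)
#>   KPG x Stewart: phi=0.307, Yates chi2=7.888 (p=0.005), sens=0.925, spec=0.320
#>   KPG x Ericson-Kurol: phi=0.363, Yates chi2=11.789 (p=0.001), sens=0.982, spec=0.265
#>   Stewart x Ericson-Kurol: phi=-0.075, Yates chi2=0.287 (p=0.592), sens=0.732, spec=0.204
panel <- simulate_raters(cohort)
round(intrarater_kappa(panel, "kpg_class"), 3)
#>    R1    R2    R3
#> 0.639 0.691 0.737
interrater_w(panel, "kpg_total", "t0")   # 0.948
```

Each rater re-measures every landmark with Gaussian noise at both
timepoints, so the kappas quantify how measurement noise propagates through
the dichotomised index; with the noise set to zero they are exactly 1.

## Limitations

The zone boundaries of the KPG subscores are calibration surrogates, not the
original instrument's anatomical zones; the panoramic projection is a simple
parametric distortion model, not focal-trough physics; and the published
Yates χ² statistics and correlation p-values for the three tables are not
derivable from the published counts themselves, so `reproduce_tables()`
reports that discrepancy as a warning and asserts only the derived accuracy
metrics. See the methods vignette (`vignettes/canine-impaction-agreement.Rmd`)
for the full modelling account.
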