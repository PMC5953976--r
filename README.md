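# petmtv

Metabolic tumour volume (MTV) — the total volume of FDG-avid tumour on a
baseline PET scan — is a prognostic biomarker in diffuse large B cell
lymphoma, but its value depends on *how* the tumour is delineated:
different threshold rules give strongly correlated yet numerically very
different volumes, and therefore very different "low vs high MTV"
cut-offs. `petmtv` implements the full comparison workflow for R users
working with volumetric SUV images:

* **Segmentation** — three threshold families on `suv_image` volumes
  (NIfTI in/out, axis-aligned grids, no resampling):
  * fixed threshold: connected component of `SUV >= 2.5` at a seed click;
  * 41% of maximum: component of `SUV >= 0.41 * max` inside an
    operator-drawn constraining box, with a heterogeneity check advising
    subdivision when regional maxima differ by more than 10%;
  * PERCIST: threshold `1.5 x mean + 2 x SD` from a 3 cm³ liver VOI
    (descending-aorta fallback when the liver is involved), a whole-image
    "tumour finder", and operator editing of physiological uptake.
  Total MTV sums disjoint lesion volumes; TLG adds volume × mean SUV.
* **Agreement** — consistency ICC (ICC(3,1), on cube-root transformed
  volumes), Kendall's tau-b, and non-parametric Bland–Altman (median
  bias, 2.5%/97.5% percentile limits of agreement), plus a
  Lilliefors-corrected KS normality check.
* **Prognosis** — ROC over observed MTV values with the
  closest-to-top-left optimal cut-off `argmin (1-sens)² + (1-spec)²`,
  low/high dichotomisation, Kaplan–Meier 5-year survival, log-rank test
  and univariate Cox hazard ratios (via the `survival` package).
* **Synthetic data** — ellipsoid phantoms with analytic ground-truth
  volumes, liver/aorta regions, brain/bladder analogues, observer-jitter
  perturbation, and calibrated 147-patient cohorts (skewed MTV that is
  normal on the cube-root scale, exponential group hazards), so every
  stage is testable without patient data.

See `vignettes/mtv-methods.Rmd` for the methods and the reasoning behind
every numerical convention.

## Worked example

```r
library(petmtv)

# A synthetic patient: two lesions (one heterogeneous), liver, aorta,
# brain/bladder hot spots, plus its operator annotations.
ph <- generate_phantom(example_phantom_spec(seed = 7))
recs <- measure_patient(ph$image, ph$annotations)
recs$fixed25
#> <mtv_record> patient phantom_007, method fixed25: total MTV 14.17 cm^3 (2 lesions), TLG 95.32

# Prognostic analysis on a calibrated synthetic cohort
co <- generate_cohort(cohort_spec(seed = 5))
fit <- mtv_prognosis(co$mtv_fixed25, co$time_pfs, co$event_pfs)
fit
#> <mtv_prognosis> AUC 0.739 (0.632-0.847, n_roc = 94), cut-off 439.3 cm^3
#>   low  MTV: n = 60, events = 12, 5-y survival 87.0%
#>   high MTV: n = 87, events = 49, 5-y survival 39.3%
#>   log-rank chi2 = 25.61 (p = 4.18e-07); HR 4.55 (2.40-8.61, p = 3.42e-06)
```

The cohort is generated with a true cut-off of 400 cm³ and 5-year PFS of
85% (low) vs 43% (high); the fitted object shows the ROC-derived cut-off
landing near the generating one and the Kaplan–Meier/Cox stage
recovering the survival separation. `run_segment`, `run_compare`,
`run_survival` and `run_pipeline` batch these stages over many patients
(`inst/cli/petmtv.R` wraps them for shell use with a YAML config).

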