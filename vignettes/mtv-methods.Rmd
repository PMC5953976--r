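---
title: "Measuring metabolic tumour volume and its prognostic value: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring metabolic tumour volume and its prognostic value: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petmtv)
```

## The problem

Baseline metabolic tumour volume (MTV) — the total volume of FDG-avid
tumour on a pretreatment PET scan — is a prognostic biomarker in diffuse
large B cell lymphoma. The practical obstacle is that MTV depends on how
the tumour is delineated: the optimal cut-off separating "low" from
"high" MTV patients can differ severalfold between segmentation rules
even when every rule predicts outcome with similar accuracy. This
package implements the three threshold families in routine use, the
agreement statistics needed to compare them, and the prognostic analysis
that turns an MTV column into a survival stratification, so the whole
chain can be exercised and audited on synthetic data with known ground
truth.

## Image model

An `suv_image` is a dense 3-D array of SUV values with per-axis voxel
spacing in mm and the physical position of the first voxel centre.
Voxel indices are 1-based, the natural convention in R; the centre of
voxel $(i,j,k)$ sits at $\mathrm{origin} + ((i,j,k) - 1)\cdot
\mathrm{spacing}$. Anisotropic spacing is supported throughout and no
operation ever resamples or interpolates: every statistic is computed
over original voxels, and volumes are exactly
$\text{voxel count} \times \prod(\mathrm{spacing})/1000$ cm³.

A cuboid VOI owns a voxel if and only if the voxel *centre* lies inside
the closed box; boundary ties count as inside. This rule is
deterministic and resolution-independent, which matters because no
vendor manual states its membership convention. NIfTI input is accepted
only when the affine is a pure positive scaling plus translation —
rotated or flipped volumes must be reoriented upstream, because silently
reinterpreting axes is the classic source of left/right errors.

## The three segmentation methods

All thresholds are inclusive (`>=`), matching how they are stated in
the literature.

* **Fixed threshold (`segment_fixed`)** — the connected component of
  $\{SUV \ge 2.5\}$ containing an operator's seed click. A seed below
  the threshold is an operator error and is rejected, not silently
  moved.
* **41% of maximum (`segment_pct_max`)** — a two-stage procedure: a
  constraining box isolates one lesion, the maximum SUV $M$ inside the
  box sets the threshold $0.41M$, and the mask is the component of
  supra-threshold in-box voxels containing the argmax. Disconnected
  islands inside the box are treated as separate lesions that need
  their own box. When neighbouring regions have maxima differing by
  more than 10% (relative to the larger), `heterogeneity_check` advises
  subdividing, because a merged region's threshold would be set by the
  hotter compartment and under-segment the cooler one. The check only
  advises; it never re-contours.
* **PERCIST (`percist_tumor_finder`)** — the threshold is
  $1.5 \times \text{mean} + 2 \times \mathrm{SD}$ of a liver reference
  VOI (a cuboid of volume 3 cm³; the only stated constraint is the
  volume, so the default is a cube of edge $3000^{1/3} \approx
  14.42$ mm). When the liver itself is involved by lymphoma — a
  clinical judgement the caller supplies, never inferred — a fixed
  $10\times10\times20$ mm VOI in the descending thoracic aorta is used
  instead. The finder labels *every* supra-threshold component in the
  image, in decreasing volume order; physiological uptake (brain,
  bladder, myocardium) is removed afterwards by the operator through
  `edit_labels`, mirroring clinical workflow. The exploratory
  $1\times\text{mean} + 2\,\mathrm{SD}$ variant is available via
  `percist_config(multiplier = 1)`.

Connectivity defaults to 26 (vertex-adjacent), the behaviour of typical
clinical tools; 6 and 18 are available for sensitivity analyses. The
reference-VOI SD uses the sample ($n-1$) denominator by default; since
vendor software does not document its denominator, `sd_type =
"population"` is offered as well.

Total MTV is the sum of disjoint lesion volumes and TLG accumulates
volume times mean SUV per lesion, so that for a single lesion TLG is
exactly MTV times the mean SUV within it.

## Agreement statistics

MTV distributions are strongly right-skewed, so the consistency ICC is
computed on cube-root transformed values by default. The ICC variant is
pinned to two-way mixed-effects, single-measure, consistency
(ICC(3,1)): $({MS}_R - {MS}_E)/({MS}_R + (k-1){MS}_E)$ with $k = 2$,
with the p-value from the $F = MS_R/MS_E$ test — a bootstrap would be
equally defensible but the F test is deterministic and cheap. Kendall's
tau is the tie-corrected tau-b with the asymptotic p-value; it is
invariant under monotone transforms, so raw and cube-root MTV give
identical tau.

The Bland–Altman analysis is non-parametric: median difference and the
2.5th/97.5th percentiles of the differences as limits of agreement, on
*untransformed* volumes, with differences oriented A − B in the order
supplied. The quantile rule is pinned to linear interpolation between
order statistics (R type 7) so the limits are bit-reproducible. The
slope of differences on pair means is reported descriptively to flag a
trend of disagreement with magnitude.

The normality pre-check is a one-sample KS test against a normal law
with estimated mean and SD. Testing with estimated parameters makes the
plain KS p-value anticonservative, so the Lilliefors correction is on
by default and the uncorrected test is an explicit opt-out.

## Prognostic analysis

The ROC treats progression as a binary endpoint within a five-year
horizon (365.25-day years, pinned): events at or before the horizon are
positives, follow-up beyond it without an event is negative, and
patients censored before the horizon are excluded from the ROC — their
five-year status is unknown — while remaining in Kaplan–Meier, log-rank
and Cox analyses, which handle censoring natively. This exclusion rule
is a documented choice, not a claim about how any particular study
handled it.

Candidate cut-offs are the observed MTV values; classification is
high-risk when $MTV \ge t$ (inclusive). The optimal cut-off minimises
$(1-\text{sens})^2 + (1-\text{spec})^2$ — the point nearest the
top-left corner — with ties broken towards the smallest threshold,
which favours sensitivity and is deterministic. AUC is the trapezoidal
area; its confidence interval comes from DeLong's method (bootstrap
optional). The Kaplan–Meier median is the first time the curve drops to
or below 0.5 and is reported as undefined when the curve never does.
Cox regression uses the Breslow tie approximation by default (Efron
available); a monotone partial likelihood (complete separation of
events) is reported as an error with the offending coefficient rather
than returned as a huge hazard ratio.

## What the synthetic data emulate — and what they do not

**Phantoms** are ellipsoidal lesions on a noisy background with a
liver-like box region, an aorta region and brain/bladder analogues.
Ellipsoids are deliberately unrealistic: their volume
$\frac{4}{3}\pi abc$ is analytic, giving exact volume-recovery oracles.
Lesions compose onto the background by voxelwise maximum, so lesion
voxels hold exactly their specified SUV — essential when a test asserts
that a threshold includes or excludes a compartment. Heterogeneous
lesions are two-compartment (hot core, warm rim), the minimal structure
that separates the 41% method from the fixed threshold: with core 10
and rim 3, the rim passes $\ge 2.5$ but fails $\ge 4.1$. The default
study phantom uses rim SUV 4.5 so that all three methods agree on it
and observer effects are isolated to annotation placement.

Phantoms do **not** model PET physics: no point-spread blur, no partial
volume effect, no reconstruction noise texture, no scatter. Passing
volume-recovery tests therefore demonstrates correctness of the
geometry and threshold logic, not clinical accuracy on reconstructed
scans, where partial-volume effects bias small-lesion volumes
substantially.

**Observer perturbation** displaces seeds, box centres and
reference-VOI centres by bounded uniform jitter (default 2 mm),
deterministic per seed. Jittered seeds that land outside avid disease
are redrawn a bounded number of times — a real observer would re-click.
For the interobserver study the constraining boxes hug each lesion
(zero margin): with generous margins the 41% mask is insensitive to box
placement by construction, and the study would measure nothing.
Seed jitter inside a connected component cannot change a flood fill, so
the fixed-threshold method is exactly reproducible under small jitter —
which is precisely the mechanism behind its superior interobserver
agreement, reproduced by the package's tests.

**Cohorts** draw the fixed-threshold MTV as a cubed truncated normal:
$MTV^{1/3} \sim N(\mu, \sigma)$ conditioned positive, with
$\mu = 592^{1/3} \approx 8.40$ and $\sigma \approx 4.35$ calibrated so
the median is ~592 cm³ and the quartiles are roughly 147 and 1387 cm³.
This family is chosen over a log-normal because the defining empirical
feature being emulated is that *raw* MTV fails a normality check while
its *cube root* passes; a log-normal matching the same quartiles stays
visibly skewed after the cube root. The ~2.8% truncation below zero
leaves a slight departure from exact normality, so the Lilliefors test
at $n = 147$ rejects the cube-root sample in about 10% of seeds rather
than the nominal 5%.

The other MTV columns are derived per patient: a second fixed-threshold
"software" column with 1.5% log-scale noise; a 41% column equal to a
Beta-distributed fraction of the fixed column (mean ≈ 0.27); and a
PERCIST column equal to the fixed column with 3% noise, inflated by a
uniform 1.2–2.2 factor in a ~12% low-liver-uptake subset. Survival is
exponential within the low/high group defined by a generating cut-off
of 400 cm³: $\lambda = -\log S_{5y}/(5 \times 365.25)$ with five-year
PFS 85%/43% (OS 89%/55%) and uniform administrative censoring over a
1.3–7.9-year window. PFS and OS times are drawn independently per
endpoint; the generator emulates each endpoint's marginal structure,
not a joint multistate illness–death process, and encodes no covariates
other than MTV group.

## Problem sizes and reproducibility

The standard phantom is a $50^3$ grid at 2 mm spacing (100 mm cube) —
large enough that discretisation error of a ~7 cm³ lesion is under 1%,
small enough that a 50-phantom two-observer study completes in seconds.
Volume-convergence checks run at 4, 2 and 1 mm. Cohort analyses use
$n = 147$ with 50-seed replication for stochastic properties and 200
replicates for hazard-ratio recovery, where the simulation uses a 48%
high-MTV prevalence (the prevalence implied by the overall and
group-wise five-year PFS being emulated) and a true hazard ratio of
5.9. With roughly ten events in the low-MTV arm, the hazard ratio
estimate is noticeably biased upward on the ratio scale
($E[e^{\hat\beta}] \approx e^{\beta + \mathrm{var}(\hat\beta)/2}$), so
a mean estimate ~10% above truth at valid CI coverage is expected
behaviour, not a defect.

Every stochastic component takes an explicit integer seed; identical
spec plus seed reproduces phantoms, cohorts and jitter byte-for-byte.
The pipeline reports embed the resolved configuration and package
version.

## Known limitations

* No DICOM handling or SUV computation from activity/weight/dose; the
  input must already be an SUV volume on an axis-aligned grid.
* No automatic lesion detection or organ segmentation: seeds, boxes and
  reference-VOI centres are operator inputs by design.
* One connected component per constraining box in the 41% method; the
  reading of the two-stage recontouring procedure is documented in
  `?segment_pct_max` and alternatives (e.g. applying 41% to an initial
  coarse contour) are not implemented.
* The cohort generator reproduces summary structure (skewness, group
  survival, agreement ordering), not individual-patient realism; ratios
  between method cut-offs in any one simulated cohort are
  sampling-variable.
* Phantom tests bound geometric/logical correctness only; clinical
  validity of any threshold on reconstructed PET data is out of scope.
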