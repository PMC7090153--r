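---
title: "Dose-surface-histogram NTCP modeling of severe radiation dermatitis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-surface-histogram NTCP modeling of severe radiation dermatitis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skinNTCP)
```

## The problem

Severe acute radiation dermatitis (CTCAE grade 3: moist desquamation
outside skin folds) after thoracic radiotherapy is governed by the dose
received by the epidermis — a surface, a few millimetres thick, wrapped
around the body. Conventional normal-tissue complication probability
(NTCP) machinery is built on dose-*volume* histograms of solid organs and
carries over awkwardly: the natural summary for skin is the
**dose-surface histogram** (DSH), the area of skin receiving more than
each dose level. This package implements an end-to-end DSH-based NTCP
analysis — segmentation, DSH extraction, cohort statistics, model fitting
and internal validation — together with synthetic data generators that
reproduce the statistical structure the analysis assumes, so the whole
chain is testable without patient data.

## Skin segmentation

The body structure $\Omega$ is recovered from a CT-like volume by HU
thresholding. Two practical obstacles are the treatment couch (a thin
high-HU slab near the body) and partial-volume bridges. We smooth each
axial slice with a moving-window mean filter (default $5\times5$ voxels)
and threshold at $-250$ HU: thin couch structures average toward air and
fall below the threshold, while the body core stays above it. The largest
26-connected component of that smoothed foreground seeds the body, and
the contour is recovered at full resolution as the thresholded voxels
connected to the seed — this removes the couch without eroding the true
boundary (on phantoms with a couch slab the result is voxel-identical to
the ground truth). Internal cavities (lungs, airways) are filled per
axial slice. Window size and threshold are conventions, not canonical
values, and both are exposed as arguments.

The skin of thickness $r$ is
$\mathrm{skin}_r = \Omega \setminus (\Omega \ominus B[r])$, the set
difference between the body and its morphological erosion by a spherical
element of radius $r$ (default 3 mm, an approximate mean skin thickness).
The element is rasterized in physical millimetres on the possibly
anisotropic grid. Because background voxel *centers* lie on average half
a voxel beyond the continuous body boundary, naive rasterization erodes
about half a voxel too little; we rasterize at radius
$r + \bar h/2$ (mean spacing $\bar h$), with ties at exactly $r+\bar h/2$
excluded. On a 20 mm sphere at 2 mm voxels this keeps both the eroded
ball and the 3 mm shell within 5% of their closed-form volumes, which the
literal per-axis rasterization misses by over 10%.

## DSH extraction

The DSH is defined as the thin-shell limit of the skin DVH,
$\mathrm{DSH}(x) = \lim_{r \to 0} \mathrm{DVH}(x)_{\mathrm{skin}_r}/r$.
Two estimators are implemented:

* **Boundary faces (default).** Exposed voxel faces on
  $\partial\Omega$ are enumerated; each carries the dose interpolated at
  its center. A plain sum of face areas converges to the integral of the
  $L^1$ norm of the surface normal (3/2 of the true area on a sphere), so
  each face is weighted by $|\hat n_a|$ of the local unit normal
  estimated from the gradient of a box-smoothed indicator; the weighted
  total then converges to the true area (within 1.2% of $4\pi R^2$ on a
  40 mm sphere at 2 mm voxels, with the error roughly halving at each
  grid refinement). The estimator has no free parameter and is
  grid-deterministic.
* **Shell extrapolation (cross-check).** Shell volumes above each dose
  level are computed for thicknesses of 1-3 voxel units with
  partial-volume weights from the Euclidean distance to the boundary, a
  quadratic is put through the three points, and the DSH is its
  derivative at zero thickness (since $\mathrm{vol}(0)=0$, the limit
  $\mathrm{vol}(r)/r$ equals $d\,\mathrm{vol}/dr|_0$; the half-voxel
  boundary offset is absorbed by the constant term). The two estimators
  agree within 5% on smooth phantoms, and the face estimator is checked
  against closed-form sphere areas and spherical-cap laws in the test
  suite.

Absolute DSHs (cm²) are normalized to percent of body surface area,
computed by the Du Bois formula
$\mathrm{BSA} = 0.007184\,\mathrm{m}^2 \cdot (W/\mathrm{kg})^{0.425}
\cdot (H/\mathrm{cm})^{0.725}$. The metrics extracted are $S_x$ (percent
of BSA receiving more than $x$ Gy — *strictly* more, matching the
definition — in 1 Gy steps), $D_x$ (minimum dose to the hottest $x\%$ of
BSA, 5% steps), $D_{2\%}$, and the surface-weighted mean dose. Curves are
stored at 0.1 Gy resolution and metrics interpolate linearly between
edges. Proton doses in Gy(RBE) are treated numerically as Gy.

## NTCP models

**DSH-recast LKB.** The generalized equivalent uniform dose of a DSH is
the surface-weighted power mean
$\mathrm{gEUD} = \big(\sum_i s_i\, d_i^{1/n}\big)^{n}$, with $d_i$ the
bin-center doses and $s_i$ the differential surface fractions normalized
to sum to one **over the in-scan skin surface**. The alternative
normalization (fractions of total BSA, summing below one) is available
but not the default: it breaks the identity
$\mathrm{gEUD}(\text{uniform } D) = D$ on which the interpretation of
TD50 — the uniform surface dose giving 50% complication probability —
rests. The dose-response is the probit
$\mathrm{NTCP} = \Phi\!\big((\mathrm{gEUD} - TD_{50})/(m\,TD_{50})\big)$.
Parameters $(TD_{50}, m, n)$ are fitted by maximizing the Bernoulli
log-likelihood (probabilities clipped at $10^{-12}$) with Nelder-Mead in
log-parameter space from a log-spaced multi-start grid, inside the box
$TD_{50} \in [0.5, 200]$ Gy, $m \in [0.01, 2]$, $n \in [0.01, 2]$ — wide
enough that published skin-toxicity estimates and their intervals sit far
from the edges. Confidence intervals come from the profile likelihood: a
bound is where the profile log-likelihood (re-optimizing the other two
parameters) drops by $\chi^2_1(0.95)/2 = 1.92$, located by bisection to
$10^{-3}$; a bound that cannot be bracketed inside the box is reported
one-sided with a warning. On large simulated cohorts the profile
intervals agree with the Wald intervals from the numerical Hessian, and
over 200 simulated 166-patient cohorts the 95% TD50 interval covers the
generating value at the nominal rate (tested at 90-99%).

**Stepwise logistic.** Candidates are screened univariably ($p < 0.1$;
Mann-Whitney for continuous, Pearson $\chi^2$ — Fisher's exact on 2x2
tables when any expected count is below 5 (Cochran's rule) — for
categorical variables), then thinned by a greedy collinearity filter:
walking candidates by ascending univariable $p$, any variable with
Spearman $|R_s| \ge 0.75$ against an already-kept one is dropped, so each
collinear family (the $S_x$ metrics are mutually rank-correlated well
above 0.9) keeps its most endpoint-associated representative. Selection
is forward stepwise — enter the variable with the smallest
likelihood-ratio $p$ if below 0.05, remove any whose Wald $p$ exceeds
0.10, iterate to a fixed point with a visited-state guard against
enter/remove cycling. The stepwise direction and thresholds are standard
conventions; the entry/removal pair (0.05/0.10) keeps removal laxer than
entry, which prevents most cycling in the first place. Odds ratios are
$e^{\hat\beta}$ with Wald 95% intervals.

## Validation

The leave-one-out driver re-runs the *entire* pipeline — screening,
collinearity filter, stepwise selection, fitting — on each size-$(n-1)$
training set and predicts the held-out patient; a test asserts the
selection is genuinely recomputed per fold. Folds whose training set
loses its last event are logged and excluded. Discrimination is the rank
(Mann-Whitney) AUC with midrank tie handling, its CI from 2000 stratified
bootstrap replicates (events and non-events resampled separately — the
assumption-light choice at a 9% event rate). Cutoffs maximize Youden's
$J$ over midpoints of adjacent observed values, ties broken toward higher
specificity; accuracy and balanced accuracy are evaluated at the Youden
cutoff derived from the same prediction set being summarized (training
cutoff for training metrics, cross-validated cutoff for cross-validated
metrics). Calibration groups patients into 5 equal-count bins — with
about 15 events a cohort of 166 cannot support deciles — and fits
observed event fraction on mean prediction by weighted least squares
(weights = bin counts), reporting slope and intercept with standard
errors and per-bin 68% Wilson intervals for plotting.

## Synthetic data: what it emulates and what it does not

Two fixture paths exist deliberately. The **volumetric path** (phantom →
segmentation → DSH) emulates geometry: elliptic-cylinder or sphere bodies
with an optional couch slab, and analytic ray-marched dose fields —
collimated coplanar beams with a photon-like build-up/attenuation profile
(surface dose 22% of the per-beam peak, 15 mm build-up, exponential exit)
or a proton-like flat entrance plateau (88% of peak) with a sharp distal
fall-off, a posterior-plus-obliques three-field arrangement for protons
and 8 equidistant fields for photons. These defaults reproduce the
qualitative modality contrast the field expects: photons expose more
surface below ~12 Gy, protons more in the mid-dose range, with a single
mean-curve crossing near 23 Gy. It is not a transport calculation: no
scatter, no heterogeneities, no realistic anatomy — only the
surface-dose structure the DSH stages consume.

The **parametric path** draws relative DSH curves directly around a
monotone template through the published cohort medians of $S_5 \ldots
S_{45}$, with four independent per-patient lognormal perturbations:
amplitude (sd 0.35 on the log scale, matched to the spread of the
published $S_{20}$ range), dose-axis stretch (sd 0.18, max-dose jitter),
in-scan surface jitter (sd 0.10), and a curvature exponent on the
template (sd 0.15). The curvature term matters for identifiability: with
amplitude and stretch alone, all curves are shape-equivalent and the
gEUD exponent $n$ is nearly unidentified at 15 events; independent shape
variation restores the information the fit needs. The one scalar the
published quantiles do not pin down — the in-scan surface at 0 Gy,
$S(0)$ — is fixed by requiring the stated generating LKB model
($TD_{50} = 9.5$ Gy, $m = 0.24$, $n = 0.62$) to reproduce the target 9%
event rate over the generated curve population; the calibration solves to
$S(0) \approx 21\%$ of BSA, a plausible thorax-scan fraction, and is
frozen as the template default. Model-recovery simulations use this
path; geometry tests use the volumetric one. Passing tests therefore
show that the *estimators and fitting machinery* behave correctly under
the assumed statistical structure — they cannot show that real skin
toxicity follows an LKB law, that real DSH curves are lognormal
perturbations of a common template, or that real segmentation noise is
absent.

Covariates (weight, height, age, GTV volume) are drawn from
range-truncated lognormal/normal distributions matched to published
medians and ranges only; no higher moments are available to match, and
covariates are linked to outcome only through the generating model.
Outcomes are Bernoulli draws of the per-patient generating NTCP, with
per-patient seed substreams so cohorts are reproducible patient by
patient under a single master seed.

## Numerical choices and degenerate inputs

* DSH storage at 0.1 Gy bins; gEUD uses bin centers, so a uniform dose is
  recovered to half a bin (use finer bins where exactness matters — the
  analytic anchor checks use $10^{-4}$ Gy).
* Probabilities are clipped at $10^{-12}$ in likelihoods; perfect
  separation in the logistic fit raises an error rather than returning a
  divergent estimate.
* Erosion with $r = 0$ is the identity; an empty body, an all-air scan, a
  zero margin, degenerate outcome vectors (all events or none) and
  constant covariates all raise immediate, specific errors.
* Youden ties break toward the larger cutoff (higher specificity); a
  constant prediction vector yields a degenerate cutoff with a warning,
  and constant predictions collapse calibration to a single bin, which is
  an error.
* Simulation sizes in tests (50 recovery cohorts, 200 coverage cohorts,
  2000 null replicates for the family-wise error check, 8 paired phantoms
  for the modality contrast) were chosen as the smallest runs whose
  Monte-Carlo noise is well inside the asserted tolerances.

## Known limitations

Dose fields are analytic cartoons; the segmentation assumes air
surrounds the body within the scan; DSH extraction ignores scan
truncation effects other than treating out-of-grid faces as exposed; no
fractionation (EQD2) correction, no chemotherapy covariate, no spatial
dose-surface maps, and no external validation — the cohorts here are
synthetic by construction.
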