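---
title: "Hemodynamic descriptors and a matched-pair rupture score: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hemodynamic descriptors and a matched-pair rupture score: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aneuhemo)
```

## The problem

Whether an intracranial aneurysm will rupture correlates with the shear
environment its wall experiences. Computational fluid dynamics (CFD)
produces, for each patient, a time-resolved wall shear stress (WSS) vector
field on a triangulated surface of the aneurysm sac (the *dome*) and its
parent vessel. Cohort studies summarise that field into a handful of
scalar descriptors per aneurysm, compare ruptured against unruptured
cases, and distil the independent risk factors into a bedside score.

Mirror aneurysms — bilateral aneurysms at symmetric arterial positions in
the same patient — allow a particularly clean design: each patient
contributes a ruptured and an unruptured lesion, so patient-level
confounders (age, sex, hypertension, smoking) cancel by matching, and the
correct regression model is the *conditional* logistic likelihood that
conditions those nuisances out.

`aneuhemo` implements that whole chain downstream of the CFD solve:
descriptors from WSS fields, 1:1 conditional logistic modelling,
and construction/validation of an integer-point risk score. The CFD solve
itself (and the angiographic vessel reconstruction that feeds it) is out
of scope; the package starts from the WSS field and records flow settings
only as provenance metadata.

## Descriptors

All descriptors are computed per face of the triangulated wall from the
instantaneous WSS vectors $\mathbf{w}_i(t)$ over one cardiac cycle of
period $T$, integrated with the periodic trapezoid rule (the cycle is
closed from the last sample back to the first, which makes the average of
a uniformly sampled sinusoid exact).

* **WSS** $= \frac{1}{T}\int_0^T |\mathbf{w}_i|\,dt$ — time-averaged
  magnitude, Pa.
* **NWSS** $=$ WSS divided by the area-weighted mean WSS of the
  parent-vessel region — dimensionless, removes the inflow scale.
* **OSI** $= \frac12\left(1 -
  \frac{|\int \mathbf{w}_i\,dt|}{\int |\mathbf{w}_i|\,dt}\right)$ —
  0 for unidirectional shear, 0.5 for complete reversal.
* **RRT** $= 1/\left|\frac{1}{T}\int \mathbf{w}_i\,dt\right|$ — reciprocal
  mean-vector magnitude, Pa⁻¹; identically
  $1/[(1-2\,\mathrm{OSI})\cdot \mathrm{WSS}]$, and the package asserts the
  two forms agree to $10^{-10}$ wherever defined.
* **WSSG** — magnitude of the spatial variation of the time-averaged WSS
  vector in the flow-aligned frame,
  $\sqrt{(\partial\tau_p/\partial p)^2 + (\partial\tau_q/\partial q)^2}$,
  where $p$ is the direction of the time-averaged WSS on the face and $q$
  its in-plane perpendicular. Reported in Pa/m.
* **CHP** $= \omega_1\,\mathrm{WSSnorm} + \omega_2\,(2\,\mathrm{OSI})$ —
  a convex combination of a normalized low-WSS term and the OSI,
  in $[0, 1]$.
* **LSA** — fraction of dome area with WSS below 10% of the parent-vessel
  mean.

Per aneurysm the package reports the minimum, maximum, area-weighted mean
and max/min ratio of the first six families over the dome, plus the
scalar LSA — the standard cohort-table row.

### Numerical choices

**Gradient operator.** WSSG needs a surface gradient. We use linear shape
functions on triangles: face-centred values are transferred to vertices
by area weighting, the linear interpolant over each triangle then has a
constant in-plane gradient. This is the standard P1 operator — exact for
linear fields given vertex data (a machine-precision test), first-order
accurate for face data (an O(h) convergence test on a quadratic field).
Because the components $\tau_p$, $\tau_q$ live in per-face frames, the
implementation differentiates the three Cartesian components of the
time-averaged WSS field once and contracts with each face's frame, which
is algebraically identical and needs only three gradient evaluations.

**CHP normalization.** The WSS term must map the sac's own WSS range to
$[0,1]$ with *low* WSS scoring high — thin, rupture-prone wall is
low-WSS/high-OSI. The default is the quarter-superellipse
$\mathrm{WSSnorm} = 1 - (1 - y^4)^{1/4}$ with
$y = (\mathrm{WSS}-\mathrm{WSS}_{max}) /
(\mathrm{WSS}_{max}-\mathrm{WSS}_{min})$, which equals 1 at the sac
minimum and 0 at the maximum and weights mid-range WSS toward the low
end. The published form of this normalization is typographically garbled
in the source literature; the superellipse reading is our documented
interpretation, and a plain linear variant
($\mathrm{WSSnorm} = -y$) is selectable through `chp_config()` for
sensitivity analysis. The weights default to
$\omega_1 = \omega_2 = 1/2$; only their sum being 1 is prescribed.
Extrema are taken over the dome of the same aneurysm, making CHP a
within-sac map.

**Means and extrema.** Dome means are area-weighted by default (CFD
surface meshes are rarely uniform); an unweighted mean is available for
sensitivity checks. Extrema are over faces. Faces where a descriptor is
undefined — OSI on an identically zero series, RRT where the mean vector
vanishes (OSI = 0.5), WSSG where the $p$ direction is undefined — are
reported `NA`, excluded from summaries, and counted.

**Rounding.** Everything is computed and stored at full precision;
`round_descriptors()` produces the conventional 3-decimal reporting
variant at the output layer only.

## The synthetic phantom

No patient data ship with the package; the generator provides meshes and
fields with *known* ground truth so every descriptor has an independent
oracle.

The phantom is a hemispherical dome (default radius 2 mm) seated on a
cylindrical parent segment (radius 1.5 mm, length 8 mm), triangulated at
a target edge length (default 0.15 mm). Around the dome apex a spherical
cap with a designed area fraction is labelled *low-shear* and carries 5%
of the parent WSS; a band below it can be labelled *oscillatory* and
follows $\cos(2\pi t/T) + 0.2$, reversing direction within the cycle
(OSI ≈ 0.35). Ordinary dome faces carry a base magnitude (default 6 Pa,
with a ±10% per-face jitter drawn once from the seed) and parent faces
exactly the parent level (default 7 Pa); those levels sit in the range
reported for real cohorts. The magnitude waveform defaults to
$1 + 0.5\sin(2\pi t/T)$ with $T = 0.8$ s sampled at 100 steps per cycle —
the usual CFD convention — so cycle averages have closed forms. All
vectors are constructed in each face's tangent plane.

Because cap area is an exact function of polar angle, the designed
low-shear fraction is the ground truth for LSA; tests require recovery
within 0.02 at the default resolution. What the phantom does *not*
emulate: secondary-flow direction fields, spatially correlated WSS
textures, irregular sac shapes, or inter-aneurysm variability of the
waveform — so passing tests demonstrate correctness of the descriptor
calculus, not realism of any particular clinical distribution.

## Matched-pair statistics

For 1:1 pairs the conditional likelihood reduces to a logit without
intercept on within-pair covariate differences $d_j$:
$L(\beta) = \prod_j \sigma(\beta^\top d_j)$. `conditional_logit_fit()`
maximises this by Newton–Raphson with step-halving to a gradient norm
below $10^{-8}$; the covariance is the inverse observed information, and
odds ratios with 95% Wald intervals follow as $e^{\beta \pm 1.96\,se}$.
Complete separation (a covariate whose nonzero differences all share a
sign makes the likelihood unbounded) is detected and reported with the
covariate named rather than returning a divergent estimate. The fit is
cross-checked in the test suite against `survival::clogit` and against a
brute-force likelihood grid.

The cohort simulator draws pair differences from configurable
distributions, splits them symmetrically around a pair baseline, and
assigns the case by the conditional-logistic probability — exactly the
model the estimator inverts, which is what makes parameter-recovery,
type-I-error and coverage simulations meaningful. Default effect sizes
are the published log-odds triple (4.253, 1.154, 1.747) on a continuous
LSA-like difference (normal, sd 0.15, matching LSA's 0–1 scale) and two
indicator differences (independent Bernoulli(0.5) per member); the
default cohort size is 91 pairs, the size of the motivating study.

**Stepwise selection.** The multivariate model is built forward from the
univariately significant set: entry by likelihood-ratio p < 0.05, removal
when a retained covariate's Wald p rises above 0.10, ties broken by
candidate order. The source analysis states only "stepwise forward"; the
entry/stay thresholds here are the common defaults and are configurable
arguments, echoed in the report's provenance block.

## Risk score

`allocate_points()` converts the retained odds ratios to integer points
with $\mathrm{points}_i = \lceil OR_i / \min_j OR_j \rceil$ — the
simplest rule consistent with the published mapping of ORs
(70.322, 3.171, 5.740) to points (23, 1, 2). Two alternatives (rounded OR
ratio, rounded log-OR ratio) are selectable; the choice is an inference,
as no mapping rule is stated in the source. Continuous terms contribute
`points * value`; dichotomised terms contribute their points when the
descriptor *strictly* exceeds its threshold. `published_risk_model()`
ships the reference model
$23\cdot\mathrm{LSA} + 1\cdot 1\{\mathrm{CHP}_{mean} > 0.087\} +
2\cdot 1\{\mathrm{WSSG}_{ratio} > 893.180\}$ with score cutoff 1.283 (and
the companion univariate LSA cutoff 0.016) for applying the published
model to new descriptor tables.

ROC machinery is implemented in-package because the DeLong comparison
needs per-observation placement values: the AUC is the Mann–Whitney
statistic with ties counted ½ (asserted equal to exhaustive pair counting
in tests), the Youden cutoff is the midpoint between adjacent observed
values at the argmax of sensitivity + specificity − 1 (ties toward higher
specificity), and `delong_compare()` builds the paired-AUC variance from
the placement values with a normal test on the difference. The DeLong
variance is validated against a stratified paired bootstrap and the
p-value against `pROC::roc.test`.

## Worked example

```{r example}
spec <- phantom_spec(low_shear_fraction = 0.3, oscillatory_fraction = 0.1,
                     seed = 7)
mesh <- make_phantom_mesh(spec)
series <- make_wss_field(mesh, spec)
d <- suppressWarnings(compute_descriptors(mesh, series, id = "phantom_1"))
round_descriptors(d)[, c("id", "WSS_mean", "OSI_max", "CHP_mean", "LSA")]

cohort <- simulate_matched_cohort(cohort_spec(n_pairs = 91, seed = 1))
report <- run_study(cohort, seed = 1)
report
```

## Problem sizes and limitations

The test-suite simulations use 91 pairs (the motivating cohort size) for
calibration checks, 2,000 pairs for estimator-bias checks, 200–1,000
replicates for Monte-Carlo assertions, and meshes of up to ~10,000 faces;
these sizes give Monte-Carlo error well inside the asserted tolerances
while keeping a full run to a couple of minutes on one core.

Known limitations:

* 1:1 matching only — no m:n sets, no Firth correction under separation
  (separation is detected and reported instead).
* The score has no calibration component (no intercept/baseline risk);
  it rank-orders and dichotomises risk only.
* Cohort-level published AUCs cannot be reproduced without the original
  patient fields; the package validates internal arithmetic and
  statistical properties on synthetic data instead.
* Dome/parent delineation is an explicit input label; the package does
  not segment geometry.
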