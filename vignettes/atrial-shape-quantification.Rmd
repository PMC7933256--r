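---
title: "Quantifying left-atrial shape: best-fit-sphere deviation mapping, asymmetry and regional deformation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying left-atrial shape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atriamorph)
```

## The measurement problem

Atrial fibrillation drives structural remodelling of the left atrium (LA):
dilation, loss of the chamber's roughly spherical resting shape, and
regional wall deformation that accompanies fibrotic (low-voltage)
substrate. Given a segmented LA surface from cardiac CT — a closed
triangulated mesh in millimetres, with the pulmonary veins (PVs) and the LA
appendage (LAA) either trimmed or left as protrusions — `atriamorph`
computes a compact set of shape metrics per patient and the statistics to
relate them to per-segment low-voltage labels across a cohort.

## The model and its assumptions

**Volumetry and asymmetry.** The chamber volume LAV follows from the
divergence theorem over the closed surface (signed tetrahedra; mm³
converted to mL in exactly one place). A cutting plane oriented parallel to
the posterior wall and placed between the PV ostia and the LAA splits LAV
into an anterior part LA-A and a posterior part LA-P; the asymmetry index
is ASI = LA-A/LAV. The posterior-wall orientation is estimated as the
total-least-squares plane of the posterior segment's vertices rather than
drawn by an operator, which removes one manual degree of freedom; the plane
anchor is the PV-centroid/LAA midpoint (interpolation scalar `planeOffset`,
default 0.5, exposed for sensitivity analysis). Clipping fans each clipped
triangle against an apex placed *on* the cutting plane, so the
cross-section cap contributes zero volume regardless of section geometry
and LA-A + LA-P = LAV holds to machine precision by construction.

**Sphericity.** A patient-specific best-fit sphere is registered to the
surface by iterative closest point (ICP): correspondence associates each
vertex with its radial foot point on the current sphere, and the
closed-form similarity update re-estimates centre and radius (rotation is a
gauge freedom for a sphere). The fixed point of this alternation is the
geometric least-squares sphere — the minimiser of the area-weighted sum of
squared radial residuals. Each vertex then carries a signed deviation
`d_i = |v_i − c| − AR` measured along the ray from the sphere centre,
positive outward (convex), negative inward (concave). S is the
area-weighted mean of |d_i| over included vertices and LAS = 1 − S/AR
(stored as a fraction; reports print percent).

Three modelling choices deserve emphasis:

- *S uses the absolute deviation.* A signed mean would vanish near the
  least-squares optimum by construction, forcing LAS toward 1 for every
  shape; the mean magnitude is the natural scale of departure from
  sphericity. Area weighting makes S insensitive to mesh resolution; an
  unweighted option is retained (`areaWeighted = FALSE`).
- *Exclusion is outward-only by default.* Structures that violate the
  chamber-shape model — PV trunks and the LAA — protrude outward, so
  vertices with `d_i > 10 mm` are masked (`exclusionMode = "absolute"` is
  available). Excluded vertices carry no weight in S or any segmental
  statistic. The sphere is fitted once on all vertices and the mask applied
  afterwards; an optional refit-on-included loop (`refitPasses`, up to 5)
  exists but is off by default since iterating fit and exclusion is an
  extension of the method, not part of it.
- *LAS = 1 − S/AR, not 1 − AR/S.* The latter form appears in some summary
  text but produces values far outside the reported percent range; only
  the former reproduces the published magnitudes (e.g. mean radius 32 mm
  with mean deviation 6 mm gives LAS = 0.8125, consistent with a cohort
  mean of 82%).

**Two sphere estimators, deliberately.** `fitSphereAlgebraic()` solves the
linear system obtained by expanding |p − c|² = r² and serves as an
independent oracle for the ICP route. The two estimators coincide exactly
on zero-residual data and agree to first order otherwise; their difference
is second order in S/AR (about 0.06% of AR on realistic deformed atria, the
radius of the algebraic fit being inflated by var(d)/2AR). Equivalence
tests therefore use randomized exact-sphere meshes, where both must agree
to 1e−6·AR, and a separate characterisation test bounds the second-order
difference on deformed surfaces at 3·(S/AR)²·AR.

**Patient frame and segments.** The anatomical frame is anchored at the
fitted-sphere centre: the superior axis points from an inferior reference
landmark (e.g. mitral annulus centre) to the centre; the posterior axis is
the PV-ostia-centroid direction orthogonalised against it; the lateral axis
completes a right-handed frame, sign-checked against the LAA (which sits
anterolateral — mirrored anatomies flip the lateral axis with a warning).
Azimuth is measured from the posterior axis, positive toward the septal
(anti-lateral) side. The six segments are plain angular bands
(`defaultSegmentBands()`): polar angle < 45° is roof; 45–105° splits into
posterior (|φ| < 60°), septum (φ ≥ 60°) and lateral (φ ≤ −60°); ≥ 105°
splits into inferior posterior (|φ| < 90°), inferior septum (φ ≥ 90°) and
lateral (φ ≤ −90°). No authoritative published boundary definition exists,
so the bands are configuration values in one documented table, not
constants — segment remapping needs no code change. D per segment is the
*signed* area-weighted mean of `d_i` (inward remodelling must show as
negative values, as reported for roof/posterior/septum).

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `exclusionThreshold` | 10 | mm | deviation beyond which vertices are masked |
| `exclusionMode` | outward | — | mask `d > t` (outward) or `|d| > t` |
| `areaWeighted` | TRUE | — | area weights in S and D |
| `refitPasses` | 0 | — | optional refit-on-included iterations (≤ 5) |
| `sphereTolerance` | 1e−9 | relative | ICP stop: centre shift and radius change < tol·AR |
| `sphereMaxIterations` | 100 | — | ICP cap; non-convergence warns, returns last iterate |
| `bands` | see above | degrees | segment boundaries |
| `planeOffset` | 0.5 | — | cutting-plane anchor between PV centroid (0) and LAA (1) |
| `welch`, `bhCorrect`, `alpha` | FALSE, FALSE, 0.05 | — | statistics flags |

The ICP stopping rule is relative to the radius, which makes the fit
exactly equivariant under uniform scaling — LAS and ASI are then similarity
invariants to 1e−9, which the suite asserts.

## Numerical choices and degenerate inputs

- Vertices closer than 1e−9 mm merge before the edge-manifold check (STL
  duplicates vertices per facet); zero-area faces are dropped; a closed
  mesh with negative signed volume has its winding flipped once. Open
  meshes are accepted with a warning but refuse volume operations.
- Plane fitting uses the SVD of centred points; collinear inputs (rank
  < 2 within 1e−9 relative) raise an error rather than returning an
  arbitrary normal.
- Sphere fits require ≥ 4 non-coplanar points (relative SVD tolerance
  1e−9). A vertex coinciding with the current sphere centre aborts the ICP
  (undefined correspondence direction).
- An all-excluded deviation field, an empty posterior segment, a degenerate
  patient frame (inferior reference at the sphere centre, PV direction
  parallel to the superior axis) are hard errors carrying the stage and
  patient id; a segment with zero included area yields `D = NA` with a
  warning instead, so one empty segment does not void a patient.
- Paired t on identically equal samples returns t = 0, p = 1; a constant
  nonzero paired difference is reported as degenerate. Wilcoxon drops zero
  differences and errors when none remain.

## Statistics

`spearmanTest()` uses average ranks and, for n ≤ 10, an exact two-tailed
permutation p-value by full enumeration of all n! permutations (valid
under ties, where the classical S-statistic tables are not); larger n uses
the t approximation. `wilcoxonTest()` enumerates all group assignments
(rank sum) or sign patterns (signed rank) for combined n ≤ 12 and falls
back to the normal approximation with tie and continuity corrections.
`pearsonTest()`, `tTest2()` and `chiSquareTest()` wrap the base R tests
(pooled-variance Student by default, mirroring common clinical practice,
with Welch by flag; Pearson χ² without continuity correction, Yates by
flag). No multiplicity correction is applied by default — the analysis this
package mirrors reported raw p-values — but Benjamini–Hochberg adjusted
columns are available (`bhCorrect = TRUE`). Kolmogorov–Smirnov normality
screening is deliberately not used to auto-switch tests; test choice is
explicit configuration.

`lvaAssociation()` emits labelled families: the headline *deformation
burden* association (Spearman of each patient's mean |D| against the
low-voltage segment count — the natural statistic for "more deformation,
more low-voltage extent"), per-metric count correlations, the pairwise
Spearman grid among D/LAV/ASI/LAS, and the extended-low-voltage (6
segments) versus limited (1–3 segments) group contrast with means ± SD;
counts of 4–5 belong to neither group. Correlation- and contrast-style
results are reported side by side because both views are in use for these
data; non-computable entries (constant vectors, groups under 2 patients)
are flagged, never raised.

## What the synthetic generator emulates — and what it does not

`generateLaMesh()` starts from a geodesic icosphere (subdivision 3, 642
vertices, ~2.5° resolution at 32 mm) and displaces vertices radially by a
six-component deformation field: per-segment amplitudes `a_s` (mm) blended
through a partition of unity of cosine-squared kernels centred on the
segments (angular falloff 65°). The partition-of-unity design has two
consequences that matter for validation: equal amplitudes reduce exactly to
uniform inflation (which the best-fit sphere absorbs into AR, leaving S and
d untouched — an asserted invariant), and each segment deforms as a whole
wall, so its amplitude remains identifiable after the fit. Small isolated
bumps would not be: a cap covering a fraction q of a segment of fractional
area A shifts the fitted sphere by enough to cancel its own segmental mean
when A approaches 1/4 — an instructive property of best-fit-sphere metrics
discovered while designing the generator. Optional PV/LAA stubs (15 mm
high, 12° caps) exercise the 10 mm exclusion rule, and isotropic radial
noise (0.3 mm, the scale of segmentation jitter) exercises robustness.

**Fit-adjusted ground truth.** Because the fit absorbs the area-weighted
mean displacement into AR and the first direction moment into the centre,
raw amplitudes are not what a best-fit-sphere analysis can recover. The
generator therefore records, for the noiseless stub-free surface, the
segmental means of the residual field about an *independently* fitted
geometric least-squares sphere (quasi-Newton minimisation via
`stats::optim`, a different algorithm from the package's ICP), labelled in
the patient frame implied by the true landmarks and that oracle sphere.
Recovery tests demand agreement within max(0.3 mm, 15%) per segment — met
in 100 of 100 randomized atria with amplitudes in ±4 mm at default
resolution and noise.

**Cohort sampling.** `cohortDistribution()` draws per-patient radii
N(32, 4²) mm and segment amplitudes with means (−0.9, −0.6, −1.6, +3.2,
+0.8, +2.8) mm and SDs (3, 2, 2, 3, 2, 3) mm — the reported cohort wall
deviations — independently across segments by default (`amplitudeCor`
adds a shared remodelling factor for sensitivity studies). Per-segment
low-voltage labels follow Bernoulli(plogis(β₀ + β₁·|a_s|)) with defaults
β₀ = −5, β₁ = 1.2 per mm, chosen by a design-stage power analysis so that
the deformation-burden association attains ≥ 95% sign-and-significance
recovery over 200 cohorts of n = 100, while a null model (β₁ = 0 with
β₀ = 0, fair-coin labels) keeps the type-I error of the same test at the
nominal 5% (measured 4.4% over 2000 null cohorts, within the binomial 99%
band). `generateCohortTable()` provides a metric-level sampler (the
linearised response of the deviation analysis, no meshes) for such
calibration studies: per-patient child seeds split from the master seed by
a counter scheme, so enlarging a cohort never perturbs existing patients.

**Limits of the emulation.** The generator produces segment-structured
deformation on a sphere. It does not emulate the global non-spherical
anatomy of a real LA (ellipsoidal elongation, PV antrum funnels, appendage
geometry): real chambers carry S around 6 mm and LAS near 82%, while
default synthetic atria, whose deformation is largely absorbed or
segmental, sit near S ≈ 1.3 mm and LAS ≈ 96%. Passing recovery tests
therefore demonstrates correctness of the measurement chain — not that
synthetic cohorts match clinical metric distributions. Volumes, ASI and
the association structure, by contrast, land close to reported cohort
values (e.g. synthetic cohort mean ASI ≈ 66% versus 67% reported).

## Problem sizes used in validation

The suite and the acceptance study use icosphere subdivisions 2–4
(162–2562 vertices), cohorts of 24 patients at mesh level (the study's
size) and 100 patients at metric level, 100 randomized recovery atria, 50
randomized sphere meshes for oracle equivalence, 1000 null and 200 effect
cohorts for calibration and power. These sizes were chosen so each study
estimates its quantity stably while the whole suite remains quick to run
routinely.

## Known limitations

- The six-segment boundaries are a reasonable published-figure-faithful
  convention, not an anatomically registered atlas; segment-level numeric
  agreement with any specific clinical software is not expected.
- LAV is the volume of the supplied closed mesh, nothing more: PV stumps
  left in the segmentation inflate it (the 10 mm rule protects surface
  metrics, not volumetry).
- The ICP fit targets the geometric least-squares sphere; codes minimising
  the algebraic residual will report AR larger by ≈ var(d)/2AR.
- Landmarks are inputs; automatic PV/LAA detection is out of scope.
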