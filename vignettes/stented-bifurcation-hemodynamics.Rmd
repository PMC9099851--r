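---
title: "Shear-rate hemodynamics of stented left-main bifurcations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shear-rate hemodynamics of stented left-main bifurcations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(stentflow)
```

## The question the pipeline answers

After a single stent is implanted across the left-main bifurcation, the
side-branch (SB) ostium can be left "jailed" by stent struts (KIO, *keep
it open*), the jailing struts can be cleared by kissing-balloon
inflation (KBI), or a bifurcation-dedicated stent (BD-DES) with only two
ostial connector struts can be used. Struts suspended in the ostial
flow accelerate blood locally; shear rates above the physiological
arterial range (100–1000 s⁻¹) are an accepted surrogate for
platelet-mediated thrombogenicity. This package rebuilds, at desk
scale, the in-vitro comparison of those three strategies: a parametric
2D longitudinal model of the bifurcation lumen, strut obstacles per
strategy, steady Newtonian flow, the two scalar endpoints — high-shear
area $A_{>1000}$ and maximum shear rate $\dot\gamma_{max}$ — plus the
OCT-derived metrics (strut apposition, elliptical index, thrombus area)
and the nonparametric statistics that compare the groups.

No imaging data are distributed: a synthetic-cohort generator, see
below, reproduces the statistical structure of the published cohort so
every stage is testable.

## Geometry and strut layouts

The lumen is a Y in the sagittal plane, carina at the origin: a 5.5 mm
proximal channel entering from the left, a 3.5 mm distal main branch
(MB) and a 3.5 mm SB leaving at 135° to the proximal axis each (90°
between them). Channel widths are exact by construction (walls are
parallel offsets of the segment axes). The SB opens from the lower
wall; the *ostium segment* is the SB cross-section anchored at the
proximal ostial corner, length equal to the SB diameter. Default
segment lengths are 15 mm, enough for the 24–25 mm device footprint
(9 mm of proximal coverage, the junction, and the distal MB rings).

Struts are square cross-sections of side equal to the strut thickness
(81 µm conventional platform, 70 µm dedicated platform), placed at a
1 mm ring pitch along the stented walls and across the ostium segment:

* **well-apposed (WA)** struts sit flush on the wall (gap 0) and are
  merged into the wall outline as square bumps. A strictly positive
  sub-thickness standoff would create micrometre slivers between strut
  and wall that no practical mesh resolves, which is why the mesher
  treats a near-touching strut as an error rather than a feature;
* **malapposed (MA)** struts stand off the wall by a gap drawn
  uniformly from (1, 2] strut thicknesses — the classification rule is
  *gap strictly greater than one thickness*, and the upper bound keeps
  the obstacle well inside the lumen;
* **floating** struts sit on the ostium segment; they are the struts
  that jail the SB.

The BD-DES carries exactly two dedicated ostial connector struts spaced
2.0–2.4 mm apart. With the published mix (floating median 0%) both
attach well-apposed at the ends of the ostial zone; if a configured mix
allocates one or two floating struts, the connectors are the ones that
cross the ostium (more than two floating struts is infeasible for this
platform and is rejected).

Requested apposition mixes are realized exactly up to largest-remainder
rounding, and the layout is a pure function of (geometry, strategy,
spec, mix, seed).

## Meshing

The fluid domain (lumen minus MA/floating strut squares, WA bumps
included in the outline) is discretized with unstructured triangles:
graded hexagonal point lattices, Bowyer–Watson Delaunay triangulation,
midpoint insertion until every boundary subedge is recovered,
flood-fill classification against the boundary loops, and
inversion-guarded Laplacian smoothing. Triangles realize the
"quadrilateral dominant" reference meshes' contract — boundary-refined
elements adequate for shear recovery — without the fragility of
unstructured quad generation.

Sizing: no element edge exceeds `h_max` (default 0.1 mm, about 100,000
elements on the default strutted model); elements adjacent to walls and
strut surfaces are refined by `near_wall_factor` (default 0.25), and
strut surfaces are additionally capped at half a strut thickness so the
81 µm obstacles are always resolved by at least two segments per face.
That surface size is held over a plateau of three strut thicknesses
around each strut before grading back to `h_max`. Because the plateau,
not `h_max`, controls the resolution wherever shear can exceed the
threshold — the high-shear region lives within a few strut widths of
the strut surfaces — the thresholded area is feature-resolved and
nearly mesh-independent across the refinement chain, which is what the
convergence study checks. Element areas sum
to the polygon area to 1 part in 10⁶ (boundary samples lie exactly on
the straight edges), every element is positively oriented, and the mesh
is a pure function of its inputs.

## Flow model and solver

Blood is Newtonian and incompressible (ρ = 1060 kg/m³,
µ = 0.0035 Pa·s). The inlet carries a mean velocity of 0.14 m/s — the
pump's 200 mL/min through the 5.5 mm circular proximal lumen,
$U = Q/(\pi (D/2)^2)$ — as a fully developed parabolic profile by
default (the reference setup states only the mean; a plug option is
kept for sensitivity runs, and with a parabolic inlet no development
length is needed). Walls and strut surfaces are rigid no-slip; both
outlets carry the natural do-nothing condition, the finite-element
equivalent of zero outlet pressure. The Reynolds number at the defaults
is ≈ 233, safely laminar; inputs outside the laminar regime are
rejected.

The discretization is stabilized equal-order P1–P1: Galerkin terms plus
PSPG pressure stabilization and SUPG streamline upwinding with the
standard elementwise τ. The nonlinear convection is resolved by Picard
iterations followed by Newton's method with adaptive damping; the
linearized saddle systems are solved by sparse LU. Near the solution
the solver switches to *chord* (modified-Newton) iterations that reuse
the last factorization while the contraction rate stays below 0.35 —
on warm-started solves this reduces the number of factorizations, the
dominant cost, from about seven to two. Convergence means the relative
nonlinear residual falls below `tol` (default 10⁻⁶; the cohort profile
uses 10⁻⁵, see below); non-convergence raises a classed error carrying
the residual history and is never silently returned.

Two structural properties are worth stating because the tests lean on
them. First, summing the discrete continuity rows against the constant
pressure test function cancels the PSPG terms exactly, so the boundary
flux of the converged P1 field balances to linear-solver roundoff —
the net-mass check (< 10⁻⁸ of the inlet flux) holds by construction at
*every* direct solve, independent of the nonlinear tolerance. Second,
the element-wise shear rate $\dot\gamma = \sqrt{2\,D\!:\!D}$ is exact
for fields with constant gradient, which gives sharp oracles (rigid
motion → 0, linear shear $u = ky$ → exactly $k$) next to the asymptotic
plane-Poiseuille ones (centre-line $1.5U$, wall shear $6U/h$).

## Shear endpoints

`compute_shear_metrics()` thresholds the element shear rates at
$\dot\gamma_c$ = 1000 s⁻¹ and sums element areas by centroid membership
in the region of interest. The reference analysis never states its
integration region, so two are always reported side by side: a circular
window of one SB diameter centered on the ostium midpoint (where the
strut-induced disturbance concentrates) and the whole domain.
$\dot\gamma_{max}$ is taken over element values, not nodal
extrapolation, for mesh robustness; note that the sharp carina apex and
strut corners are genuine corner singularities, so its absolute value
grows slowly under refinement — orderings between strategies are
meaningful, absolute maxima are mesh-bound. The strut-free model's wall
shear sits at 150–190 s⁻¹ per segment ($6U/h$ with the split fluxes),
far below threshold: essentially the whole high-shear area of a
stented model is strut-induced.

## OCT metrics

The synthetic pullback mimics the acquisition protocol: 540 frames at
0.1 mm (10 mm/s at 100 frames/s over 54 mm), analysis at every tenth
frame (1 mm). Per frame the generator provides lumen diameters, a
thrombus area and the strut records. The measurements are:

* **apposition classification** — floating iff in the ostium, MA iff
  the wall gap strictly exceeds the strut thickness, WA otherwise;
  percentages over all struts in the bifurcation-ostium region. On
  synthetic pullbacks this recovers the generator's planted labels
  exactly (round-trip property);
* **elliptical index** — the per-frame $D_{max}/D_{min}$ averaged over
  analyzed proximal frames. "Standardized for the length of the stent"
  is ambiguous between this reading and the global
  $\max D_{max}/\min D_{min}$; both are consistent with the published
  table at printed precision, so the per-frame mean is the default and
  the global variant stays available via `method = "global"`;
* **thrombus area** — mean of the three largest per-frame areas among
  bifurcation-region frames (± one SB diameter of the ostium center);
* **proximal summary** — min/mean/max of the frame mean-diameters and
  the mean lumen area.

## Synthetic cohort

The generator's defaults are the study conditions: five samples per
strategy, per-group apposition mixes equal to the normalized published
medians (the printed WA/MA/floating medians sum to 99.4–100.4%, so they
are renormalized), elliptical-index targets 1.05–1.06, proximal
diameters ≈ 5.5 mm, coating-damage category medians per group, and the
published thrombus median/IQR triples. Dispersions the publication
cannot constrain (it prints only medians and IQRs of n = 5) are chosen
once at what a bench study of this kind plausibly shows: a Dirichlet
concentration of 150 for per-sample mixes (≈ ±3 percentage points on
the floating share), 0.012 on the per-frame diameter ratio, 0.06 mm on
frame diameters, and a negative-binomial size of 8 for damage counts.
`noise = 0` collapses every draw to the group central values, which the
tests use as an exactness oracle.

Thrombus needs one modeling decision. The published per-group triples
(e.g. 0.52 (0.17–0.65) mm²) describe the per-sample top-3-frame mean,
and they are strongly left-skewed: median − Q1 far exceeds
Q3 − median. A zero-inflated lognormal — the natural first choice —
can only reproduce such triples with its zero mass pushed against the
Q1 identifiability boundary (25%), where sampled quartiles are
unstable; a zero-inflated Weibull reaches further but hits the same
wall on the most skewed triple. The default is therefore a
quantile-parameterized distribution: the piecewise-linear quantile
function through (Q1, median, Q3) with short linear tails, in the
spirit of metalog-type quantile-matched models. Its quantiles are
exact by construction, the density near each quartile is healthy, and
a zero median automatically yields an atom of at least one half at
zero. The two parametric families remain selectable
(`family = "zi-weibull"`, `"zi-lognormal"`), each fitted by exact
three-parameter quantile inversion where the triple is reachable.

The sample burden drawn from that model is distributed over the
bifurcation-region frames with a peaked spatial profile rescaled so the
top-3-frame mean equals the burden exactly — the downstream statistic
is calibrated, not merely approximated. Thrombus is generated as
*data*, not mechanistically from shear; an optional hook
(`thrombus_floating_hook`) couples a sample's burden to its
floating-strut share for end-to-end runs, off by default.

What the generator does *not* emulate: OCT speckle or image content,
strut detection errors, lumen segmentation noise, pulsatile flow, or
any biology of thrombus growth. Tests passing on this cohort show that
the pipeline's measurements and statistics behave correctly under the
published summary structure — not that the physical study would
replicate.

## Statistics

Summaries are median (Q1–Q3) with linear-interpolation (type 7)
quantiles. The omnibus test is the tie-corrected Kruskal–Wallis H
(delegated to `stats::kruskal.test`) with the χ² p-value on k − 1
degrees of freedom; for total n ≤ 12 an exact permutation p is also
computed by full enumeration of group assignments. Dunn's post-hoc
pairwise test (pooled-rank means, tie-corrected variance, two-sided) is
gated on a significant omnibus test, mirroring the study protocol, and
refuses to run otherwise; p-values are reported unadjusted and
Bonferroni-adjusted, because the original analysis tool's adjustment is
not stated. All tests are two-sided.

## Numerical choices and profiles

* default mesh: `h_max` 0.1 mm, `near_wall_factor` 0.25 (full runs);
* desk/cohort profile used by `run_config()`: `h_max` 0.15 mm,
  `near_wall_factor` 0.5 (strut surfaces still capped at half a
  thickness), solver tolerance 10⁻⁵ with warm starts from the memoized
  strut-free reference solution, and a trimmed domain — proximal
  segment 11.5 mm (the parabolic inlet needs no development length) and
  SB 10 mm (it carries no device; the ostial window keeps > 4 mm of
  clearance from the outlet). With both outlets at zero pressure the
  unequal branch lengths shift the flux split a few percent toward the
  shorter SB; since every strategy is run in the same domain, the
  between-group comparison is unaffected;
* convergence-study chain: 0.30 / 0.21 / 0.15 mm (ratio √2) on the
  jailed-ostium example, monitoring the mid-proximal centre-line
  velocity and the ostial high-shear area;
* nonlinear solver: Picard → Newton with chord reuse (threshold 0.35),
  adaptive damping halving on residual growth;
* degenerate inputs: zero/negative dimensions, non-Y angles, mixes not
  summing to one, overfull ostia, sub-thickness strut-wall slivers and
  turbulent-regime velocities are all rejected with specific errors.

Problem sizes in the test-suite and analysis scripts (mesh levels,
cohort sizes, replicate counts) are the package's desk-scale defaults:
large enough to pin each property at its stated tolerance, small enough
that the whole study re-runs on one CPU in minutes.

## Known limitations

The model is 2D: strut cross-sections in the sagittal cut stand in for
the full cage, so metal-to-artery ratios and out-of-plane flow are not
represented — orderings between strategies transfer, absolute areas do
not. Flow is steady (as in the reference experiment), Newtonian, and
rigid-walled. Maximum shear rate sits on corner singularities and is
reported as an element-wise, mesh-bound quantity. The published
per-group dispersions are unknowable from n = 5 medians/IQRs, so all
cohort dispersions beyond the calibrated quantiles are documented
choices, not estimates.
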