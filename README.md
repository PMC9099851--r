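# stentflow

Desk-scale in-silico comparison of left-main bifurcation stenting
strategies. After provisional stenting, the side-branch (SB) ostium is
either left jailed by struts ("keep it open", KIO), cleared by kissing
balloon inflation (KBI), or treated with a bifurcation-dedicated stent
(BD-DES) whose ostial zone carries only two connector struts. Struts
suspended in the ostial flow accelerate blood locally; shear rates above
the physiological arterial range (100–1000 s⁻¹) are a standard surrogate
for platelet activation and acute stent thrombogenicity. This package
rebuilds that comparison end to end for researchers in computational
hemodynamics and interventional-cardiology device testing.

The pipeline:

1. **Geometry** — parametric 2D longitudinal lumen of the Y-shaped
   bifurcation (proximal 5.5 mm, distal MB 3.5 mm, SB 3.5 mm, 90° between
   branches, 135° to the proximal axis), with square strut cross-sections
   (81 µm conventional, 70 µm dedicated platform) placed per strategy:
   well-apposed (flush on the wall), malapposed (wall gap > one strut
   thickness) or floating across the SB ostium.
2. **Meshing** — boundary-refined unstructured triangulation
   (Bowyer–Watson with constrained-edge recovery); element edges ≤
   `h_max`, strut surfaces resolved at half a strut thickness.
3. **Flow** — steady incompressible Navier–Stokes (ρ = 1060 kg/m³,
   µ = 0.0035 Pa·s, mean inlet velocity 0.14 m/s ≡ 200 mL/min, no-slip
   walls, zero-pressure outlets) with a stabilized P1–P1 finite-element
   method and a Picard→Newton solver.
4. **Endpoints** — shear-rate magnitude γ̇ = √(2 D:D); high-shear area
   A(γ̇ > 1000 s⁻¹) and maximum shear rate, in an ostium-centered window
   and globally.
5. **OCT metrics** — strut apposition percentages, elliptical index
   (mean per-frame Dmax/Dmin of the proximal segment), top-3-frame
   thrombus area, proximal lumen summary, on synthetic pullbacks.
6. **Statistics** — median (IQR), tie-corrected Kruskal–Wallis (exact
   permutation p for n ≤ 12), Dunn's post-hoc gated on omnibus
   significance.

A synthetic-cohort generator calibrated to the published group
medians/IQRs stands in for the physical samples, so the whole study runs
from a seed with no external data.

## Worked example

```r
library(stentflow)

geom <- build_bifurcation()                       # default Y geometry
lay  <- place_struts(geom, "KIO",                 # jailed ostium
                     mix = c(0.79, 0.05, 0.16), seed = 1)
mesh <- generate_mesh(geom, lay, mesh_config(h_max = 0.15,
                                             near_wall_factor = 0.5))
flow <- solve_steady_flow(mesh, opts = solver_opts(picard_iters = 2))
shear <- compute_shear_rate_field(flow, mesh)
compute_shear_metrics(shear, roi = ostium_roi(geom))
```

On this configuration the run prints (numbers from an actual run):

```
mesh: 49,607 elements;  solve: converged, relative residual 5.3e-08
$a_high_mm2 [1] 0.1695   $shear_max [1] 4291.5   $gamma_c [1] 1000
```

i.e. 0.17 mm² of the ostial window exceeds 1000 s⁻¹, concentrated
around the six floating struts; the same pipeline on a KBI layout
(floating median 3.8%) gives ≈ 0.04–0.05 mm², and on BD-DES ≈ 0.005 mm²
— the strut-free baseline is ≈ 0.001 mm² with wall shear at 150–190 s⁻¹.
Maximum shear rate sits on strut corners and is mesh-bound; orderings,
not absolute maxima, are the meaningful output.

The full study — cohort generation, per-sample CFD, OCT metrics and
group statistics — is a single call:

```r
report <- run_study(run_config(cohort = cohort_config(n_per_group = 5,
                                                      seed = 1)))
render_tables(report)    # median (Q1–Q3) per group + Kruskal-Wallis p
```

The numbered scripts under `analysis/` run the same stages as a
narrative workflow (`01_build_cohort.R` → `04_figures.R`), writing
tables and figures under `results/`.

## Layout

```
R/                  geometry, struts, meshing, solver, metrics, OCT,
                    statistics, cohort generator, study orchestration, IO
src/                meshing and finite-element assembly kernels (Rcpp)
analysis/           numbered narrative drivers (01–04)
scripts/            acceptance.R
tests/testthat/     unit, property and acceptance suites
vignettes/          methods vignette (models, assumptions, limitations)
```
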