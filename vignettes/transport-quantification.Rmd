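---
title: "Quantifying brain solute transport from DCE-MRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying brain solute transport from DCE-MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braintransport)
```

## The problem

Intrathecally infused contrast agents spread through the rodent brain
faster than hindered diffusion allows, preferentially along perivascular
spaces. Whether the excess is convection, dispersion or something else is
contested; what can be measured robustly at whole-brain scale is a lumped
transport coefficient. This package estimates one effective diffusivity per
anatomical subdomain from DCE-MRI concentration dynamics and converts it
into quantities — Péclet numbers, mean velocities, enhancement ratios —
that are directly comparable to the known diffusive rate of the tracer.

The deliberate simplification is that everything is forced into a
diffusion-form model,

$$\frac{\partial c}{\partial t} = \nabla\cdot(D_\mathrm{eff}\nabla c) + s,$$

with piecewise-constant $D_\mathrm{eff}$ per subdomain, a point source
rectangular in time for the infusion, and a no-flux boundary (the skull is
essentially impenetrable over the ~80 min experiment; efflux routes are
neglected, which is why frames after 52 min are excluded from fitting). A
convective model would need a velocity direction field that the data cannot
supply at 100 µm resolution. The price of the lumped model is that a
convective front is represented by a diffusive profile; the benefit is a
well-posed inverse problem with three parameters.

### Assumptions

* The tracer is biologically inert: no uptake or adsorption sink.
* Porosity is uniform (φ = 0.20), so the superficial concentration
  $\bar c = c\,\phi$ can be used throughout without conversion.
* Arteries and ventricle walls exchange negligibly with the tissue; their
  diffusivity is tied to brain tissue by a blocked fraction of $10^{-8}$.
* Loss through the boundary is negligible over the fitted time window,
  verified by the total-amount diagnostic (`total_amount()` must rise
  during infusion and stay constant after).

## Pipeline parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| TR | 16 | ms | spoiled-gradient-echo repetition time |
| flip angles | 3°, 15° | — | two-point variable-flip-angle T1 mapping; 15° is the imaging angle and supplies S0 |
| r1 | 3.2e-3 | L/(mmol·ms) | gadoteridol relaxivity |
| φ (porosity) | 0.20 | — | adult brain extracellular fraction |
| artery T1 max | 1200 | ms | blood T1 is short; subject range 1000–1400 |
| ventricle T1 min | 3000 | ms | CSF T1 is long |
| PAS threshold | 0.15 mM at t = 20 min | — | high early concentration marks periarterial routes |
| PAS reach | 7 (surface) / 3 (branching) | voxels | Chebyshev distance from the artery masks |
| infusion | 0.034 µmol/min, 0–20 min | — | 0.5 µl/min of 68 mM tracer; total 0.68 µmol |
| dt | 0.5 | min | implicit-Euler step |
| fit window | t ≤ 52 | min | limits sensitivity to the no-efflux assumption |
| exclusion radius | 0.5 | mm | injection-site T2/T2* interference |
| D (free) | 0.016 | mm²/min | free diffusivity of the tracer |
| λ (tortuosity) | 1.73 | — | literature spans 1.6–1.85; all selectable |
| characteristic lengths | 12 / 5 / 0.5 | mm | caudal–rostral extent (PAS_Surf), ventral–dorsal (PAS_Branch), inter-vessel spacing (BT) |

A note on $D_\mathrm{app}$: the exact value $0.016/1.73^2 = 0.005346$ is
conventionally reported to one significant figure (0.005 mm²/min), and the
downstream arithmetic (Péclet numbers, the small-PVS decomposition) is
conventionally done with the rounded value. `transport_constants()`
therefore uses the rounded value by default (`round_d_app = TRUE`);
`apparent_diffusivity()` always returns both.

## What the phantom emulates — and what it does not

`phantom_spec()` describes a stated world: an ellipsoidal brain (default
semi-axes 2.9 × 2.9 × 2.1 mm in a 64 × 64 × 48 grid of 0.1 mm voxels), one
surface artery hugging the ventral midline, two branching arteries rising
dorsally, two lateral ventricles, per-tissue baseline T1 (artery 800,
tissue 1800, PAS 1900, ventricle 4000 ms — all inside the physiological
500–4500 ms band and positioned so threshold segmentation is recoverable by
construction), the 20-min infusion near the caudal ventral surface,
Gaussian noise at 2% of the mean baseline signal (Rician optional), and
multiplicative T2/T2\* dropout (factor 0.1) in a 2-voxel surface shell and
wherever concentration exceeds 50 mM. PAS shells default to the full
segmentation reach (Chebyshev ≤ 7 / ≤ 3 voxels), which makes the phantom's
own labels the fixed point of the segmentation rules on clean data.

Choices where no value was externally given, made once: noise level (2% is
typical magnitude-MRI SNR at this resolution), dropout factor 0.1 (strong
but not total obliteration), surface shell 2 voxels (middle of the reported
1–3 range), injection dropout 50 mM (signal suppression at very high local
concentration).

What a green phantom test does *not* establish: anatomical realism (no
Circle-of-Willis topology, no subarachnoid space, no skull), realistic
absolute concentrations (the desk-scale brain is ~⅙ the real volume but
receives the full 0.68 µmol dose, so concentrations run ~5× high; every
fitted or thresholded quantity is unaffected, but absolute values should
not be read as physiological), or model error (truth is generated by the
same diffusion-form model that the fit assumes, on the same discretization
— a deliberate inverse-crime setup that isolates solver/fitting defects;
real-data misfit from convective fronts is outside what the phantom can
show). Relatedly, in a full-size brain the PAS shells occupy a fraction of
a percent of the volume; at desk scale they occupy ~20% of in-brain voxels,
so "BT dominates the volume" holds only as a plurality/majority statement
here.

## Numerical choices

* **Discretization.** Cell-centered finite volumes on a structured
  hexahedral grid (integer coarsening of the voxel lattice), harmonic-mean
  face diffusivities, implicit Euler in time. Row sums of the discrete
  operator vanish, so after the source switches off the total amount is
  conserved to rounding — the package's no-flux diagnostic is exact by
  construction, and observed drift in tests is ≤ 1e-6 relative. The
  reference analysis used quadratic Lagrange finite elements on a
  tetrahedral mesh; at desk scale, grid refinement is cheaper than element
  order, so `solver_config(order = 2)` is reserved (and currently
  rejected with an informative error).
* **Near-source accuracy.** A point load on one cell makes the solution
  inaccurate within a few cells of the source: against the closed-form
  continuous-release solution $q/(4\pi D r)\,\mathrm{erfc}(r/2\sqrt{Dt})$,
  the error is below 5% beyond three cell *diameters* (diam of a
  hexahedron = $\sqrt3\,h$) and decreases under refinement, but can reach
  ~10% at two to three cell *widths*. The fitting objective excludes the
  injection neighbourhood anyway. `solver_config(source_sigma = …)`
  optionally spreads the load over a small Gaussian ball for
  mesh-independence studies.
* **Time stepping.** dt = 0.5 min; step boundaries are snapped to the
  source start/stop and to output frames, so the injected total is exact
  regardless of dt.
* **IDW interpolation.** Voxel data are moved to mesh nodes with
  truncated-Gaussian inverse-distance weights (σ = 1 voxel, radius 3σ).
  Weights are positive and normalized, giving a max principle; it acts as
  mild smoothing of the data, mirrored in the reference workflow.
* **Ties and determinism.** Grid-search ties break to the
  lexicographically smallest triplet; PAS voxels qualifying for both
  classes go to PAS_Branch; subdomain precedence is Artery > Ventricle >
  PAS_Branch > PAS_Surf > BT. All randomness flows through explicit seeds.
* **Degenerate inputs.** Zero-signal voxels and non-physical VFA solutions
  are masked invalid rather than fatal; empty artery thresholds warn;
  disconnected brain masks and sources outside the mesh are errors.

## Open design points, and how they were decided

* **Which baseline is S0** in the concentration equation is ambiguous in
  the field; the 15° (imaging-angle) baseline is used, stated explicitly.
* **Distance metric** for "within N voxels" is Chebyshev (a 7-voxel reach
  means up to 7 dilation steps); Euclidean is available by flag.
* **Ventricle segmentation** uses a simple long-T1 threshold (3000 ms) —
  the simplest rule consistent with T1-based identification.
* **Artery classes** (surface vs branching) are an anatomical annotation,
  not an algorithm. Because the vasculature is one connected tree, classes
  are taken per voxel from the annotation map, with component-majority
  fill for unannotated voxels.
* **Negative concentrations** from noise are kept (flagged) by default:
  clamping would bias the rms objective.
* **Signal forward model** in the phantom uses the same linearized
  contrast relationship the analysis inverts, so noiseless round trips are
  exact to 1e-8 mM and isolate solver/fitting errors; a full SPGR
  T1-shortening forward model would introduce a controlled model mismatch
  and is a natural extension.
* **Velocity convention** is $v = D_\mathrm{eff}/L$; subtracting the
  diffusive reference first changes the result only at the $D_\mathrm{app}$
  scale and is available via `mean_velocity(correct_for = …)`.
* **Open-channel Péclet for brain tissue** is ambiguous (the subtraction
  form gives ~5, the plain ratio ~6); both the raw and reported values are
  returned and neither is treated as a validation quantity.

## Known limitations

* No B1-inhomogeneity correction and no T2\* modelling beyond exclusion
  masks; real-data use assumes the same preprocessing (registration,
  masking) as the originating experiments.
* The structured mesh approximates the brain surface at cell resolution;
  thin PAS shells should keep at least 2 cells across (use `factor = 1`
  at default phantom scale).
* The grid search is exhaustive by design (surfaces are cheap at desk
  scale and give the full error landscape); no gradient-based refinement
  between grid points, so the recovered optimum is quantized to the grid.
* Cross-subject aggregation is limited to summarizing independently
  fitted optima; no hierarchical modelling.
* Efflux routes, convective terms and posture/anesthesia effects are out
  of scope.

## What the tests establish

The suite regenerates all fixtures in code. Closed-form oracles (heat
kernels, unit arithmetic, hand-computed rms values) anchor the solver,
relaxometry and metrics; property tests cover label partitioning,
segmentation monotonicity and determinism, IDW max principle, mesh volume
convergence, mass conservation, and solver symmetry/comparison behaviour.
The acceptance tests additionally verify: the erfc oracle at the 32³ scale
(≤ 5% beyond three cell diameters, improving under refinement), the 0.68
µmol plateau (± 0.5%), VFA and concentration round-trip identities (1e-6
relative / 1e-8 mM), ≥ 99% off-boundary segmentation agreement, exact
noiseless parameter recovery (rms = 0 at the generating triplet), noisy
(2% + dropout) recovery within one log-grid step over five seeds, and the
two-orders-of-magnitude separation between periarterial and tissue
diffusivities. The numbers quoted in the README worked example are the
printed output of that code.
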