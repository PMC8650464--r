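# braintransport

Quantification of macroscopic solute transport in the rodent brain from
dynamic contrast-enhanced MRI (DCE-MRI).

After an intrathecal infusion of a gadolinium contrast agent, DCE-MRI shows
tracer moving through the brain faster than diffusion alone can explain —
first along the periarterial spaces (PAS) of the major surface arteries,
then along branching/penetrating arteries, and finally into the wider brain
tissue. `braintransport` turns that qualitative observation into physical
transport parameters: it converts the T1-weighted signal to concentration,
segments the brain into transport subdomains, fits one effective
diffusivity per subdomain with a diffusion-form PDE model, and derives
Péclet numbers and mean velocities that can be compared directly with known
diffusion rates. It is aimed at researchers analysing glymphatic /
perivascular transport experiments, and at modellers who need a tested,
ground-truth-validated reference implementation.

Because raw animal datasets of this kind are rarely deposited, the package
ships a synthetic digital brain phantom (ellipsoidal brain, artery / PAS /
ventricle / tissue subdomains, tissue-dependent baseline T1, infusion,
noise and T2/T2\* dropout) so that every stage of the pipeline is testable
against known ground truth.

## Model

The analysis lumps diffusion, dispersion and convection into a single
effective diffusivity per anatomical subdomain and solves

```
∂c/∂t = ∇·(D_eff ∇c) + s(c),     no-flux boundary on the brain surface
```

with a point source, rectangular in time, for the infusion (default
0.5 µl/min × 68 mM for 20 min = 0.68 µmol). Signal is related to
concentration through the spoiled-gradient-echo equations:

* baseline T1 mapping from two flip angles (3°, 15°, TR = 16 ms):
  `S(M0, α) = M0 sin α (1 − E1)/(1 − cos α · E1)`, `E1 = exp(−TR/T1,0)`;
* concentration from signal change:
  `c̄ ≅ (1/(r1 · T1,0)) · (S_Gd − S0)/S0`, with `r1 = 3.2×10⁻³ L/(mmol·ms)`
  and `c̄ = c·φ` the superficial concentration (porosity φ ≈ 0.20).

The subdomain diffusivities `(D_eff,BT, D_eff,PAS_Surf, D_eff,PAS_Branch)`
are estimated by exhaustive grid search minimising

```
rms = sqrt( Σ (c_data − c_sim)² / T )
```

over mesh nodes and frames (arteries, ventricles, the injection
neighbourhood and frames after 52 min excluded). Physical interpretation
then uses the apparent diffusivity `D_app = D/λ²` (0.016/1.73² ≈ 0.005
mm²/min for gadoteridol), the Péclet number
`Pe = (D_eff − D_ref − D_disp)/D_ref` (with `D_ref = D_app` for porous and
`D_ref = D` for open-channel transport), and the mean velocity
`v = D_eff/L` with a characteristic length per subdomain.

## Worked example

Build a half-scale phantom, simulate the ground truth at the reference
parameters, check the no-flux diagnostic, and recover the parameters by
grid search:

```r
library(braintransport)
spec <- phantom_spec(grid_shape = c(32, 32, 24),
                     brain_semi_axes = c(1.45, 1.45, 1.05))
gt   <- build_phantom(spec)
gt   <- simulate_truth(gt, transport_params(c(BT = 0.10, PAS_Surf = 95,
                                              PAS_Branch = 60)))
tail(total_amount(gt$concentration, gt$brain_mask), 3)
#>   time_min amount_umol
#> 7       60        0.68
#> 8       70        0.68
#> 9       80        0.68
```

The total amount plateaus at the injected 0.68 µmol — the no-flux sanity
check. Fitting a 3×3×3 log-spaced grid that contains the truth:

```r
fit <- grid_search(attr(gt, "nodal"), attr(gt, "mesh"), deff_grid(),
                   attr(gt, "source"))
fit
#> <fit_result> 27 triplets; optimum:
#>         BT   PAS_Surf PAS_Branch
#>        0.1       95.0       60.0
#> rms at optimum: 0 mM
metrics_report(fit$optimum)
#> Transport metrics (Deff in mm^2/min, v in mm/min)
#>   subdomain deff pe_open pe_porous L_mm velocity enhancement
#>          BT  0.1       5        18  0.5      0.2          20
#>    PAS_Surf 95.0    6000     19000 12.0      8.0       19000
#>  PAS_Branch 60.0    4000     12000  5.0     12.0       12000
#> small-PVS Deff: 3 mm^2/min (600x D_app)
```

Reading the report: periarterial Péclet numbers in the thousands mean
transport along major arteries is convection-dominated; the brain-tissue
value (Pe ≈ 18 against the porous reference) says convection also matters
in the parenchyma; and attributing the excess brain-tissue transport to the
~3% perivascular volume fraction implies a small-PVS transport coefficient
of ~3 mm²/min, 600× faster than hindered diffusion.

## Command line

```sh
braintransport phantom --out-dir ph --grid 64,64,48 --seed 1
braintransport t1map --baseline-low b3.nii --baseline-high b15.nii --tr 16
braintransport concentration --signal dyn.nii --baseline b15.nii --t1 t1_map.nii
braintransport segment --t1 t1_map.nii --conc conc.nii --mask mask.nii \
    --class-map class_map.nii
braintransport mesh --mask mask.nii --labels labels.nii --out mesh.json
braintransport simulate --mesh mesh.json --deff-bt 0.1 --deff-surf 95 \
    --deff-branch 60 --source-location 3.2,0.7,1.0
braintransport fit --mesh mesh.json --conc conc.nii --t-max 52 \
    --source-location 3.2,0.7,1.0
braintransport metrics --deff-bt 0.1 --deff-surf 95 --deff-branch 60
braintransport run --config config.json --out-dir results --seed 1
```

(`braintransport` here is `inst/cli/braintransport`, installed under
`system.file("cli", package = "braintransport")`.)

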