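# ivimon

Interaction vertex imaging (IVI) for 4D monitoring of scanned carbon-ion
therapy of moving targets — a desk-scale simulation and analysis package.

## The problem

Carbon-ion pencil beams stop at a depth set by the integrated density along
their path (the Bragg peak). When a lung tumour moves with breathing, a spot
planned to stop inside the dense tumour can overshoot through low-density
lung tissue — locally overdosing healthy tissue and underdosing the target.
IVI monitors this *during* delivery: nuclear fragmentation of the primary
ions produces light charged fragments (mostly protons and helium) that
escape the patient; tracking them with pixel telescopes behind the target
and intersecting their back-projected lines with the known pencil-beam axis
reconstructs the fragmentation *vertices*. Because fragment production
scales with local density, the per-spot vertex distribution moves when the
anatomy moves.

`ivimon` implements the full measurement chain for a breathing lung-tumour
phantom — a PMMA sphere-plus-cylinder "tumour" inside 0.23 g/cm³ foam
"lung" in a 26 cm PMMA aquarium, riding a motion table that follows the
Lujan breathing trace x(t) = A sin⁴(πt/τ) with A = 20 mm, τ = 3 s:

- **phantom / motion / plan** — geometry and material queries for arbitrary
  rays, the motion trace with its three phase bins (0–3 / 3–17 / 17–20 mm),
  a layered scanned-spot plan for the spherical target (range–energy power
  law R = αEᵖ), and the nozzle (MWPC), motor and FPGA timing logfiles as
  documented CSV dialects.
- **fragsim** — seeded forward simulation: density-proportional vertex
  sampling (exponential thinning), forward-peaked fragment emission,
  Highland multiple-Coulomb-scattering kicks
  θ₀ = 13.6 MeV/pβc · z · √(x/X₀) · [1 + 0.038 ln(x/X₀)],
  and the four 3-sensor CMOS tracker arms at ±10.5°/±21°.
- **trackrec / vertexrec** — straight-track fits and greedy cluster
  matching, rigid software alignment, frame-to-spot association, primary
  track construction (deterministic method a; Gaussian/Highland-randomised
  method b), closest approach of skew lines, and the per-spot computed
  vertex: means in x/y, a distribution quantile q in z (q chosen where the
  static_in/static_out contrast is maximal; ≥ 50 vertices required).
- **monitor** — thresholds from repeated measurements (thr = 2·RMS),
  delivered-as-planned classification with efficiency against the motor
  truth as a function of the position cut pos_m (0.5–3.5 mm), edge-spot
  selection (6 mm shell, x_v > 5, y_v < 0), and per-spot motion-phase
  assignment with its confusion matrix.

## Worked example

```r
library(ivimon)

## motion-phase occupancy of unsynchronised spot delivery
f <- phase_time_fractions(lujan_params(), n_samples = 1e5, seed = 1)
round(100 * f, 1)
#> [1] 43.0 39.1 17.9
```

About 43% of spots land in Phase 1 (target near the in-position), 39% in
the transit Phase 2 and 18% at the outer extreme — the breathing trace
dwells at its turning points.

```r
## a scaled-down end-to-end study: ~500 spots, 3 cases x 5 repeats
st <- run_study(ivi_config(), seed = 1)   # ~13 min
print(st)
#> ivi_study: 509 spots, 5 repeats; q* = 1 ; thr_diff = 33.66 mm
#>   total efficiency (pos_m sweep): 57.1% 60.9% 69.9% 79.9% 84.6% 86.1% 87.2%
round(st$confusion_edge, 1)
#>         calls
#> truth    undefined Phase1 Phase2 Phase3
#>   Phase1       5.0   80.0    8.3    6.7
#>   Phase2      32.5    2.5    0.0   65.0
#>   Phase3       0.0    0.0    0.0  100.0
```

The efficiency of flagging motion-displaced spots rises with the
motor-position cut pos_m (57% → 87%), and edge spots delivered at the
motion extremes are assigned their true phase in 80–100% of cases; the
transit phase is hardest, as its range signature resembles the displaced
static case.

## Command line

```sh
Rscript inst/cli/ivimon.R analyze --seed 1 --repeats 5 --out runs/demo
Rscript inst/cli/ivimon.R report --out runs/demo
```

## Vignette

`vignettes/ivi-monitoring.Rmd` documents the model assumptions, parameter
choices, numerical conventions and the limits of what the synthetic world
can establish.
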