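---
title: "Interaction vertex imaging for 4D range monitoring: models, parameters and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interaction vertex imaging for 4D range monitoring: models, parameters and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`ivimon` simulates and analyses interaction vertex imaging (IVI) as a
spot-by-spot range and motion monitor for scanned carbon-ion therapy of a
breathing lung-tumour phantom. This vignette is the package's own account of
the science: the models, every tunable that matters, the numerical
conventions, and — importantly — what a green test suite does and does not
establish.

## The measurement principle

A carbon pencil beam stops where its accumulated water-equivalent path
length (WEPL) matches its range. Nuclear fragmentation along the way emits
light charged fragments at angles of tens of milliradians with ranges well
beyond the primary's, so some escape the target. Tracking telescopes behind
the target reconstruct their straight lines; intersecting each back-projected
secondary with the known per-spot primary axis (closest approach of two skew
lines) yields a cloud of fragmentation vertices per beam spot. Since
fragment production per unit length scales with the local mass density, the
longitudinal vertex distribution encodes what the beam traversed: when
breathing motion replaces dense tumour surrogate with low-density lung
surrogate, the distribution stretches downstream (range overshoot) and
per-spot summaries move by tens of millimetres — far more than the
repeat-measurement noise.

## The phantom and its frame

Right-handed frame, origin at the isocenter, `z` along the beam, `x` along
the motion; all lengths in millimetres. The phantom is a 260 mm PMMA cube
("aquarium", density 1.17 g/cm³, WER 1.16, X₀ 347 mm) with 10 mm walls on
the x faces and 5 mm on the y/z faces, so the cavity exactly holds the
240 × 250 × 250 mm foam block (0.23 g/cm³; WER and X₀ scaled from PMMA by
the density ratio, i.e. PMMA-like composition). The tumour surrogate is a
PMMA insert: a proximal hemisphere of radius 25 mm centred on the isocenter
plus a cylinder extending 95 mm downstream. The spherical end faces
upstream so that spots planned into the sphere overshoot into foam when the
phantom is displaced; the cylinder length is a free choice (long enough to
absorb distal fragments, fully inside the foam).

The motion table displaces the whole phantom rigidly along x. The motor
position follows the Lujan trace `x(t) = A sin^(2n)(π(t − t₀)/τ)` with
A = 20 mm, τ = 3 s and n = 2 (the classic cos⁴-shaped cycle; the exponent
is not dictated by the geometry, but n = 2 reproduces the ≈ 44/38/18%
occupancy split of the three motion phases 0–3 / 3–17 / 17–20 mm that the
measurement campaign reports). Motion starts at the in-position on the
delivery trigger. **Mounting sign**: the beam-frame offset is the *negative*
of the motor position (`motion_sign = -1`). This is the only mounting for
which the edge-study selection rule (spots with `x_v > 5` mm, `y_v < 0`)
picks the side of the target that *loses* PMMA coverage during motion —
i.e. the high-gradient overshoot region the edge study is defined to probe.
With the opposite sign the same rule would select spots that gain coverage,
making the published selection incoherent.

## Delivery and logfiles

The plan covers the margin-shrunk sphere (radius 25 − 3 mm) with iso-energy
layers spaced by 3 mm WEPL and a 2 mm lateral raster per layer, delivered
serpentine, layers in increasing energy. Spot weights are uniform —
24 000 ions per spot, the desk-scale equivalent of a 2 Gy prescription
spread over thousands of spots; full inverse dose optimisation is out of
scope and nothing downstream depends on absolute weights. The range-energy
relation is a two-point power law `R = αE^p` anchored at (200 MeV/u,
86 mm) and (400 MeV/u, 275 mm) of carbon in water; with the phantom
geometry this stops ~131 MeV/u beams in the proximal half of the sphere,
~170 MeV/u near its centre and ~196 MeV/u in the cylinder, matching the
behaviour of the reference experiment's three single layers.

Beam intensity is 2 × 10⁷ ions/s with 2 ms scanning gaps and 1 s energy
changes. The intensity is scaled down together with the spot weights so a
spot lasts ~1.2 ms ≈ 6 tracker frames (186.5 µs integration time),
preserving the multiple-frames-per-spot structure of the real DAQ. Every
run writes the three logfiles the reconstruction merges: the nozzle spot
log (scanner settings, MWPC centroids/widths at two planes, particle count,
energy, timestamps), the motor log (100 µs sampling, lossless 6-decimal
CSV), and the FPGA timing log (100 kHz ticks: frame clocks, next-spot,
motion trigger).

## The forward model

Per ion: delivery time uniform in the spot interval; lateral entry Gaussian
(σ = 2.5 mm) around the planned spot position; transport parallel to z
(planned slopes are ≤ 3 × 10⁻³, bending the in-phantom path by well under a
millimetre). The stopping depth inverts the piecewise-linear cumulative
WEPL along the wall–foam–insert–foam–wall segment structure. Fragmentation
is exponential thinning with mean free path λ_w = 260 mm in water scaled by
local density; a vertex is recorded if the ion fragments before stopping.

Each vertex emits `n_frag = 3` proton-surrogate fragments with independent
Gaussian angular deviations (σ = 80 mrad per axis) and water range 2.5 ×
the residual primary range at the vertex. The multiplicity is the one
calibrated quantity: the absolute detected-fragment fraction depends on
unpublished cross-section and acceptance details, and the reference
campaign reports 0.2–1% of primaries; with one fragment per vertex the
simulated fraction is 3–5 × too small, with three it lands in the band.
Typical light-charged-fragment multiplicities of carbon inelastic
collisions at therapy energies are indeed 2–4.

Fragments travel straight, receiving Highland multiple-scattering kicks
(θ₀ = 13.6 MeV/pβc · z · √(x/X₀) · [1 + 0.038 ln(x/X₀)], proton pβc from
the inverse Bragg–Kleeman range) as thin-lens deflections at the exit of
each traversed layer (insert, foam, wall). Layer boundary positions are
taken along the unperturbed direction — the kicks are milliradians, so the
boundary-location error is far below a millimetre, and this keeps the
transport fully vectorised. A fragment is detected when its water range
exceeds the WEPL to the phantom exit and its line crosses all three sensor
planes of one arm (±10.5°, ±21°; central sensor 248 mm from the isocenter,
20 mm plane spacing, ~2 × 2 cm active area); cluster positions are smeared
by 10 µm per axis (pixel pitch/√12 plus tracking slack).

## Reconstruction conventions

- **Track fit**: per-arm telescope fit — independent straight-line
  regressions of the two in-plane coordinates against the plane distance;
  residual rms over all six coordinates; greedy best-residual matching with
  a 50 µm cut, each cluster used at most once, combinatorics capped and
  pre-filtered by a 0.3 plane-to-plane slope bound (tracks point back to
  the target).
- **Alignment**: rigid per-sensor offsets from a no-target run; the outer
  sensors define the frame (a rigid offset of a whole arm is unobservable
  from internal residuals), the middle sensor's offset is the mean residual
  against the outer-sensor line. Recovery is within a few micrometres at
  10⁴ tracks.
- **Frame association**: a frame belongs to the spot whose interval
  contains the frame midpoint; frames straddling gaps with less than half a
  frame of overlap map to no spot. The readout hardware does not define a
  rule; the midpoint rule agrees with maximum overlap whenever the midpoint
  is covered.
- **Primary track** (method a): origin = mean of the two MWPC centroids at
  the z of MWPC 1; slopes = planned voxel seen from the scanner-magnet
  pivots (7534 / 8234 mm upstream). Method b redraws the origin from the
  measured beam widths and adds a slope randomisation with the Highland
  angle accumulated in quadrature over the traversed layers; with zero
  widths and scattering disabled it is bit-identical to method a. Method b
  is deliberately *blurrier* — it propagates the measurement uncertainty
  into the vertex cloud — and method a is the default for monitoring, as
  its distributions are sharper.
- **Vertices**: closest approach of the per-spot primary line with each
  secondary; midpoint of the connecting segment; parallel lines fall back
  to the projection of the primary origin. Vertices need DCA ≤ 5 mm
  (configurable; the reference analysis states no cut) and z inside the
  aquarium.
- **Computed vertex**: means in x/y; in z the smallest sample z whose
  empirical cumulative fraction reaches q (no interpolation — the sample
  convention makes the quantile reproducible and oracle-checkable).
  A spot needs ≥ 50 vertices to be valid. q is scanned over 0.5–1.0 in
  steps of 0.05 and fixed where the mean absolute static_in/static_out
  contrast peaks; ties break toward smaller q. On the synthetic world this
  selects q* = 1.0 — the tail contrast grows monotonically — where the
  reference experiment found 90%; its detector acceptance clips the deep
  tail in ways the simplified fragment model does not reproduce. Nothing
  downstream assumes an interior optimum.

## The decision layer

All comparisons are per spot. With five repeats per case, the static
references are repeat-averaged; `difference_in` / `difference_out` are the
absolute z differences of each moving-case repeat against them. The
threshold is `thr_diff = 2 × RMS`, where the RMS is the repeat variability
of the static_in-minus-static_out difference about its per-spot mean,
*pooled across spots*. Per-spot thresholds were implemented and evaluated:
with five repeats the χ-noise of a 5-sample RMS dominates and degrades both
error rates, so pooling is the default. Classification: `difference_in`
at or below threshold is "delivered as planned". Phases: below/above →
Phase 1, above/below → Phase 3, both above → Phase 2, both below →
undefined; equality counts as below throughout.

Ground truth comes from the motor log at the spot mid-time (spots last
~1 ms, a 3 s breathing cycle is frozen at spot scale): the delivery truth
is `|motor| < pos_m` with pos_m scanned over 0.5–3.5 mm, the phase truth is
the motor position binned into the three phases. Spots whose planned
central ray misses the insert at zero offset ("planned overshoot") are
excluded from phase scoring; the uniform-fluence plan targets the shrunk
sphere, so this set is empty here by construction — in the reference plans
it came from dose optimisation.

## Known biases and degenerate cases

- The longitudinal vertex coordinate carries a systematic shift of
  ~+10 mm: fragments whose scattering kicks steer them *into* a tracker are
  preferentially detected, displacing the back-projected line. This
  kick-selection bias is intrinsic to the geometry (it would occur in the
  real detector too), affects all three cases identically, and cancels in
  the differences the monitor thresholds. The transverse centroids are
  unbiased (≪ 1 mm).
- The q = 1 summary is a sample maximum and is noisy for spots whose beam
  halo grazes the insert edge; a ~3σ tail of the 2.5 mm beam spread probing
  foam can move it by tens of millimetres. These spots sit at the boundary
  of "delivered as planned" semantics: their central ray sees no shift but
  part of the beam genuinely does.
- Parallel-line closest approach, zero-length path segments, empty vertex
  sets, spots below the validity cut and frames outside the delivery are
  all handled explicitly and covered by tests.

## What the synthetic world does and does not establish

The simulator reproduces the *mechanisms*: density-proportional vertex
yield, overshoot of the vertex distribution under displacement, energy- and
geometry-dependent detection efficiency, frames/spots/logs bookkeeping, and
repeat-to-repeat stochasticity from counting statistics alone. It does not
model nuclear cross-section energy dependence, fragment species mixtures
and spectra, energy-loss straggling, delta rays, pixel-level charge
sharing, sensor noise (a uniform noise-cluster rate exists as a config
option, default 0), dead time, or beam intensity structure. Consequently a
green end-to-end test establishes that the *pipeline* detects the motion
signatures its own forward model generates at desk scale — it does not
certify the absolute efficiencies of the physical experiment, whose
headline numbers (detected fractions per energy, gradient-detection
reliability percentages) depend on exactly the physics simplified away.
Those serve as qualitative anchors only: detection rising with energy,
efficiency rising with pos_m, Phase 1/3 far easier to call than the
transit phase.

## Reproducibility

Every random stage derives its seed from the master seed through a fixed
integer chain (`seed_chain`), so a configuration plus one integer
reproduces every CSV byte-for-byte. The acceptance script
(`scripts/acceptance.R`) recomputes the motion-phase occupancy percentages
from scratch at any seed.
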