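---
title: "Methods: spatial modelling and quantification of effector shuttling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial modelling and quantification of effector shuttling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the modelling and numerical choices behind
`hipposhuttle`: the reaction–diffusion model and its assumptions, the
solver, the fitting machinery, the image-quantification pipelines, the
gene-signature index, and what the synthetic-data generators do and do
not emulate.

## The shuttling model

Two first-order reaction networks describe a Hippo effector (YAP or
TAZ) as an unphosphorylated species U and a phosphorylated species P on
a two-compartment cell (cytoplasm, nucleus) with a closed plasma
membrane:

* **canonical** — phosphorylation and dephosphorylation confined to the
  cytoplasm, P excluded from the nucleus, U exchanged across the
  nuclear membrane in both directions;
* **alternative** — phosphorylation and dephosphorylation in the
  nucleus, import of U, export of P, cytoplasmic dephosphorylation of
  the exported P.

Both include zeroth-order cytoplasmic synthesis of U (`k_syn`) and
first-order cytoplasmic degradation of U and P (`k_deg`). These two
closure reactions are a modelling decision: they give the linear system
a unique, strictly positive steady state and produce the
disseminating-from-the-nucleus gradient that distinguishes the two
topologies in images; without them the steady state would be determined
by the (arbitrary) initial amount. Upstream kinases are not explicit
state variables — their activity is folded into the phosphorylation
rate constant.

Membrane transport is a first-order flux density: permeability
(µm/s) times source-side concentration, applied on every
cytoplasm–nucleus pixel face. Because each face transfers the same
amount out of one pixel and into the other, transport is exactly
conservative on the grid.

### Parameters

| parameter | units | default | role |
|---|---|---|---|
| `k_phos` | 1/s | 0.1 | U → P (nucleus in alternative, cytoplasm in canonical) |
| `k_dephos_nuc` | 1/s | 0.2 | nuclear P → U (alternative only) |
| `k_dephos_cyt` | 1/s | 0.05 | cytoplasmic P → U |
| `k_import` | µm/s | 0.2 | nuclear-membrane import of U |
| `k_export` | µm/s | 1.0 | export (P in alternative, U in canonical) |
| `k_syn` | conc/s | 0.01 | cytoplasmic synthesis of U |
| `k_deg` | 1/s | 0.01 | cytoplasmic degradation of U and P |
| `D_*` | µm²/s | 3 | diffusion per species and compartment |

The defaults were chosen once so that the nuclear
phosphorylation/dephosphorylation ratio `r = k_phos / k_dephos_nuc`
sweeps the biologically relevant regimes: the well-mixed NCR of the
alternative network is strictly decreasing in `r`, diverges as `r → 0`
(export acts only on P, so without phosphorylation the nucleus has no
exit path) and crosses 1 between the low-`r` nuclear-enriched and
high-`r` nuclear-excluded regimes. A diffusion coefficient of a few
µm²/s and export faster than import are in the range of published
estimates for YAP mobility and transport. Fitting bounds default to
rate constants 1e-4–1 1/s, permeabilities 1e-3–10 µm/s and diffusion
0.1–30 µm²/s (`default_param_bounds()`), spanning published values
while avoiding numerically stiff extremes; all are user-overridable.

The well-mixed compartment-ODE reduction (`wellmixed_steady_state()`)
is solved directly as a linear system and doubles as the oracle for the
spatial solver in its high-diffusion limit.

## The FTCS solver

The spatial model is integrated with an explicit forward-time
centred-space scheme on the pixel grid (implemented in C++): a
4-neighbour Laplacian restricted to same-compartment neighbours
(compartment boundaries are reflecting), reaction terms per pixel, and
membrane fluxes on the face lists. Concentrations are areal densities
on the 2D image plane, matching the single-confocal-slice data the
model is meant to fit; there is no 3D geometry.

Numerical choices:

* **Time step.** `stable_timestep()` takes the smaller of the diffusive
  CFL bound `safety · h²/(4 D_max)` and the first-order bound
  `safety / k_max`, where `k_max` is the largest total first-order loss
  rate any pixel can experience — permeability losses count three
  times, because a pixel can carry up to three membrane faces. Because
  the diffusive and kinetic losses can coincide on membrane pixels, the
  update additionally clamps transient negative undershoot to zero;
  with the default `safety = 0.9` and non-extreme parameters the clamp
  never triggers.
* **Steady state.** Integration stops when the maximum pixel-wise rate
  of change falls below `tol` times the mean cell concentration
  (default `tol = 1e-6` per second), or at `t_max` (returned flagged,
  not as an error). The reported `final_rate_norm` makes the stopping
  state auditable.
* **Initial condition.** All protein as U, uniform in the cytoplasm.
  The network is linear with a unique attracting steady state, so the
  fitted observable is initialization-independent; the test suite
  asserts this from two different initial conditions, and that two
  admissible time steps agree within 1%.
* **Grid convergence.** The membrane flux introduces a concentration
  boundary layer of width ~`D / k_export` next to the nuclear envelope.
  Halving the pixel size changes compartment means by under 2% when
  that layer is resolved at both resolutions; with very fast export the
  layer is a pixel wide and convergence in the nuclear means is slower.
  This is why simulated and experimental patterns are compared through
  the same max-normalized observable rather than bit-wise.

## Fitting

Targets and simulated observables (U + P summed per pixel — the tag
labels both forms) are each normalized to their own maximum, removing
the arbitrary intensity scale. The cost at a parameter point is

```
w_img · mean over cell pixels of (target − simulation)²
+ w_ss · mean over cell pixels of (dc/dt / mean concentration)²
```

The second term penalizes parametrizations whose simulation has not
actually reached steady state. With the defaults `w_img = w_ss = 1` a
residual drift of 1% of the mean concentration per second costs the
same as a 1% image mismatch — the weights are unitless and
config-exposed because no published values exist for them.
"Summarized residual" is the same image term (mean of squared
residuals over cell pixels), which makes scan values comparable across
geometries of different size.

Optimization is a global-best particle swarm (default 20 particles,
200 iterations; reduced sizes are used in the test suite) in log10
parameter space, since rate constants span orders of magnitude.
Inertia 0.729 and cognitive/social coefficients 1.49445 are the
standard constriction values; bounds are handled by reflection; the
swarm is bit-deterministic given its seed, and the caller's RNG stream
is left untouched. Ensembles of fitted parametrizations are produced
by looping over seeds.

### Identifiability and the recovery design

For this observable the fit is structurally under-determined: at steady
state the U + P field inside each compartment is shaped only by the
membrane fluxes, so the nuclear reaction pair enters through the single
combination `k_phos / (k_dephos_nuc + export rate)`. Letting `k_phos`
and `k_dephos_nuc` float jointly therefore leaves the ratio
`r = k_phos / k_dephos_nuc` unconstrained along an exact degeneracy
(the package's tests demonstrate the well-fitting degenerate
solutions). The ratio-recovery experiment consequently follows the
scan design: all parameters except the nuclear phosphorylation rate
are held at their generating values and `r` is derived from the fitted
`k_phos` — under that design the ratio is recovered within 25% at the
tested truths. The same reasoning applies to absolute rates generally:
concentrations are in arbitrary units and only steady-state data are
fitted, so conclusions are drawn from ratios and from topology
comparisons, never from absolute rate values.

`ratio_scan()` re-simulates the alternative model over a ratio grid
with everything else fixed and reports the summarized residual and the
simulated NCR per ratio; non-convergent rows are flagged rather than
dropped. Against a nuclear-enriched target the residual is minimized
at low ratios, against a cytoplasm-enriched target at high ratios, and
the NCR column is non-increasing in the ratio — the model-selection
logic the acceptance script reruns end to end.

## Image quantification

The published pipelines rely on interactively trained pixel
classifiers, which cannot be redistributed; the package abstracts the
classifier to a contract (image in, per-pixel foreground probability in
[0, 1] out) with two backends: a deterministic baseline (Gaussian
smoothing, then min–max rescale or absolute clamping) and an optional
random forest on standard pixel features (`rf_classifier()`).
Probability maps are thresholded (Otsu by default) and components
outside a size window are dropped.

* **NCR.** Nuclear and cell masks come from the H2B and effector
  channels; cytoplasm = cell minus nucleus. A 1-pixel boundary margin
  (erode the nucleus, exclude the same band from the cytoplasm) keeps
  mixed boundary pixels out of the compartment means; without it the
  bright perinuclear halo biases the measured NCR low by ~10%, with it
  the render → segment → NCR loop closes to within 5% of the simulated
  compartment ratio. Density stratification splits fields at the
  arithmetic mean cell count, at-or-above going to the high group.
* **PLA.** Nuclei and dots are segmented separately — the dot channel
  with a smoothing scale matched to the diffraction-limited dot size,
  so neighbouring dots are not blurred together. The pseudo-cytoplasm
  is the 30-pass dilation of the nuclear mask (a single dilation with a
  square brush of width 2·30 + 1, 8-connected semantics) minus the
  nuclei; dots are assigned by centroid, and fused blobs are split by
  area relative to the median blob, which removes the merging
  undercount at realistic dot densities. Nuclear + cytoplasmic +
  unassigned always equals the total.
* **IHC.** Tiles below the 50% tissue-fraction cutoff are excluded
  (flagged, not dropped). Positivity uses a fixed probability cutoff
  (default 0.5) on an absolute intensity scale rather than per-tile
  Otsu, because tiles with few or no positive nuclei have no bimodal
  histogram to split; densities are positive nuclei per tissue-mm².
  The variance-of-Laplacian `focus_score()` is available as an optional
  prescreen for out-of-focus fields, with the threshold left to the
  user (the published screening was manual).

## Signature expression index

Expression values (log2 scale assumed, linear supported) are z-scored
per gene across all samples (the alternative — z-scoring across
time-point means — is exposed through replicate handling options);
zero-variance genes score 0 and are flagged. The index at a time point
sums the per-gene z-scores strictly greater than 0.5 — strict because
the rule is defined as "greater than" — and divides by the signature
size. Replicate z-values are averaged per gene and time *before*
thresholding (the published index is a single curve per signature);
threshold-then-average is available as an option. Large signatures can
be pre-filtered to genes moving more than 2-fold against the control
group. Peak times are arg-max with ties broken to the earliest time
and flagged. Real signature gene lists must be supplied by the user;
the shipped lists under `inst/extdata/signatures/` are synthetic
placeholders of the documented sizes (23/28/23 genes).

## Synthetic data: what it does and does not emulate

The generators are pure functions of a specification and a seed.
`synth_geometry()` emulates the confocal acquisition geometry (default
physical pixel 1.24 µm; grids of 48–256 px are used in the tests and
128 px in the acceptance script, with the 512 px full-FOV scale
available) with elliptical cells and offset elliptical nuclei kept
clear of the cell boundary. `render_fluorescence()` applies gain,
Poisson shot noise, Gaussian read noise and a constant background.
PLA scenes place Poisson-distributed dots uniformly within nuclei and
their dilation rings; IHC tiles contain a smoothed-noise tissue blob
thresholded to an exact tissue fraction with disk-shaped positive
nuclei; expression time courses give signature genes a log-time
Gaussian activity bump (default peaks staggered at 9 h / 18 h / 36 h
inside the observed activation windows) over i.i.d. replicate noise.
The density-dependence fixture couples the phosphorylation ratio to
local cell count through a logistic map purely as a test device.

Not emulated: point-spread-function blur, chromatic aberration and
channel bleed-through, segmentation-hostile cell crowding, histology
colour deconvolution, and microarray probe effects. Passing tests
therefore demonstrate that the pipelines recover known ground truth
under idealized imaging physics — they do not certify performance on
real microscopy, where classifier training and artifact screening
dominate.

## Problem sizes and runtime choices

The test suite and acceptance script run single- and few-cell
geometries of 48–128 px, swarm sizes of 8–20 particles and 15–50
iterations, and 20-seed replications for the statistical recoveries;
these sizes were chosen so the whole suite completes in minutes on one
CPU while leaving every recovery criterion comfortably inside its
tolerance. The full published-scale settings (512 px fields, 20 × 200
swarms, 200-seed ensembles) are plain parameter choices away and use
the same code paths.

## Known limitations

* 2D single-slice physics; no 3D nuclear geometry or membrane
  curvature effects.
* Explicit time stepping only; stiff parameter corners (permeabilities
  near 10 µm/s on coarse grids) cost small time steps.
* Absolute rates are not identifiable from steady-state images in
  arbitrary units; only ratios and topology comparisons are meaningful.
* The baseline classifier is intensity-based; textured or uneven
  backgrounds need the random-forest backend or an external classifier
  honouring the probability-map contract.
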