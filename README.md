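# hipposhuttle

Spatial modelling and image quantification of YAP/TAZ
nuclear–cytoplasmic shuttling.

## The scientific problem

The Hippo pathway controls cell proliferation through its effectors YAP
and TAZ: when unphosphorylated they act in the nucleus, when
phosphorylated they are held in the cytoplasm. In live-cell confocal
images of hepatocyte-derived cells, the spatial pattern of tagged
YAP/TAZ — in particular the bright "halo" around the nuclear envelope —
carries information about *where* the phosphorylation cycle runs. This
package is for quantitative cell biologists and modellers who want to

* simulate reaction–diffusion models of effector shuttling on pixel
  geometries derived from (or emulating) microscopy images,
* fit those models to max-normalized fluorescence images and compare
  competing pathway topologies,
* quantify images the same way the models are fitted: per-field
  nuclear/cytoplasmic ratios (NCR) with cell-density stratification,
  proximity-ligation (PLA) dot counts per subcellular compartment, and
  positive-nuclei densities on immunohistochemistry (IHC) tiles,
* score gene-signature activity over a post-injury expression time
  course with a z-score index.

## The model

Two model topologies are implemented, both with first-order kinetics
for every reaction and a closed plasma membrane. Species are the
unphosphorylated (U) and phosphorylated (P) effector; the fluorescent
tag reports U + P.

* **Canonical**: phosphorylation U → P and dephosphorylation P → U run
  in the cytoplasm only; P never enters the nucleus; U crosses the
  nuclear membrane in both directions.
* **Alternative (nuclear phosphorylation)**: U → P and P → U run in the
  nucleus; U is imported, P is exported and dephosphorylated in the
  cytoplasm. The dimensionless nuclear ratio *r* = k_phos / k_dephos
  controls localization: low *r* retains the effector in the nucleus,
  high *r* expels it.

Both share zeroth-order cytoplasmic synthesis and first-order
degradation, so a unique steady state exists. On a pixel label map
(exterior / cytoplasm / nucleus) the concentrations obey

    dc/dt = D ∇²c + reactions,   with membrane flux density J = k · c_source

on each nuclear-membrane pixel face, solved with an explicit
forward-time centred-space (FTCS) scheme until the distribution stops
changing. Fitting minimizes a weighted two-term cost — mean squared
pixel difference between the max-normalized simulated observable and
the target image, plus the mean squared concentration rate of change
(penalizing non-converged simulations) — with a global-best particle
swarm (default 20 particles × 200 iterations) in log10 parameter space.

## Worked example

Simulate a nuclear-enriched cell with the alternative topology, scan
the phosphorylation/dephosphorylation ratio against a rendered noisy
target, and refit the phosphorylation rate:

```r
library(hipposhuttle)

spec <- scene_spec(grid = 128, n_cells = 1, cell_radius = c(24, 28),
                   nucleus_radius = c(8, 10), gain = 2000, seed = 11)
geom <- synth_geometry(spec)
net  <- shuttle_topology("alternative")
pars <- set_phospho_ratio(shuttle_params(), 0.17)
sim  <- simulate_steady_state(geom, net, pars, tol = 1e-6, t_max = 5000)
sim
#> FTCS simulation (alternative topology): 13225 steps of dt = 0.1153 s (t = 1525.1 s)
#>   steady state reached: TRUE (max |dc/dt| = 8.57e-07 conc/s)
#>   simulated NCR: 2.712

target <- render_fluorescence(sim, geom, spec)$channels$effector
ratio_scan(target, geom, shuttle_params(),
           ratios = c(0.05, 0.17, 0.4, 0.75, 1.5))
#>      r summarized_residual   ncr_sim converged
#> 1 0.05        5.182504e-02 8.7254309      TRUE
#> 2 0.17        9.961074e-05 2.7110328      TRUE
#> 3 0.40        1.311956e-01 1.2678092      TRUE
#> 4 0.75        3.412409e-01 0.7673939      TRUE
#> 5 1.50        3.712611e-01 0.4773197      TRUE

fit <- fit_shuttling_model(target, geom, net,
                           bounds = default_param_bounds()["k_phos", , drop = FALSE],
                           n_particles = 10, n_iterations = 20, seed = 2,
                           sim_tol = 1e-4, sim_t_max = 2500)
phospho_ratio(fit$best_params)
#> [1] 0.1695044
```

Reading the output: a simulated NCR of 2.7 means the effector is
2.7-fold enriched in the nucleus; the ratio scan is minimized at the
generating ratio 0.17 (summarized residual ~1e-4, the rendering-noise
floor) while the cytoplasm-enriched regime (r = 0.75, NCR 0.77) fits
this nuclear-enriched target badly; and the one-parameter particle
swarm recovers the generating ratio to within 3%.

The quantification side mirrors the published pipelines:
`segment_channels()` + `ncr_for_fov()` + `density_split()` for
live-cell NCR, `pla_count()` (30-iteration nuclear-mask dilation for
the pseudo-cytoplasm) for PLA, `ihc_quantify()` (1 mm² tiles, ≥50%
tissue filter) for IHC, and `zscore_matrix()` + `expression_index()`
(z > 0.5, normalized to signature size) + `peak_time()` for signature
activity. `synth_*()` generators produce every input with ground
truth.

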