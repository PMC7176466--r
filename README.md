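# lungeit

Regional lung mechanics monitoring with electrical impedance tomography
(EIT), for researchers studying ventilator-induced lung injury and
EIT-guided ventilation in ALI/ARDS.

Mechanical ventilation injures the heterogeneous lung regionally — dependent
regions collapse (atelectasis) while open regions overstretch
(overdistension) — yet ventilators are steered by whole-lung numbers. A
16-electrode EIT belt images regional impedance change ΔZ at 20 frames/s,
and ΔZ tracks regional tidal volume. `lungeit` implements the complete
processing chain from raw voltage frames to regional mechanics maps:

1. **Forward model / reconstruction** — 2-D finite-element thorax model with
   adjacent current stimulation (208 channels), one-step Gauss–Newton
   normalized-difference imaging
   `x̂ = (JᵗJ + λ²R)⁻¹ Jᵗ y`, `y = (V − V_ref)/V_ref`,
   with a Laplacian smoothness prior, optional electrode-movement
   compensation, and λ calibrated so the *noise figure* equals 0.60;
   images rasterized to a 32×32 grid in the radiological convention.
2. **Breath detection** — global-signal spectral peak sets an automatic
   bandpass (f_upper = 2·f_peak, 128-tap zero-phase FIR); peak
   inspiration/expiration from the filtered extrema; intra-tidal difference
   images.
3. **Lung ROI** — functional-EIT image (per-pixel SD of filtered ΔZ),
   automatic threshold by classification stability, per-step ROIs merged by
   logical OR.
4. **Regional mechanics** — per-pixel dynamic compliance
   `C_dyn = ΔZ/ΔP_awo` across a recruitment/PEEP-titration protocol,
   `C_max`/`P*` maps, overdistension/atelectasis fractions
   `F(P) ∈ [−1, 1]`, C_max-weighted step summaries, and EIT-vs-ventilator
   compliance correlation.
5. **Phantom simulator** — protocol datasets (voltage streams, ventilator
   log) with full ground truth: lung-shaped tidal conductivity oscillation,
   cardiac component, white measurement noise, and per-region tent-shaped
   compliance-versus-pressure curves.

See the vignette (`vignettes/regional-lung-mechanics.Rmd`) for the model
details and design choices.

## Worked example

Simulate a four-step slice of the ventilation protocol and push it through
the full pipeline:

```r
library(lungeit)
meshes <- thoraxMeshPair()            # fine (simulation) + coarse (inverse)

recon <- buildReconModel(meshes$coarse, nfTarget = 0.60)
recon
#> ReconModel: 224 elements x 208 channels, lambda = 0.1944,
#>   noise figure = 0.601 (electrode movement modeled)

scenario <- simScenario(seed = 42, breathsPerStep = 8)
protocol <- defaultProtocol()[c(1, 3, 10, 12), ]   # baseline, R2, T5, T7
sim <- simulateProtocol(meshes$fine, scenario, protocol)
res <- analyzeProtocol(lapply(sim$steps, `[[`, "voltages"), sim$ventLog,
                       recon = recon)

res$complianceSeries
#>   step_label       stage pressure delta_p    eit_cdyn   vent_c
#> 1          B    baseline       22      12 0.016814190 4.068861
#> 2         R2 recruitment       35      15 0.009328638 2.359349
#> 3         T5   titration       12      12 0.021484462 4.979886
#> 4         T7   titration        8      12 0.019440285 4.610203

res$correlation$r
#> [1] 0.9991538

m <- detectionMetrics(res$steps[[2]]$breaths, sim$steps[[2]]$truth$breaths,
                      frameRate = 20)
c(sensitivity = m$sensitivity, specificity = m$specificity)
#> sensitivity specificity
#>         100         100
```

Reading the output: λ was tuned by bisection until the noise figure hit
0.60 ± 0.01, so noise amplification is standardized rather than hand-picked.
`eit_cdyn` is the whole-ROI mean dynamic compliance per step in arbitrary
ΔZ units; it drops under the high recruitment pressures (R2, overdistension)
and recovers during titration, tracking the simulator's ventilator
compliance `vent_c` (Pearson r ≈ 0.999 here — EIT and ventilator agree on
*when* compliance changes even though their units differ). Breath detection
on the reconstructed, filtered global signal found every simulated breath in
step R2 with no false positives. Per-pixel products (`res$summaries`,
`res$fMaps`, `res$stepSummaries`) hold the C_max/P* maps, the F(P) maps and
the C_max-weighted overdistension/atelectasis percentages per step.

A one-command version of the same thing (simulation + analysis + CSV/JSON
reports under `out/`):

```r
runPipeline(pipelineConfig("out", seed = 1))
```

or from a shell, `Rscript inst/scripts/lungeit-pipeline.R run --out out`.

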