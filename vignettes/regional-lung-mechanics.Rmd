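---
title: "Imaging regional overdistension and atelectasis with thoracic EIT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imaging regional overdistension and atelectasis with thoracic EIT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungeit)
```

## The problem

Mechanical ventilation of the injured lung (ALI/ARDS) trades two regional
hazards against each other: atelectasis — collapsed, non-aerated tissue in
the dependent lung — and overdistension of the tissue that is already open.
Both are heterogeneous, so whole-lung quantities such as global compliance
cannot localize them. Electrical impedance tomography (EIT) measures boundary
voltages from a belt of 16 electrodes while small currents are injected, and
reconstructs a cross-sectional image of impedance *change* at 20 frames/s.
Because regional impedance change (ΔZ) tracks regional air content, an EIT
image series during a stepwise recruitment/PEEP-titration protocol carries
enough information to map where the lung opens, where it collapses, and where
it is overstretched.

`lungeit` implements that full chain as a library: forward model and
reconstruction, breath detection, functional-EIT lung segmentation, and
regional compliance analysis, together with a phantom simulator that
generates protocol datasets with complete ground truth.

## Forward model and reconstruction

The thorax cross-section is a 2-D linear-triangle finite-element model with
16 point electrodes placed equidistantly (by arc length) on the boundary,
numbered clockwise in the radiological convention. Currents are injected
through adjacent electrode pairs and voltages read on all adjacent pairs not
involving a driving electrode, giving $n_M = 16 \times 13 = 208$ channels per
frame. Two meshes are used throughout: a fine mesh (~1000 elements) for
simulation and a coarse mesh (~220 elements) for inversion, so simulated data
are never inverted on the mesh that produced them.

Imaging is normalized-difference: for each frame
$y = (V - V_\mathrm{ref})/V_\mathrm{ref}$, where $V_\mathrm{ref}$ averages
the peak-expiration frames. The reference is found in two passes — first the
lowest decile of the per-frame mean voltage, then, after breath detection,
the detected peak-expiration frames ±1. The image is the one-step
Gauss–Newton estimate

$$\hat{x} = (J^t J + \lambda^2 R)^{-1} J^t y,$$

with $J$ the conductivity Jacobian (adjoint method) row-normalized by the
homogeneous-background voltages, optionally augmented with an
electrode-movement block computed by central finite differences of the
electrode positions. $R$ is block diagonal: a graph Laplacian over the
element adjacency (smoothness prior) for conductivity, a scaled identity for
the 32 movement parameters. Movement columns are rescaled so their mean
column norm matches the conductivity block before $\lambda$ applies;
movement estimates are discarded from the images. ΔZ is defined as
$-\hat{x}$ so that inspiration (a conductivity decrease) is positive, and
images are rasterized onto a 32×32 grid (area-weighted element averages;
pixels with less than 50 % thorax coverage are invalid).

### Regularization strength: the noise figure

$\lambda$ is not hand-tuned. It is calibrated so that the *noise figure* —
the ratio of measurement-domain to image-domain signal-to-noise for a small
central target — equals 0.60. With a one-element central target $x_t$,
$y_t = J x_t$ and channel-iid unit-variance noise, the noise figure has the
closed form

$$\mathrm{NF} = \frac{\overline{\lVert B_{k\cdot} \rVert_2} \;
\overline{|y_t|}}{\overline{|B y_t|}},$$

evaluated through the row norms of the reconstruction map $B$. NF decreases
monotonically in $\lambda$ over the search bracket, so a bisection on
$\log\lambda$ (bracket auto-expanded by doubling) reaches the target within
±0.01. The exact weighting (mean absolute value, unit-variance channel
noise, one-element central target) is fixed here for reproducibility; other
noise-figure conventions would shift $\lambda$ but not the pipeline
structure.

## Breath detection

The global signal is the mean ΔZ over valid pixels. Its dominant frequency
above 0.01 Hz (mean-detrended, Hann-tapered spectrum, zero-padded ≥ 4×) sets
the upper bandpass corner at $f_\mathrm{upper} = 2 f_\mathrm{peak}$. The
filter is a 128-tap linear-phase FIR applied forward–backward (zero phase,
implemented as one pass of the symmetric autocorrelation kernel with reflect
padding), so extrema positions are preserved exactly.

Two numerical choices deserve a note. First, a 6.4 s impulse response cannot
realize a literal 0.01 Hz −3 dB corner; the lower corner is therefore
*nominal* and implemented as an exact DC null (the taps are de-meaned),
which is all it contributes in this band. Second, at 128 taps and 20 frames/s
the respiratory band is narrower than the design transition width, so the
raw response is a rounded hump; the taps are normalized to exactly unit gain
at $f_\mathrm{peak}$ so the tidal amplitude survives filtering, and the
upper cutoff is calibrated numerically so the forward–backward −3 dB point
sits at $2 f_\mathrm{peak}$. A 1.8 Hz cardiac component is attenuated far
beyond the 3 dB the protocol requires.

Peak inspiration/expiration are the alternating extrema of the filtered
global signal (sign changes of the discrete derivative). Swings smaller than
20 % of the signal's interquartile amplitude are pruned — the prominence
threshold is this package's choice, since noise-level extrema must be
excluded somehow — and unpaired leading/trailing extrema are dropped.
Detection accuracy against ground truth uses greedy one-to-one matching of
inspiration peaks within 0.5 s; each inter-breath period counts as one true
negative unless it contains a false detection.

The intra-tidal (tidal difference) image is the mean over accepted breaths of
the inspiration-minus-expiration frame difference, with negative pixels
retained.

## Lung ROI: functional EIT

The fEIT image is the per-pixel sample standard deviation of the filtered ΔZ
series. A pixel joins the lung ROI if its SD exceeds $\theta$ times the
image maximum (taken over valid pixels only). $\theta$ is selected
automatically on the grid 0.05–0.60 (step 0.025) by minimizing the number of
pixels classified inconsistently against the ROIs at $\theta \pm 0.025$;
ties break toward 0.25 (the center of the recommended manual range), then
toward the lower value. Per-step ROIs are merged by logical OR into the
aggregate ROI used for all mechanics.

On the synthetic data the automatic threshold tends to settle higher than
the 0.20–0.35 range reported for patient data: the simulated
reconstructions are smoother than clinical recordings, and on a smooth
single-hump fEIT image the stability criterion favors compact
high-threshold cores. The aggregate-OR design compensates, because the
ventilation locus moves with pressure across the protocol, and the union
recovers the lung footprint (the test suite checks Dice ≥ 0.6 against the
true mask at 20 dB SNR). This is a known bias of threshold-stability
selection on clean data, not a tuning target.

## Regional mechanics

With $\Delta P_\mathrm{awo} = P_\mathrm{plat} - \mathrm{PEEP}$, each step's
pixelwise dynamic compliance is $C_\mathrm{dyn} = \Delta Z / \Delta
P_\mathrm{awo}$. Within a stage (recruitment or titration) the per-pixel
maximum $C_\mathrm{max}$ and its pressure $P^*$ are extracted; the
stage-relevant pressure is the plateau pressure during recruitment and PEEP
during titration. Ties in the argmax resolve to the lowest tied pressure;
pixels with $C_\mathrm{max} \le 0$ are flagged invalid and excluded
downstream. The overdistension/atelectasis fraction is

$$F(P) = \begin{cases}
\dfrac{C_\mathrm{dyn}(P) - C_\mathrm{max}}{C_\mathrm{max}}, & P < P^* \\[1ex]
\dfrac{C_\mathrm{max} - C_\mathrm{dyn}(P)}{C_\mathrm{max}}, & P \ge P^*,
\end{cases}$$

bounded in $[-1, 1]$: positive values are the overdistended fraction,
negative values the (reversible) atelectatic fraction. Step summaries report
the $C_\mathrm{max}$-weighted averages of the positive and negative parts of
$F$ (an unweighted variant is available; the weighted one is the default and
outputs are labelled), plus the percentage of ROI pixels at their maximum
compliance. Whole-lung EIT compliance (ROI-mean $C_\mathrm{dyn}$ per step) is
compared with the ventilator's compliance series by Pearson correlation with
a $t$-distribution $p$-value on $n-2$ degrees of freedom.

## The phantom simulator

The simulator exists to give the pipeline inputs with *known* answers, at the
statistical structure the method assumes — it is not a physiological model.
Per frame, element conductivity is

$$\sigma_e(t) = 1 - w(t)\, C_e(P)\,\Delta P_\mathrm{awo}
  + b(t)\, a_e^{\mathrm{card}},$$

with $w(t)$ a raised-cosine breath waveform (inspiration over 40 % of the
cycle, expiration over 60 %, smooth unique extrema; the intra-breath shape is
unspecified in the clinical literature and this choice keeps both peaks
well-defined), $b(t)$ a cardiac sinusoid confined to a central ventral
region, and white Gaussian channel noise added at a prescribed SNR. Voltages
come from the full nonlinear forward solve on the fine mesh, frame by frame.

The regional truth is a tent: compliance rises linearly to $C_\mathrm{max}$
at $P^*$ and falls linearly on both sides. Defaults, chosen once as
plausible study conditions and then left alone:

| parameter | default | rationale |
|---|---|---|
| respiratory rate | 23.5 /min | reported population mean |
| heart rate | 109 /min | reported population mean |
| cardiac amplitude | 30 % of respiratory | reported relative magnitude |
| SNR | 20 dB | reported noise conditions |
| frame rate | 20 Hz | device frame rate |
| breaths per step | 15 | reported per-step average |
| mean $C_\mathrm{max}$ | 0.015 σ-units/cmH₂O | keeps conductivity excursions ≲ 25 % of baseline |
| tent half-width | 40 cmH₂O | every protocol step stays ventilated ($F < 1$), as in patients |
| $P^*$ field | 8 → 18 cmH₂O ventral → dorsal | dependent lung opens at higher pressure |
| baseline PEEP / VC ΔP | 10 / 12 cmH₂O | typical volume-controlled settings |

The lung is two ellipses with smoothly heterogeneous $C_\mathrm{max}$
(patchy compliance); the dorsoventral $P^*$ gradient makes the ventilation
locus migrate with pressure, which also produces hysteresis-like map pairs
because recruitment is indexed by plateau pressure and titration by PEEP.
Per-step noise streams derive from the master seed plus the step index, so
any step is independently reproducible; equal seeds give bit-identical
output.

What the simulator does **not** emulate: airway flow dynamics and the flat
expiratory pause of passive exhalation, perfusion, electrode drift or
contact-impedance artifacts, chest-wall deformation, and patient-to-patient
geometric variability. Passing tests therefore demonstrate that the
pipeline's machinery is correct and self-consistent under the assumed signal
structure — not that it meets the same figures on clinical recordings.

## Numerical choices and degenerate inputs

* Meshing is a structured star-shaped triangulation (equal-arc boundary
  resampling, scaled interior rings, center fan): electrodes land exactly on
  nodes, element counts are predictable, and no external mesher is needed.
  Self-intersecting contours and targets below 50 elements are refused.
* The FEM ground is the most dorsal boundary node; adjacent-pair drive and
  measurement make every channel reference-free.
* Jacobian checks use finite-difference steps of $10^{-6}$ (conductivity)
  and $10^{-3}$ of the inter-electrode spacing (movement); tangled meshes
  trigger step halving, then an error.
* Zero reference voltages abort normalization with the channel named;
  all-masked frames, single-frame fEIT inputs, empty breath tables, and
  zero-variance correlation inputs raise errors rather than propagate NaN.
* $F(P)$ outside $[-1, 1]$ by more than $10^{-9}$ is an error; smaller
  excess is clipped as numerical noise.

## Problem sizes

The shipped analyses run on a ~960-element fine mesh and ~224-element coarse
mesh, 13 protocol steps × 15 breaths (~10 000 frames at 20 Hz); the test
suite uses the same meshes with fewer breaths per step for the unit-level
checks and the full protocol for the end-to-end ones. These sizes were
chosen to make a complete simulate–reconstruct–analyze cycle comfortable on
a laptop while keeping the inverse problem genuinely ill-posed.

## Known limitations

* 2-D point-electrode model: no complete-electrode model, contact
  impedances, or out-of-plane currents; absolute image geometry depends on
  the packaged synthetic contour, not on patient anatomy.
* Amplitudes are relative. ΔZ and $C_\mathrm{dyn}$ carry an arbitrary
  uniform gain, so only ratios, correlations and the dimensionless $F(P)$
  are comparable across runs; recovered $C_\mathrm{max}$ matches truth up to
  one global scale.
* Only *reversible* atelectasis is visible: a region with no airflow anywhere
  in the protocol never enters the ROI.
* The tent compliance model reaches zero outside its support; real
  pressure–volume behaviour saturates instead. Quasi-static compliance is
  systematically underestimated by any dynamic method, this one included.
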