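---
title: "Models and methods behind ribbonphys"
author: "ribbonphys authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ribbonphys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribbonphys)
```

`ribbonphys` implements the analysis chain used to characterise inner hair
cell (IHC) ribbon synapses — presynaptic Ca~V~1.3 activation, exocytic
capacitance changes, single-active-zone Ca^2+^ imaging, synaptic-puncta
volumetry, ABR thresholds and the accompanying statistics — together with
synthetic generators for every raw input. This vignette is the package's own
account of the science: the models and their assumptions, the parameters
that matter, what the generators do and do not emulate, and the numerical
choices that were genuinely open.

## Channel model and whole-cell IV analysis

All simulators share a minimal biophysical model: a Boltzmann-gated calcium
conductance with linear driving force plus ohmic leak,

$$I(V) = g_{max}\,P_o(V)\,(V - V_{rev}) + g_{leak}(V - V_{hold}), \qquad
P_o(V) = \frac{1}{1 + \exp\!\big((V_{half} - V)/k\big)}.$$

Assumptions worth stating explicitly:

* **Open probability increases with depolarization.** The Boltzmann is
  written so that $P_o \to 1$ for $V \gg V_{half}$, the physiological
  convention for an activation curve.
* **Linear driving force.** Permeation is not modelled (no GHK
  rectification); the linear form matches the conductance formalism used
  when fractional activation is computed from an IV curve. The reversal
  potential is a model parameter, default +45 mV, treated in fits as a free
  parameter bounded to [+20, +80] mV — a typical range for calcium currents
  in a mixed intracellular/extracellular ion milieu.
* **No capacitive transients, no stochastic gating.** Sweeps represent
  compensated, averaged recordings; channel noise is summarized by additive
  Gaussian current noise.

Voltages live in two frames. Protocol builders accept the *membrane* frame
(holding −87 mV), the frame in which results are quoted; recordings store
amplifier command voltages, which are 17 mV more positive (the liquid
junction potential). The analysis chain therefore really performs the
offline LJP correction (`ljp_correct()`), as an analyst would.

The IV procedure (`extract_iv()`) averages, per step, the most-inward
sliding window of 5 ms fully inside the depolarization ("maximal activation
region"); ties go to the earliest window, and the window is half-open so the
sample at the step→holding transition is never included. `fit_activation()`
fits the gated-conductance model plus a constant offset. The offset needs a
word: selecting the most-inward window is an extreme-value operation on the
window noise, which leaves a small negative pedestal (≈ −2 pA at 5 pA
noise) at *every* voltage, including ones where the channel is shut.
Without the offset this pedestal masquerades as shallow activation and
biases the fitted $k$ upward by more than the cohort SEM; with it, noiseless
recovery is exact to numerical precision and noisy recovery is unbiased.
Initialisation is fixed for determinism: $V_{rev}$ at +45 mV, $V_{half}$
from the half-maximal crossing of the directly normalized conductance
$I/(V-45)$, $k$ at 7 mV, offset at 0.

Quality control (`qc_recording()`) encodes the inclusion rules for both
recording modes: ruptured-patch recordings require series resistance
≤ 14 MΩ, holding leak ≤ 50 pA in magnitude and rundown ≤ 25%;
perforated-patch recordings require leak < 30 pA and series resistance
< 30 MΩ.

## Exocytosis: ΔC~m~, Q~Ca~ and the admittance inversion

The capacitance generator uses a two-component vesicle-pool model: a
readily releasable pool depleting exponentially
($RRP\,(1 - e^{-t/\tau})$, defaults 20 fF and τ = 10 ms) plus a linear
sustained component (0.25 fF/ms) that switches on at 20 ms, the
conventional boundary between fast and sustained exocytosis. Capacitance is
not tracked during the pulse (samples are NA), mirroring sine-wave
measurements. `compute_delta_cm()` subtracts the mean over the 400 ms
before the pulse from the mean over 400 ms starting 100 ms after it; the
skip avoids the period where conductance transients corrupt the
capacitance estimate in real recordings. `compute_qca()` integrates the
leak-subtracted current by the trapezoidal rule (error-controlled, exact
for the piecewise-constant pulses used here) and reports pC.

`estimate_cm_from_admittance()` inverts the three-element circuit
analytically. With $A = \mathrm{Re}(Y) - G_t$ and $B = \mathrm{Im}(Y)$:
$G_s = (A^2+B^2)/A + G_t$, $G_s + G_m = G_s^2 A/(A^2+B^2)$ and
$C_m = (G_s+G_m)\,A/(\omega B)$. The inversion is the exact inverse of the
forward admittance on physical inputs and refuses inconsistent ones
($B \le 0$ or $\mathrm{Re}(Y) \le G_t$).

## Single-active-zone fluorescence–voltage analysis

The generator couples the channel model to a saturating indicator.
Per frame, the spot-center calcium is
$c(t) = c_{rest} + \alpha\,\max(0, -I_{Ca}(V(t)))$ — influx only; beyond
the reversal potential the drive is zero, not the absolute value of an
outward current. The spatial profile is an isotropic Gaussian (σ = 2 px)
on a resting-calcium cell disc over a darker extracellular background, and
pixel fluorescence follows the hyperbolic indicator law
$F = F_{min} + (F_{max}-F_{min})\,c/(c+K_D)$ with $K_D = 10$ µM. The scale
α is set so the peak spot-center calcium is 1 µM by default: a low-affinity
indicator run at a tenth of its $K_D$ stays near-linear, which is exactly
why such dyes are chosen for this measurement. Ten baseline frames precede
the ramp; frames are instantaneous samples at their midpoints, the same
convention the analysis uses to assign voltages.

The analysis chain:

1. `delta_f_image()` — mean of the 5 stimulation frames whose command
   voltage is nearest the expected peak-drive voltage (−17 mV) minus the
   baseline mean.
2. `select_hotspot()` — strongest 3×3-smoothed ΔF across candidate planes,
   earliest plane on exact ties.
3. `extract_trace()` — 3×3 average around the center; background is the
   mean over a 60×60 px block placed automatically on the *darkest* region
   of the baseline image. Darkness, not small |ΔF|, is the criterion:
   blocks inside the cell also show ≈ 0 ΔF, and noise could select
   different blocks for the two interleaved movies, scaling their ΔF/F₀
   inconsistently and distorting the merged FV curve. One block per
   recording is reused for both movies.
4. `build_fv()` — frames of both ramps are assigned LJP-corrected command
   voltages at their midpoints and merged; for the standard protocol
   (1 mV/ms, 10 ms frames, 5 ms shift) the merged grid spacing is exactly
   5 mV.
5. `fit_fv()` — staged: (i) a modified Boltzmann, line × sigmoid + offset,
   fitted only up to the first post-peak return of ΔF/F₀ to ≤ 2% of its
   maximum (beyond the reversal there is no influx, and the model cannot
   represent a curve clamped at zero — fitting through that segment shifts
   $V_{half}$ by about +1 mV); (ii) the "G~max~ line" fitted to the
   descending limb starting 15 mV above the FV peak — at the peak itself
   channels are still ≈ 10% short of full activation, and including those
   points tilts the line and biases $V_{half}$ by ≈ −0.8 mV; (iii) the
   ratio FV-fit / line over the pre-reversal range, clipped against
   numerical noise; (iv) a Boltzmann fit of the ratio with the amplitude
   free near 1, so residual line miscalibration lands in the amplitude
   rather than in $V_{half}$. Both window choices are exposed as arguments
   (`limb_offset`, `gmax_margin`).

`dff_max()` averages the 5 consecutive stimulation points centered on the
ΔF/F₀ maximum — deliberately an average, not the instantaneous peak,
matching how maximal Ca^2+^ influx is conventionally reported.

## Puncta segmentation and juxtaposition

The generator rasterizes hard-sphere puncta with log-normal volumes
(defaults: ribbon-like channel 0.16 µm³ mean / 0.09 µm³ SD; PSD-like
channel 0.36 / 0.16 µm³) at confocal-like voxels (0.1 × 0.1 × 0.2 µm), a
Bernoulli fraction of channel-A puncta receiving a partner displaced by
0.35 µm and the remaining B puncta placed at least 1.5 µm from any A
punctum. Same-channel puncta keep ≥ 1.4 µm center separation — synaptic
puncta on an IHC are sparse at this scale.

`segment_puncta()` re-expresses surface-based commercial quantification as
an open pipeline: Gaussian smoothing at 0.07 µm (surface detail), a
background estimate by large-kernel smoothing at 0.562 µm, a global
threshold at mean + 4 SD of the background-subtracted stack, 26-connected
components, and marker-based splitting: local maxima of a field smoothed at
a third of the 0.4 µm split distance, merged when closer than the split
distance *or* when the intensity profile between two maxima shows no
saddle deeper than 15% (plateau noise produces nearby maxima without a
saddle; genuinely touching puncta produce one). Voxels of split components
are assigned to the nearest marker — a watershed surrogate that is
adequate for compact, convex puncta.

Volumes are refined on the unsmoothed background-subtracted stack by
counting voxels above half the object's peak. This choice is deliberate:
a global noise threshold applied to smoothed data places the object
boundary at a fixed *absolute* level, which for a blurred hard-edged object
sits well below half-maximum and inflates radii by a blur-dependent
amount; the half-maximum criterion locates the edge of a symmetric blur
unbiasedly. The detection threshold still controls *what* is found;
half-maximum only controls *how big* it is measured to be. Setting
`refine = "threshold"` reverts to counting detection-mask voxels.

`pair_juxtaposed()` matches channels greedily by ascending centroid
distance, one-to-one, with a 0.8 µm default cutoff — the paper-scale
distance between a ribbon centroid and the centroid of its apposed PSD.
Greedy matching is deterministic and, for the sparse geometries generated
here, agrees with optimal assignment.

## ABR threshold detection

The generator emits one averaged waveform per level (0–120 dB in 5 dB
steps): noise below threshold, and from threshold upward a stereotyped
damped wave complex in the 3–9 ms window growing linearly at 1 µV/dB.
`detect_threshold()` replaces the human "clearly recognizable potential"
call with a surrogate: waveforms are smoothed with a 1.5 ms moving average,
the noise SD is estimated from the raw pre-stimulus window of the
lowest-level trace and scaled by the smoothing factor (the sample SD of the
smoothed short window itself is biased low by autocorrelation), and a level
is detectable when its response-window peak-to-peak exceeds 6× that SD.
The threshold is the lowest level from which detection is sustained to the
top level, which suppresses isolated noise crossings.

The 6× default deserves its rationale: a peak-to-peak over a window is an
extreme-value statistic whose *noise-only* expectation is ≈ 3.5 smoothed
SDs here, with a 99th percentile near 6. A criterion of 4 SD — a natural
first guess — sits inside the noise distribution and false-triggers on
about half of all silent levels; 6 SD keeps false detections near 1% while
remaining far below the at-threshold signal. The criterion, windows and
smoothing are all user-settable, and raising the criterion can only raise
the detected threshold (monotonicity).

## Statistical decision procedure

`select_two_sample_test()` reproduces the gated test choice: Jarque–Bera
normality on each sample (the classic moment form,
$JB = n/6\,(S^2 + (K-3)^2/4)$ against $\chi^2_2$) and a two-tailed F-test
on the variance ratio, all at α = 0.05; Student's t (pooled variance — the
gate has already required variance equality) iff all three gates pass,
Mann–Whitney–Wilcoxon otherwise (exact for small tie-free samples, the
tie-corrected continuity-corrected normal approximation otherwise).
`kruskal_dunn()` provides the ≥ 3-group path: tie-corrected Kruskal–Wallis
plus Dunn's pairwise z statistics on pooled ranks with Holm adjustment by
default (Bonferroni and Šidák are options; the choice of correction is not
standardized in the field, and Holm dominates Bonferroni uniformly).
Summaries print as `mean ± SEM, SD, n`.

## What the generators emulate — and what they do not

The generators are designed so that every analysis stage has a well-defined
ground truth, at realistic magnitudes: ~200 pA peak calcium currents, fF
capacitance jumps on an 8 pF cell, ΔF/F₀ of order 1 on a 10 µM-K_D
indicator, sub-µm³ puncta at confocal voxel sizes, µV-scale ABR waves.
They do **not** emulate: series-resistance and space-clamp errors, GHK
rectification, stochastic channel gating, dye bleaching or diffusion,
microscope PSF anisotropy beyond the Gaussian spot, tissue autofluorescence
gradients, multi-hotspot interference, or cell-to-cell correlations beyond
the stated parameter draws. Passing recovery tests therefore demonstrates
the *analysis* is unbiased and correctly scaled under the stated noise
model — not that it is robust to every artefact of real recordings.

## Problem sizes and numerical conventions

Recovery suites run at the study's group sizes (14 and 25 cells for
whole-cell cohorts, 50 and 69 active zones, ~300 puncta over 13–14 cells,
200 ABR series, 1000 sample pairs for the statistics oracle) — sizes chosen
so every suite completes in minutes on a single core while keeping SEM-level
tolerances meaningful. Degenerate inputs fail loudly and specifically:
flat IVs, flat FV curves, zero baselines, overlapping background blocks,
non-positive capacitive admittance and overlapping ROIs all raise errors
naming the problem. Ties are broken deterministically (earliest window,
earliest plane, first-listed marker), all fits use fixed documented starts,
and every generator accepts a single integer seed that makes its output
bit-reproducible.

## Known limitations

* Fractional activation is tied to the linear driving-force model; a
  strongly rectifying current would bias $g_{max}$ and, mildly, $k$.
* The FV pipeline assumes one hotspot per movie; overlapping active zones
  are out of scope.
* Half-maximum volume refinement assumes compact objects with a single
  dominant intensity plateau; hollow or strongly lobed structures would be
  under-measured.
* The ABR detector is a fixed-criterion surrogate for trained human raters;
  agreement with human calls cannot be established from synthetic data.
* Cells within an animal are treated as independent (no mixed-effects
  modelling), matching the convention of pooling cells across animals.
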