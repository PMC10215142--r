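---
title: "Contactless SpO2 by ratio-of-ratios rPPG: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contactless SpO2 by ratio-of-ratios rPPG: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spo2cam)
```

## The measurement model

Pulse oximetry rests on the different absorption of oxygenated and
deoxygenated hemoglobin across wavelengths. In the camera-based (remote
photoplethysmography) setting, each channel of the video signal over a
skin patch is modeled as a quasi-static reflectance level (DC) plus a
small pulsatile modulation (AC) at the cardiac frequency. The quantity

$$R = \frac{AC_{red}/DC_{red}}{AC_{blue}/DC_{blue}}$$

is a wavelength contrast of relative pulsatile amplitude. Red absorption
differs strongly between the two hemoglobin species while blue is
comparatively insensitive, so $R$ falls as saturation rises, and over the
physiological range a linear calibration

$$\mathrm{SpO_2} = A - B \cdot R$$

suffices; the package's reference coefficients are $A = 125$, $B = 28$,
giving $\mathrm{SpO_2} = 97$ at $R = 1$. An earlier red/blue formula with
an *additive* slope, $\mathrm{SpO_2} = 97.61 + 0.42\,R$, is provided as a
comparison model: for $R \ge 0$ it can never output below its intercept,
so it cannot report desaturation — the package reproduces this floor
analytically.

Assumptions inherited from the model: a still subject (no motion
compensation), a forehead patch large enough that pixel averaging
suppresses sensor noise, illumination that varies at most slowly over the
measurement, and a cardiac rate inside the filter passband.

### Estimation procedure

`estimate_stream()` implements the session measurement:

1. Both channel series are bandpass filtered (zero-phase).
2. A window slides over the aligned series; per window, AC is the
   **population** standard deviation (divide by $N$) of the *filtered*
   samples and DC is the mean of the *raw* samples.
3. Each window's $R$ is calibrated to SpO2 and clamped to $[0, 100]$.
4. The session summary is the **median** of window estimates, and a triage
   label is attached.

AC from the filtered window and DC from the raw window is the single most
consequential pairing in the pipeline, and deliberate: the bandpass
removes the mean that the denominator of $AC/DC$ requires, so the DC
pathway must bypass the filter. Computing DC from the filtered signal
would divide by numbers near zero and is never done.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| passband | 0.7–4.0 | Hz | 42–240 bpm, the standard rPPG cardiac band; generous enough for rest and mild tachycardia |
| filter order | 4 | – | Butterworth, steep enough to kill respiratory/illumination drift below 0.7 Hz without ringing |
| window | 100 | samples | ≈ 3.3 s at 30 fps: several cardiac cycles, short enough to yield ~15 windows in a 30 s session |
| hop | window/2 | samples | 50 % overlap; halves variance of the median without correlating windows completely |
| edge exclusion | 1 | s | forward–backward filtering has edge transients; windows never touch the first or last second |
| calibration | A = 125, B = 28 | % , %/R | the reference subtractive fit; both coefficients refittable |
| sd type | population | – | the windowed σ divides by N; a sample-sd switch exists for sensitivity checks |
| fps fallback | 30 | Hz | assumed when a source carries no timing; always overridden by source metadata when present |

Triage bands are ≥ 95 normal, 91–94 monitor, ≤ 90 emergency. The printed
bands leave the open intervals (90, 91) and (94, 95) unassigned for
non-integer values; the package assigns them to the more severe neighbor
(safety-first), so 90.5 is an emergency and 94.5 is monitor.

## Numerical choices

- **Mean subtraction before filtering.** `signal::filtfilt` zero-pads the
  sequence, so a series with a large DC offset (typical forehead levels
  are 100–150 bpp) would excite long edge transients. The mean is
  subtracted before filtering — the passband excludes DC anyway — which
  makes the filter exactly null on constant input and shrinks edge
  transients by two orders of magnitude. Residual transients are handled
  by the 1 s edge exclusion.
- **Pulseless windows.** A window whose blue AC falls below $10^{-6}$ bpp
  is flagged no-pulse (a classed condition, not a crash) and excluded from
  the session median; a session with no valid window raises
  `spo2_insufficient_data`.
- **Clamping.** Calibrated values outside $[0, 100]$ are clamped and
  flagged rather than erroring; the flag survives into the report.
- **Calibration fitting.** `fit_calibration()` defaults to holding
  $A = 125$ fixed and solving the one-parameter least-squares slope, which
  reproduces the reference fit's construction (slope adjusted on a small
  cohort); a full two-parameter OLS mode is available and is what the
  recovery tests exercise. The full fit refuses rank-deficient input (all
  $r$ identical).
- **HOG conventions.** Gradients are central differences with zero at the
  border; orientation is unsigned, $\theta = \mathrm{atan2}(g_y, g_x)
  \bmod 180°$, which realizes the stated folding of 181–360° onto 0–180°;
  zero vectors get angle 0 with magnitude 0. Magnitudes are split linearly
  between the two nearest of the nine bin centers (0, 20, …, 160°) with
  160↔0 wrap. Blocks are 2×2 cells of 8×8 px, stride one cell, L2
  normalization with $\epsilon = 10^{-12}$; an all-zero block stays zero.
  Gamma preprocessing (exponent configurable, e.g. 0.5) exists but is off
  by default, since no principled exponent is established.
- **ROI rasterization.** The forehead mask is the convex hull of the 13
  forehead landmarks, rasterized by pixel-center inclusion with a
  half-open rule: an axis-aligned $w \times h$ rectangle covers exactly
  $w h$ pixels, and shared edges never double-count. Collinear landmarks
  or a hull entirely outside the frame raise a degenerate-ROI error.
- **Landmark indexing.** Full-face sets have 81 points stored 0-based
  (0–80) with the forehead block at 68–80; published descriptions of the
  same layout mix 1-based ranges inconsistently, so the package documents
  its convention once and applies it everywhere.
- **Detection gaps.** A frame with no detected face inherits the last
  valid landmarks for up to one second (still-subject assumption); longer
  gaps mark samples invalid, and any window touching them is skipped.

## The synthetic generator

`synth_series()` realizes exactly the signal model the estimator assumes:

$$x_c(t) = k\,[DC_c + AC_c \cdot w(2\pi f_{hr} t)] + \varepsilon_c(t)$$

with $w$ a unit sinusoid (optionally a two-harmonic, dicrotic-like pulse),
$k$ a global illumination scale, and $\varepsilon$ white Gaussian noise.
The blue amplitude is fixed and the red amplitude is solved from the
target ratio, which is itself obtained by inverting the calibration line
at the requested ground-truth SpO2 — so the analytic $(AC/DC)$ ratio of
the generated series equals the target exactly, before noise and
quantization. `synth_frames()` renders the same waveforms into uniform
skin patches of an image sequence with fixture landmarks tracing the
patch, exercising the full detection/masking/extraction path; 8-bit
quantization is optional.

Defaults, chosen once as a realistic resting measurement: 30 s at 30 fps,
72 bpm, DC 150 bpp (red) and 100 bpp (blue), blue AC 1 bpp (≈ 1 %
perfusion modulation), noiseless, unquantized.

What the generator does **not** emulate: pulse-shape variability and
heart-rate drift, motion and ballistocardiographic artifacts, spatially
inhomogeneous and time-varying illumination, sensor gamma/white-balance
nonlinearity, compression noise, and skin-tone optics. Passing tests
therefore certify the *algebra and signal processing* of the pipeline —
recovery under the model's own assumptions, illumination invariance,
filter behavior — not clinical accuracy on real faces, which requires
human validation data.

## Problem sizes in the test suite

The suite runs synthetic sessions of 12–30 s at 30 fps (360–900 samples),
frames of 60×80 px, cohorts of 6 subjects, 1000-window statistics oracles,
and a 200-replicate slope-recovery simulation; these sizes were chosen so
the full suite exercises every path in well under a minute while keeping
the Monte-Carlo assertions stable across seeds.

## Known limitations

- The calibration coefficients are taken from a small-cohort fit over a
  narrow, mostly-healthy saturation range (roughly 94–99 %); extrapolation
  to deep desaturation is linear-by-assumption and unvalidated.
- The packaged validation readings are the 30 printed pairs of a larger
  60-point study; the full-study mean absolute error of 0.62 % is
  therefore *not* recomputable from shipped data and is never asserted —
  the suite checks that the printed subset's MAE (0.467 %) does not exceed
  it, and that the printed maximum error of 2 % is attained.
- No video container decoding is bundled: frame sequences enter as
  in-memory arrays (the frame-iterator contract) or as channel-series CSV;
  real camera capture and face detection plug in through the landmark
  backend interface.
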