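---
title: "Oscillometric blood pressure from a pinhole projection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oscillometric blood pressure from a pinhole projection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pinholebp)
```

## The measurement chain

The device is a finger clip: a circular contact of diameter 10 mm presses
on the fingertip, backed by a compression spring (stiffness 0.49 N/mm,
preload 0.1 N, 6.7 mm travel). A pinhole rides on the pressing platform, so
its projection on the camera sensor grows as the spring compresses. The
applied contact pressure is

$$ P = \frac{F}{\pi (d/2)^2}, \qquad F = F_0 + k\,x, $$

converted at 133.322 Pa/mmHg; internally all lengths are mm, forces N,
pressures mmHg. With the defaults the reachable pressure runs from about
9.5 mmHg (below any diastolic pressure of interest) to about 315 mmHg
(above any systolic pressure of interest), which is what makes a full
oscillometric sweep possible. The upper force is quoted as 3.3 N in device
descriptions; the model keeps full precision ($0.1 + 0.49\times6.7 =
3.383$ N) and treats 3.3 N as a rounded display value.

Per frame, the app computes three quantities, mirrored by the `imaging`
functions:

* `equalize_histogram()` — global 8-bit CDF remapping
  $v \mapsto \mathrm{round}\big(255\,(\mathrm{cdf}(v)-\mathrm{cdf}_{\min})/
  (n-\mathrm{cdf}_{\min})\big)$, applied **only** before area detection to
  remove between-subject brightness differences;
* `detect_projection_area()` — count of pixels strictly above grey
  level 20; diameter $d = 2\sqrt{A/\pi}$;
* `extract_ppg_sample()` — mean of **raw** pixels in the closed band
  [20, 254] (background below, saturation above). The written description
  of the app is ambiguous about whether the PPG mean uses the equalized or
  raw image and whether the band bounds are inclusive; we fix *raw* and
  *closed interval* and document them as constants.

Force is expressed on a proportional 0–100 % scale calibrated per session
from the disc size at rest (0 %) and fully pressed (100 %); the scale is
taken linear in *diameter* (the description says only "circle size"). The
plotted force signal is low-pass filtered at 0.4 Hz — below the slowest
plausible heart rate (36 beats/min = 0.6 Hz) — to strip the cardiac
artifact.

## Guidance protocol

Twenty targets equally divide 5–95 % of the force scale, endpoints
inclusive. The state machine is RED until the force enters the
±2-percentage-point band (YELLOW), GREEN after 2 s continuously in band,
and the level completes after 5 s more; any out-of-band sample in
YELLOW/GREEN discards the attempt. "Movement detection" is modelled as
exactly this band violation — it is the only concrete signal the app
description defines. Completion is evaluated from elapsed time *before*
the band test, so a level completes at $t_{\text{yellow}} + 7$ s even if
the user has already moved toward the next target; recorded windows are
half-open, giving exactly `record_s × frame_rate` samples per level.

Session time is reported as accumulated in-band time: each completed level
contributes exactly 7 s and each discarded attempt the time from band
entry to the violation. An ideal user therefore takes exactly
$20 \times 7 = 140$ s, and a single violation 1 s into GREEN adds exactly
3 s, independent of the sampling grid. Wall-clock time (including
between-level transitions) is reported separately. The 0 %/100 %
calibration is replayed at session start and excluded from the 140 s
figure. A restart repeats only the current level.

## Forward model (synthetic data)

A virtual subject carries true SBP/DBP (hence MBP = SBP/3 + 2·DBP/3),
heart rate, a perfusion gain, an envelope width, and a baseline disc
brightness. The pulse-amplitude envelope is

$$ A(P) \;=\; g \cdot \exp\!\left(-\frac{(P-\mathrm{MBP})^2}{2w^2}\right)
   \cdot s\!\left(\frac{\mathrm{SBP}-P}{\tau}\right), $$

a Gaussian centred at MBP — the standard first-order shape of
oscillometric envelopes — multiplied by a smoothstep $s$ that falls to
exactly zero at SBP over a taper $\tau$ = 10 mmHg: above systolic pressure
the artery is occluded and the projection stops pulsing. The Gaussian form
and the taper are modelling choices; the source system documents only the
qualitative shape (unimodal envelope, collapse above SBP). The PPG
waveform is a raised cosine with unit peak-to-trough span (period
60/HR s); a second-harmonic dicrotic term is available and off by default.

Frames are rendered as a centred disc whose diameter is linear in
compression between `d_min` and `d_max` (the description says only that
the projection grows as the pinhole nears the camera), filled with
`skin_baseline − A(P)·w(phase)`, over a dim background (< 20), plus
i.i.d. Gaussian pixel noise (default sd 2 grey levels), rounded and
clipped to 8 bits. Defaults: 128×128 px, 30 fps (any rate above 20 fps is
supported; neither is specified by the source system).

Two renderings of a session are provided. `mode = "frames"` produces the
full 8-bit stacks and is what the imaging tests and the screening
acceptance run consume. `mode = "signal"` produces the *extracted
equivalent* directly: the in-disc mean of a uniform disc with per-pixel
noise sd $\sigma$ is the clean PPG value plus noise of sd
$\sigma/\sqrt{n_{\text{px}}}$, so the signal mode is distributionally
identical to running the extractor on rendered frames, at a fraction of
the cost. Cohort-scale analyses use it.

Two effects of the frame path are worth knowing. First, with a noisy
background, global equalization lifts part of the background above the
detection threshold; the measured area is then offset but remains strictly
monotone in the true disc size, and the proportional 0 %/100 % calibration
absorbs the offset — noiseless frames map the background exactly to 0.
Second, a noiseless *uniform* disc quantizes the PPG to whole grey levels,
which distorts small pulse amplitudes; realistic sensor noise dithers this
away (the disc mean then tracks the clean waveform to well under a grey
level). Amplitude-fidelity checks therefore run at the default noise.

### Cohort population

Reference pressures are drawn as correlated Gaussians — SBP
$\mathcal N(116.8, 20.3^2)$, DBP $\mathcal N(73.5, 12.3^2)$, correlation
0.6 — matching the summary statistics of the validation cohort the method
was designed for, with rejection outside SBP [85, 175], DBP [45, 110] and
pulse pressure [25, 80] mmHg (below 25 is non-physiological; 80 is the
screening cap, so a default cohort is fully retainable). Because of the
truncation the realized population mean differs slightly from the raw
Gaussian parameter; tests compare cohort means against an independent
Monte Carlo reference of the same truncated population. Heart rate is
$\mathcal N(70, 10^2)$ on [45, 110] beats/min; perfusion gain
$\mathcal N(10, 3^2)$ on [4, 20] grey levels; envelope width
$\mathcal N(20, 2.5^2)$ on [12, 30] mmHg; baseline brightness
$\mathcal N(180, 15^2)$ on [120, 220]. All values were fixed once, on
physiological plausibility. Forced screening cases (pulseless: gain 0.2;
high pulse pressure: 82–95 mmHg) can be injected in controlled numbers.

## Oscillogram construction

Each level's 5-s PPG window is band-pass filtered at 0.5–10 Hz with a
zero-phase forward–backward Butterworth design (order 2 per direction; the
source names only the band). The series mean is removed first and the ends
are odd-reflection padded before filtering, so the long settling transient
of the 0.5 Hz corner decays in the padding rather than inside the short
window — without this, edge pulses are visibly attenuated.

Pulse peaks are detected with a topographic-prominence floor of 0.5 grey
levels and a minimum spacing of 1/3 s (180 beats/min ceiling); neither is
specified by the source, and both are arguments. A pulse is *complete*
when its peak lies at least a quarter period (median peak spacing) from
both window ends — cycles truncated by the window, where the filter is
also least trustworthy, are excluded; a 5-s window yields roughly 3–7
complete pulses across 36–84 beats/min. Each pulse's amplitude is its peak
height above the mean of its genuine (interior) flanking troughs, falling
back to the single interior trough when the other side is cut off. The
per-level average gives one oscillogram point; a level with no complete
pulse is flagged and contributes amplitude 0.

The two endpoint levels are excluded (at the lowest force the finger can
leave the clip; at the highest the spring bottoms out) and the remaining
18 amplitudes are min–max rescaled to [0, 1]; "normalize between 1 and 0"
admits a divide-by-max reading, available as `method = "maxdiv"`. A flat
oscillogram is a normalization error. Screening excludes subjects whose
raw oscillogram maximum is below 1 grey level (no usable pulse; the floor
is configurable) or whose reference pulse pressure exceeds 80 mmHg.

## Estimator

Stage 1 fits two independent single-target LASSO models (SBP, MBP) on the
18 features — the simplest reading of the description; a shared-penalty
multi-target variant sits behind `multi_target = TRUE`. The penalty is
chosen by 5-fold inner cross-validation on the training fold only, over
glmnet's default logarithmic path; features keep their common [0, 1] scale
(no re-standardization). Stage 2 is OLS of DBP on exactly
(\widehat{SBP}, \widehat{MBP}); with perfect stage-1 predictions it
recovers the identity DBP = 1.5·MBP − 0.5·SBP implied by the MBP formula.
Stage-2 training inputs are the stage-1 predictions for the same training
fold (no nested holdout; the source is silent on this). A wholly
zero-variance feature matrix falls back to an intercept-only model with a
warning rather than an error, so degenerate cohorts still validate.

Leave-two-subjects-out folds are formed by sorting the roster, permuting
it under a seed, and splitting into consecutive pairs; an odd roster is an
error requiring an explicit user decision. Agreement is summarized per
target as MAE ± sd of absolute errors, bias (mean of prediction −
reference), Bland–Altman limits bias ± 1.96·sd(error), and Pearson
correlation, over held-out predictions only.

## Problem sizes and what the tests show

The packaged analyses use a 60-subject signal-mode cohort (seed 7) for
parameter recovery — cross-validated SBP MAE below 8 mmHg and DBP MAE
below 6 mmHg — and a 29-subject frame-mode cohort at desk-scale optics
(48×48 px, diameters 12–44 px) with four forced pulseless subjects and one
forced high-pulse-pressure subject for the screening count (24 retained).
Imaging checks run at 32–64 px frames. These sizes keep the full suite in
the minutes range on one core.

Passing tests demonstrate internal consistency: the pipeline recovers the
parameters of its own forward model under the stated noise. They do not
demonstrate accuracy on real fingers — the generator has no motion
artifact beyond force-band violations, no skin-tone or ambient-light
optics, no beat-to-beat variability, and its Gaussian envelope is an
idealization — so measured-cohort error statistics cannot be inferred from
the synthetic ones.

## Numerical notes and limitations

* Filters require the sampling rate to exceed twice the upper band edge
  (> 20 Hz for the 0.5–10 Hz band); series shorter than the low-pass
  warm-up pass through with a warning.
* Histogram equalization of a constant frame is the identity; a constant
  PPG window band-passes to exactly zero and is flagged pulseless.
* Force-scale values are clipped to a diagnostic range [−10, 110] %; a
  degenerate size calibration (0 % size ≥ 100 % size) is an error.
* Ties in peak spacing pruning resolve in favour of the taller peak;
  plateau maxima count once at the plateau start.
* All randomness flows through explicit integer seeds; sessions, cohorts
  and cross-validation are bit-reproducible for a fixed seed, and the
  caller's RNG state is always restored.
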