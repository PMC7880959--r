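---
title: "Classifying eye-movement events with adaptive velocity thresholds"
author: "gazevents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying eye-movement events with adaptive velocity thresholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazevents)
```

## The problem and the model

Gaze recordings from video-based eye trackers are dense coordinate time
series: one X/Y screen position in pixels per sample, at a fixed rate
(this package is exercised at 500 and 1000 Hz). Analyses almost always
operate on *events* instead: fixations (stable gaze for visual intake),
saccades (rapid ballistic shifts), post-saccadic oscillations (brief ocular
instability right after a saccade, also called glissades), and smooth
pursuit (slow tracking of a moving target). `gazevents` implements a
velocity-based classifier: all decisions are made on the per-sample angular
speed

$$v_i = \mathrm{px2deg} \cdot f_s \cdot
        \sqrt{(x_i - x_{i-1})^2 + (y_i - y_{i-1})^2},$$

where `px2deg` converts one (square) pixel to degrees of visual angle and
$f_s$ is the sampling rate. The forward difference is assigned to the later
sample; sample 1 is masked.

The core difficulty is choosing the saccade velocity threshold. Fixed
thresholds fail across devices, participants and noise levels, so the
threshold is estimated from the data by a robust iteration: starting from a
start value $PT_0$ chosen above any plausible saccade onset velocity
(`velthresh_startvelocity`, 300 deg/s), each step takes the velocities $V$
strictly below the current threshold and sets

$$PT_n = \mathrm{median}(V_{n-1}) + F \cdot \mathrm{MAD}(V_{n-1}),$$

stopping when $|PT_n - PT_{n-1}| < 1$ deg/s (a fixed named constant, not a
parameter). Two deliberate choices here:

* **Raw MAD.** The MAD carries no 1.4826 normality rescaling. Velocity
  distributions during fixation are strongly skewed, which is the reason for
  replacing the classical mean/SD update in the first place; the
  `noise_factor` default of 5 is calibrated against the raw MAD. Users
  porting thresholds from mean/SD formulations should expect roughly
  `noise_factor ≈ 1.48 × (SD multiplier)`.
* **Termination on degenerate data.** If the sub-threshold set becomes
  empty or stops changing between iterations, the last computed threshold
  and its context statistics are returned (constant velocity $v$ yields
  $PT = \mathrm{median} = v$, $\mathrm{MAD} = 0$). A hard cap of 1000
  iterations guards against pathological oscillation and warns.

From the converged context the event thresholds derive as
$\theta_\mathrm{onset} = \mathrm{median} + F\cdot\mathrm{MAD}$ and
$\theta_\mathrm{peak} = \mathrm{median} + 2F\cdot\mathrm{MAD}$: candidate
saccades must peak above $\theta_\mathrm{peak}$; their boundaries are the
nearest local velocity minima at or below $\theta_\mathrm{onset}$.

## Preprocessing

Applied strictly in order:

1. **Spike filter.** A sample that is a strict local extremum on one axis,
   farther from each neighbor than the neighbors are from each other, is
   replaced by the nearer neighbor's value. This removes single-sample
   tracker glitches; two-sample excursions are left alone. The rule is
   isolated in `filter_spikes()` so variants can be swapped.
2. **Signal-loss dilation.** Blinks produce artifacts while the eyelid
   closes and re-opens. Every missing-data run of at least
   `min_blink_duration` (0.02 s) is widened by `dilate_nan` (0.01 s) on both
   sides. Internally, true loss windows are `NaN` and dilation margins plain
   `NA`; both count as missing everywhere downstream, but margins never
   re-qualify as loss windows, which makes dilation idempotent.
3. **Two smoothing branches.** A comparatively long running median
   (`median_filter_length`, 0.05 s) suppresses noise and small movements
   while preserving the position steps of large saccades — this *chunking
   stream* is used only to locate major saccades. A Savitzky–Golay filter
   (`savgol_length` 0.019 s, order 2) produces the *classification stream*
   on which all event decisions are made. Smoothing windows that touch a
   missing sample propagate the missing marker: the package never fabricates
   gaze during a blink.
4. **Velocity and clamping.** Velocities above `max_vel` (1000 deg/s) are
   biologically implausible; they are clamped with a warning, since their
   presence usually signals filter settings inappropriate for the noise at
   hand.

Durations convert to sample counts by `round(duration × fs)`; filter windows
are forced odd (one sample added when even) so smoothing stays symmetric and
phase-free. Velocities for the chunking stream are computed *after* median
filtering the coordinates, mirroring the threshold determination on a
median-filtered series.

## Chunking and event classification

Noise in prolonged recordings is not stationary, so no threshold is ever
used globally. One global robust estimate on the chunking stream — where it
deliberately overestimates, so only the fastest movements exceed it — yields
candidate runs of consecutive above-threshold samples. (The applied cut-off
is the derived *peak* threshold: of the two derived thresholds it is the
one consistent with selecting only the fastest movements.) Runs are weighted by their velocity sum and accepted greedily in
descending weight (ties: earlier run) until accepting another would push the
average rate over the whole recording — masked time included — beyond
`max_initial_saccade_freq` (2 Hz, below natural free-viewing saccade rates).
The accepted runs' peak samples become chunk boundaries.

Each accepted peak is re-examined on the classification stream with
thresholds estimated from a `saccade_context_window_length` (1 s) window
centered on it; if it survives ($v_\mathrm{peak} \ge \theta_\mathrm{peak}$,
duration $\ge$ `min_saccade_duration`, clear of the previous event by
`min_intersaccade_duration`) it becomes a chunk-boundary saccade `SACC`.
Intersaccadic segments are then searched for intra-chunk saccades (`ISAC`)
with thresholds from the whole segment; windows shorter than
2 × `min_intersaccade_duration` + `min_saccade_duration` +
`max_pso_duration` are not searched at all. Boundary refinement walks
outward from the peak: once velocity first reaches the onset threshold the
walk continues while it keeps strictly decreasing, so intermediate minima
that stay *above* the threshold (merged double peaks) are skipped. The walk
never crosses masked samples; bounds clamped at a context edge are flagged.

**PSOs.** If velocity re-exceeds $\theta_\mathrm{onset}$ within
`max_pso_duration` (0.04 s) of a saccade offset, a PSO is classified from
the saccade offset onward, labeled high-velocity (`HPSO`/`IHPS`) if it also
exceeds $\theta_\mathrm{peak}$, low-velocity (`LPSO`/`ILPS`) otherwise. The
thresholds are the parent saccade's — the oscillation is part of the same
kinematic episode, and re-estimating on a tiny window would be unstable.
One genuinely open detail is which excursion anchors the offset search: a
damped oscillation crosses zero velocity between its lobes, and walking
from the *global* peak would cut the event at the first inter-lobe minimum,
pushing the return phase into the following fixation. `gazevents` anchors
the offset walk at the *last* above-threshold excursion inside the window:
the oscillation lasts until it settles. The event never outlasts the
window.

**Pursuit vs. fixation.** Remaining unlabeled stretches of at least
`min_fixation_duration` (0.04 s) are low-pass filtered with a zero-phase
(forward–backward) Butterworth filter, order 2, cutoff
`lowpass_cutoff_freq` (4 Hz) — zero-phase so event timing is preserved; the
order is the mildest common choice given that only the cutoff is prescribed.
Runs exceeding `pursuit_velthresh` (2 deg/s, above natural ocular drift) are
extended to their local minima (same walk as saccades, confined to the
stretch) and become `PURS` if at least `min_pursuit_duration` long; all
residual stretches of at least `min_fixation_duration` become `FIXA`.
Duration minima are enforced after boundary refinement. Stretches too short
for stable zero-phase filtering (≤ 18 samples) fall back to unfiltered
velocities with a warning.

Events own inclusive sample ranges; onset time is $(i_\mathrm{on}-1)/f_s$
and offset time $i_\mathrm{off}/f_s$, so abutting events share a boundary
instant without overlapping, and a PSO's onset time equals its saccade's
offset time exactly. Every event row carries onset/offset coordinates from
the smoothed trace, amplitude (straight-line distance × `px2deg`), and
peak/median/mean velocity over finite in-event samples.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `px2deg` | — | deg/px | viewing-geometry conversion; mandatory |
| `sampling_rate` | — | Hz | dense fixed-rate input; mandatory |
| `noise_factor` | 5 | — | MAD multiplier; raise on noisy data to cut false positives |
| `velthresh_startvelocity` | 300 | deg/s | must exceed any plausible minimum saccade velocity |
| `max_initial_saccade_freq` | 2 | Hz | caps greedy chunking; below natural saccade rates |
| `saccade_context_window_length` | 1 | s | threshold context for chunk-boundary saccades |
| `min_saccade_duration` | 0.01 | s | rejects supra-threshold blips |
| `max_pso_duration` | 0.04 | s | oscillations must start within this window |
| `min_fixation_duration`, `min_pursuit_duration` | 0.04 | s | minimum reportable events |
| `min_intersaccade_duration` | 0.04 | s | saccade proximity rule and search-window gate |
| `lowpass_cutoff_freq` | 4 | Hz | isolates drift velocities for the pursuit decision |
| `pursuit_velthresh` | 2 | deg/s | above natural fixational drift |
| `median_filter_length` | 0.05 | s | chunking stream; long enough to erase small events |
| `savgol_length`, `savgol_polyord` | 0.019, 2 | s, — | classification stream noise reduction |
| `min_blink_duration`, `dilate_nan` | 0.02, 0.01 | s | which gaps count as blinks, and their margins |
| `max_vel` | 1000 | deg/s | clamp for biologically implausible samples |

## The synthetic generator

`gaze_script()` + `generate_recording()` produce recordings with per-sample
ground truth; they are the package's primary test surface, so their
kinematic choices matter and are fixed here:

* **Saccades** follow the minimum-jerk displacement profile
  $x(\tau) = A(10\tau^3 - 15\tau^4 + 6\tau^5)$, the standard kinematic model
  for saccades, with zero velocity *and* zero acceleration at both ends.
  (A raised-cosine profile looks similar but has discontinuous acceleration
  at its endpoints; on near-noiseless data the Savitzky–Golay filter rings
  there at ~2–4 deg/s, above clean-context onset thresholds, creating
  spurious oscillation events.) Peak velocity obeys the main sequence
  $v_\mathrm{peak} = k A^m$ with documented defaults $k = 80$, $m = 0.6$;
  duration follows as $1.875\,A/v_\mathrm{peak}$. Scripts implying peaks
  above 1200 deg/s are rejected.
* **Fixations** drift with a two-dimensional Ornstein–Uhlenbeck velocity
  process (RMS speed `drift_vel`, default 0.8 deg/s; correlation time
  0.1 s), starting from standstill at the fixation onset — the eye has just
  stopped moving. Wandering drift is what fixational eye movements look
  like at these sampling rates, and it is what gives the adaptive threshold
  a realistic noise floor to estimate from.
* **PSOs** are one damped overshoot–return velocity cycle,
  $v(t) \propto -\sin(2\pi t/d)\,e^{-t/d}$, starting at zero velocity
  (continuous with the saccade end), scaled to a peak of
  `relative_peak_fraction` (0.06) of the parent saccade's peak velocity and
  saturated at `max_peak_vel` (12 deg/s): oscillations of the eyeball, as
  opposed to pupil-CR-inflated ones, do not scale indefinitely with saccade
  size. The saturation also keeps the saccade–PSO junction dip below
  clean-data onset thresholds — the dip's sampled depth is bounded below by
  $2\pi f\,v_\mathrm{peak}\cdot\Delta t/2$, sample quantization alone.
  Pupil-CR-like oscillations can be emulated by raising the cap.
* **Pursuits** are constant-velocity ramps; **blinks** are `NaN` windows
  flanked by three-sample eyelid excursions (~0.7 deg); coordinate noise is
  Gaussian with piecewise-constant multipliers (`noise_profile`) for
  recordings whose noise level changes over time. One private RNG stream,
  seeded from the script, makes generation deterministic and leaves the
  global RNG untouched.

Ground-truth labels use the collapsed vocabulary `FIXA`, `SACC`, `PSO`,
`PURS`, `BLINK`: whether a saccade is chunk-defining and whether an
oscillation is high- or low-velocity depend on classifier-internal
thresholds, not on generated kinematics.

**What the generator does not emulate** — and hence what green tests do not
establish about real data: microsaccades and tremor, pupil-CR PSO biases,
saccadic curvature and kinematic asymmetries, head motion, calibration
drift, sampling jitter, and device-specific noise spectra. Passing the
recovery tests shows the decision logic is correct under controlled,
physiologically shaped input, not that accuracy on any specific tracker
matches the numbers reported for hand-labeled corpora.

## Agreement metrics

The metrics module compares per-sample label sequences: misclassification
proportion (fraction of disagreeing samples over the universe where either
labeling assigns an included category — samples included by only one rater
count as disagreements, since they are in that universe; the alternative of
excluding them is a one-line change), category-wise Jaccard indices (with
the both-empty case defined as 1 and flagged), and Cohen's kappa

$$K = \frac{P_o - P_c}{1 - P_c}$$

with chance agreement $P_c$ from the two sequences' marginal label
frequencies, plus a one-vs-rest binary variant per event type. All metrics
collapse sub-labels first (`ISAC`→`SACC`; `HPSO`/`IHPS`/`LPSO`/`ILPS`→`PSO`),
matching how reference labelings treat these categories.
`duration_stats_rmsd()` scores an event list against the average of two
reference raters on (mean duration, SD of durations, event count) per event
type, normalizing each characteristic by its maximum across the compared
entities before taking the root mean square; characteristics undefined for
empty or single-event lists are flagged and dropped.

## Numerical choices and degenerate inputs

* Ties in greedy chunk selection go to the earlier run; candidate peaks tie
  to the earlier sample — classification is deterministic.
* Threshold estimation failure (e.g. all velocities above the start value in
  a context) skips saccade classification in that context with a warning;
  failure at the chunking stage degrades to a single whole-recording chunk.
* All-missing input returns an empty event table with a warning. Event
  windows whose velocities are entirely masked are dropped with a warning.
* Events never span missing data: each contiguous finite stretch is
  processed independently, and PSO windows truncate at the first masked
  sample.
* Test problem sizes: the ground-truth recovery and noise-locality fixtures
  are 60-s recordings at 1000 Hz; structural invariants run over 50
  randomized 4–10-s scripts. These sizes exercise every code path —
  chunking, both saccade contexts, PSOs, pursuit, blinks — while keeping the
  default suite fast.

## Known limitations

* Blinks are masked, not classified as events; real-time operation is out of
  scope (chunking sorts major saccades over the whole recording).
* On very clean recordings the onset/offset walk descends into the noise
  floor, biasing boundaries outward by up to about half the Savitzky–Golay
  window; with realistic noise the thresholds sit higher on the velocity
  flank and the bias largely cancels.
* A 1-s saccade context that straddles qualitatively different movement
  regimes (e.g. half pursuit, half fixation) has bimodal sub-threshold
  statistics; thresholds then land between the modes, and weak oscillations
  after such saccades can be missed or truncated.
* The pursuit/fixation split uses a fixed drift threshold on low-pass
  filtered velocity; pursuit slower than `pursuit_velthresh` is labeled
  fixation by design.
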