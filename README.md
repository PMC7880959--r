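# gazevents

Adaptive, robust velocity-based classification of eye-movement events in R.

Researchers who record gaze with remote or tower-mounted eye trackers —
increasingly while participants watch movies or other dynamic, feature-rich
stimuli — rarely analyse raw coordinate streams directly. The unit of
analysis is the eye-movement *event*: fixations, saccades, post-saccadic
oscillations (PSOs, also called glissades), and smooth pursuit. `gazevents`
converts dense monocular gaze recordings (X/Y screen coordinates in pixels at
a fixed sampling rate) into a table of labeled events, and is built to stay
robust on prolonged recordings with signal loss (blinks) and noise levels
that drift over time, such as eye tracking during simultaneous MRI.

## The algorithm

The classifier is velocity-based. After spike removal, blink-margin masking
and smoothing, angular eye speed is computed per sample. The saccade
threshold is not fixed but estimated from the data by robust iteration:
starting from a deliberately high value *PT*₀ (default 300 deg/s), each step
collects the velocities *V* strictly below the current threshold and sets

&nbsp;&nbsp;&nbsp;&nbsp;*PT*ₙ = median(*V*ₙ₋₁) + *F* · MAD(*V*ₙ₋₁)

where MAD is the raw median absolute deviation and *F* the `noise_factor`
(default 5), stopping when |*PT*ₙ − *PT*ₙ₋₁| < 1 deg/s. Median/MAD
statistics make the update nearly insensitive to the heavy right tail that
saccades and artifacts add to the velocity distribution, where a mean/SD
update would be dragged upward.

Because noise in long recordings is not stationary, thresholds are never
estimated globally for event classification. A heavily median-filtered
velocity stream is used once to locate the *major* saccades (greedily, by
above-threshold run weight, capped at `max_initial_saccade_freq` = 2 Hz),
which chunk the recording into intersaccadic intervals. Chunk-boundary
saccades (label `SACC`) get their thresholds from a 1-s window centered on
their velocity peak; saccades inside a chunk (`ISAC`) use the whole chunk as
context. Saccade on-/offsets are the nearest sub-threshold local velocity
minima around the peak (onset threshold median + *F*·MAD; peaks must exceed
median + 2*F*·MAD). A PSO (`HPSO`/`LPSO` at chunk boundaries, `IHPS`/`ILPS`
inside) is classified when velocity re-exceeds the onset threshold within
40 ms of a saccade offset. Remaining segments are low-pass filtered
(Butterworth, 4 Hz) and split at a fixed 2 deg/s drift threshold into smooth
pursuit (`PURS`) and fixation (`FIXA`).

The package also ships the agreement metrics used to validate such
classifiers against human raters (sample-level misclassification, Jaccard
index, Cohen's kappa, event-duration-statistics RMSD) and a deterministic
synthetic gaze generator with per-sample ground truth.

## Worked example

```r
library(gazevents)

# synthesize a 8.2-s recording with known ground truth:
# fixations, three saccades (two with PSOs), one pursuit
sc <- gaze_script(sampling_rate = 1000, px2deg = 0.0177, seed = 42)
sc <- sg_fixation(sc, 2)
sc <- sg_saccade(sc, 5); sc <- sg_pso(sc)
sc <- sg_fixation(sc, 2)
sc <- sg_saccade(sc, 8)
sc <- sg_pursuit(sc, 2, velocity = 5)
sc <- sg_saccade(sc, 6); sc <- sg_pso(sc)
sc <- sg_fixation(sc, 2)
rec <- generate_recording(sc)

events <- classify_recording(rec$series)
events[, c("label", "onset_time", "offset_time", "amplitude", "peak_vel")]
```

```
  label onset_time offset_time amplitude peak_vel
1  FIXA      0.001        2.00    0.2631     2.02
2  SACC      1.999        2.04    5.0159   207.44
3  HPSO      2.045        2.08    0.0527    11.84
4  FIXA      2.083        4.08    0.4113     3.07
5  SACC      4.079        4.13    8.0124   277.08
6  PURS      4.134        6.13    9.9902     6.51
7  SACC      6.133        6.18    6.0166   233.97
8  LPSO      6.182        6.20    0.1340    11.91
9  FIXA      6.200        8.22    0.3185     7.27
```

Every scripted event is recovered with its correct label: the two 5-/6-deg
saccades carry oscillations (`HPSO`/`LPSO`), the 2-s, 5-deg/s target motion
is labeled pursuit, and amplitudes match the scripted values to within the
coordinate noise. Comparing the classification sample-by-sample against the
generator's ground truth:

```r
pred <- events_to_samples(events, length(rec$series$x))
misclassification(pred, rec$truth$labels)   # 0.0029
cohens_kappa(pred, rec$truth$labels)        # 0.993
```

Only 0.3 % of samples disagree (boundary samples around each event), and
chance-corrected agreement is near-perfect.

For file-based workflows, `read_gaze()` / `write_events()` handle the
headerless input TSV and the BIDS-style events table (`onset`, `duration`,
label and property columns), and the command-line wrapper

```sh
inst/cli/gazevents <inputfile> <outputfile> <px2deg> <samplingrate> \
    [--noise_factor 5 ...]
```

classifies a recording, writes the events table and saves a diagnostic
figure (coordinates and velocity with per-label shading) for quality
control. Every algorithm parameter is exposed both as a CLI flag and as an
argument of `gaze_params()`.

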