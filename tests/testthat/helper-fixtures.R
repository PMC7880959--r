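# --- independent threshold oracles -----------------------------------------

# literal transcription of the robust iterative threshold update: start at
# pt0, new threshold = median + F * MAD of velocities strictly below the
# previous threshold, stop when consecutive thresholds differ by < 1 deg/s
oracle_threshold <- function(v, pt0, f) {
  v <- v[is.finite(v)]
  pt <- pt0
  repeat {
    sub <- v[v < pt]
    med <- median(sub)
    mad <- median(abs(sub - med))
    pt_new <- med + f * mad
    if (abs(pt_new - pt) < 1) return(pt_new)
    pt <- pt_new
  }
}

# the classical mean/SD update the robust rule replaces; used only to
# demonstrate the robustness advantage
oracle_threshold_meansd <- function(v, pt0, f, max_iter = 1000) {
  v <- v[is.finite(v)]
  pt <- pt0
  for (i in seq_len(max_iter)) {
    sub <- v[v < pt]
    if (length(sub) < 2) return(pt)
    pt_new <- mean(sub) + f * sd(sub)
    if (abs(pt_new - pt) < 1) return(pt_new)
    pt <- pt_new
  }
  pt
}

# --- synthetic fixtures ------------------------------------------------------

# 60-s recording: 8 fixations, 10 saccades (6 with PSOs), 2 pursuits.
# Pursuits are saccade-bounded (the natural gaze sequence when a target
# starts/stops moving), the final saccade ends the recording.
fixture_script_60s <- function(seed, noise_sd = 0.1, noise_profile = 1) {
  sc <- gaze_script(seed = seed, noise_sd = noise_sd,
                    noise_profile = noise_profile)
  sc <- sg_fixation(sc, 6.4)                       # f1
  sc <- sg_saccade(sc, 5); sc <- sg_pso(sc)        # S1 + P1
  sc <- sg_fixation(sc, 6.6)                       # f2
  sc <- sg_saccade(sc, 8); sc <- sg_pso(sc)        # S2 + P2
  sc <- sg_fixation(sc, 6.3)                       # f3
  sc <- sg_saccade(sc, 4)                          # S3
  sc <- sg_pursuit(sc, 4, velocity = 5)            # U1
  # post-pursuit saccade: its threshold context includes the pursuit, so a
  # weak oscillation would be missed there; give it a strong (pupil-CR-like)
  # oscillation instead
  sc <- sg_saccade(sc, 6)
  sc <- sg_pso(sc, relative_peak_fraction = 0.12,
               max_peak_vel = 28)                  # S4 + P3
  sc <- sg_fixation(sc, 6.5)                       # f4
  sc <- sg_saccade(sc, 10); sc <- sg_pso(sc)       # S5 + P4
  sc <- sg_fixation(sc, 6.4)                       # f5
  sc <- sg_saccade(sc, 4); sc <- sg_pso(sc)        # S6 + P5
  sc <- sg_fixation(sc, 6.6)                       # f6
  sc <- sg_saccade(sc, 7)                          # S7
  sc <- sg_pursuit(sc, 4, velocity = 5)            # U2
  sc <- sg_saccade(sc, 5)                          # S8
  sc <- sg_fixation(sc, 6.3)                       # f7
  sc <- sg_saccade(sc, 12); sc <- sg_pso(sc)       # S9 + P6
  sc <- sg_fixation(sc, 6.5)                       # f8
  sc <- sg_saccade(sc, 6)                          # S10 (ends the recording)
  sc
}

# recording whose second half carries 10x the coordinate noise; the noise
# step falls about 1 s into a long fixation, shortly after a major saccade,
# so the mixed-noise intersaccadic segment is dominated by its noisy part
# (threshold contexts estimated on such a segment stay conservative)
fixture_script_noise_halves <- function(seed) {
  sc <- gaze_script(seed = seed, noise_sd = 0.1, noise_profile = c(1, 10))
  sc <- sg_fixation(sc, 8)
  sc <- sg_saccade(sc, 5); sc <- sg_pso(sc)
  sc <- sg_fixation(sc, 5)
  sc <- sg_saccade(sc, 8)
  sc <- sg_pursuit(sc, 3, velocity = 5)
  sc <- sg_saccade(sc, 6)
  sc <- sg_fixation(sc, 5)
  sc <- sg_saccade(sc, 10)
  sc <- sg_fixation(sc, 10)    # the noise step lands ~1 s into this one
  sc <- sg_saccade(sc, 6)
  sc <- sg_fixation(sc, 4)
  sc <- sg_saccade(sc, 8)
  sc <- sg_fixation(sc, 3)
  sc <- sg_saccade(sc, 10)
  sc <- sg_fixation(sc, 3)
  sc <- sg_saccade(sc, 7)
  sc <- sg_fixation(sc, 3)
  sc
}

# random event composition for property-style structural tests
random_script <- function(seed) {
  rng <- local({ set.seed(seed); list(
    n_blocks = sample(2:4, 1),
    u = runif(40), amp = runif(40, 2, 10), dur = runif(40, 0.8, 2.0))
  })
  sc <- gaze_script(seed = seed + 10000L)
  k <- 0
  sc <- sg_fixation(sc, rng$dur[k <- k + 1])
  for (b in seq_len(rng$n_blocks)) {
    sc <- sg_saccade(sc, rng$amp[b])
    if (rng$u[b] < 0.5) sc <- sg_pso(sc)
    if (rng$u[b + 10] < 0.25) {
      sc <- sg_pursuit(sc, rng$dur[k <- k + 1], velocity = 5)
      sc <- sg_saccade(sc, rng$amp[b + 10])
    }
    if (rng$u[b + 20] < 0.2) sc <- sg_blink(sc, 0.12)
    sc <- sg_fixation(sc, rng$dur[k <- k + 1])
  }
  sc
}

# match classified events against ground-truth events: same collapsed label
# sequence; returns per-event boundary errors in samples, or NULL when the
# event sequences do not line up
match_events_to_truth <- function(events, truth_events) {
  got <- collapse_labels(events$label)
  if (!identical(as.character(got), as.character(truth_events$label)))
    return(NULL)
  data.frame(
    label = truth_events$label,
    onset_err = events$onset_sample - truth_events$onset_sample,
    offset_err = events$offset_sample - truth_events$offset_sample)
}
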