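vs <- function(v, sr = 1000) velocity_series(v, sr)

test_that("chunking splits a recording at its fastest movements", {
  v <- rep(0, 1000)                       # 10 s at 100 Hz
  v[200:205] <- 100
  v[600:605] <- 100
  ck <- chunk_recording(vs(v, sr = 100))
  expect_length(ck$major_peaks, 2)
  expect_equal(nrow(ck$chunks), 3)
  expect_true(ck$major_peaks[1] %in% 200:205)
  expect_true(ck$major_peaks[2] %in% 600:605)
  # chunks tile the full series half-open
  expect_equal(ck$chunks$start[1], 1)
  expect_equal(ck$chunks$end[nrow(ck$chunks)], 1001)
  expect_equal(ck$chunks$start[-1], ck$chunks$end[-nrow(ck$chunks)])
})

test_that("flat velocity yields a single chunk with a warning", {
  expect_warning(ck <- chunk_recording(vs(rep(5, 500), sr = 100)), "single chunk")
  expect_equal(nrow(ck$chunks), 1)
  expect_length(ck$major_peaks, 0)
})

test_that("the frequency cap bounds the number of accepted boundary saccades", {
  v <- rep(0, 10000)                      # 10 s at 1000 Hz
  starts <- seq(100, by = 198, length.out = 50)
  for (s in starts) v[s:(s + 9)] <- 100
  ck <- chunk_recording(vs(v))
  expect_lte(length(ck$major_peaks), 20)  # 2 Hz x 10 s
  expect_equal(length(ck$major_peaks), 20)
})

test_that("saccade bounds land on sub-threshold local minima bracketing the peak", {
  v <- c(rep(0, 10), seq(10, 100, 10), seq(90, 0, -10), rep(0, 10))
  peak <- which.max(v)
  b <- find_saccade_bounds(v, peak, onset_threshold = 20)
  expect_lt(b$onset, peak)
  expect_gt(b$offset, peak)
  expect_lte(v[b$onset], 20)
  expect_lte(v[b$offset], 20)
  # local-minimum property in walk direction
  expect_gte(v[b$onset + 1], v[b$onset])
  expect_gte(v[b$offset - 1], v[b$offset])
  expect_false(b$clamped_onset || b$clamped_offset)
})

test_that("bounds skip intermediate minima that stay above the threshold", {
  v <- c(rep(0, 5), seq(10, 100, 10), seq(95, 30, -5), seq(35, 80, 5),
         seq(75, 0, -5), rep(0, 5))
  p1 <- which.max(v)
  b <- find_saccade_bounds(v, p1, onset_threshold = 20)
  # the 30 deg/s dip between the merged pulses must not stop the walk
  second_peak <- length(v) - 5 - 16  # inside the second pulse
  expect_gt(b$offset, second_peak)
  expect_lte(v[b$offset], 20)
})

test_that("bounds clamp at context edges and never cross masked samples", {
  v <- c(100, 80, 40, 10, 0, 0)
  b <- find_saccade_bounds(v, 1, onset_threshold = 20)
  expect_equal(b$onset, 1)
  expect_true(b$clamped_onset)
  v2 <- c(0, 5, NA, 50, 100, 50, 5, 0)
  b2 <- find_saccade_bounds(v2, 5, onset_threshold = 20)
  expect_gte(b2$onset, 4)
  expect_true(b2$clamped_onset)
})

test_that("post-saccadic oscillations are picked up only within their window", {
  v <- rep(0.5, 300)
  v[105:115] <- c(5, 12, 20, 25, 24, 18, 12, 8, 5, 2, 1)
  pso <- classify_pso(v, saccade_offset = 100, onset_threshold = 10,
                      peak_threshold = 40, sampling_rate = 1000,
                      chunk_boundary = FALSE)
  expect_false(is.null(pso))
  expect_equal(pso$label, "ILPS")         # low-velocity, intra-chunk
  expect_equal(pso$onset, 101)
  expect_lte(pso$offset, 140)
  # high-velocity variant at a chunk boundary
  v2 <- v; v2[105:115] <- v2[105:115] * 3
  pso2 <- classify_pso(v2, 100, 10, 40, sampling_rate = 1000,
                       chunk_boundary = TRUE)
  expect_equal(pso2$label, "HPSO")
  # re-crossing 50 ms after the offset is beyond the window
  v3 <- rep(0.5, 300); v3[150:160] <- 30
  expect_null(classify_pso(v3, 100, 10, 40, sampling_rate = 1000))
  # monotone decay below the onset threshold: no oscillation
  expect_null(classify_pso(rep(0.5, 300), 100, 10, 40, sampling_rate = 1000))
})

test_that("sub-duration blips are not classified as saccades", {
  set.seed(8)
  v <- runif(1000, 0.4, 0.6)
  v[500:504] <- 100                       # 5 ms blip
  ev <- classify_saccades(vs(v), 1, 1000, gaze_params())
  expect_length(ev, 0)
})

test_that("zero-velocity windows yield no saccades", {
  expect_length(classify_saccades(vs(rep(0, 500)), 1, 500, gaze_params()), 0)
})

test_that("pursuit and fixation segmentation follows the drift threshold", {
  p <- gaze_params()
  ev <- classify_pursuit_fixation(vs(rep(5, 1000)), 1, 1000, p)
  expect_length(ev, 1)
  expect_equal(ev[[1]]$label, "PURS")
  expect_equal(ev[[1]]$onset, 1)
  expect_equal(ev[[1]]$offset, 1000)
  ev2 <- classify_pursuit_fixation(vs(rep(0.5, 1000)), 1, 1000, p)
  expect_length(ev2, 1)
  expect_equal(ev2[[1]]$label, "FIXA")
  # a 30 ms unlabeled gap is below the minimum fixation duration
  expect_length(classify_pursuit_fixation(vs(rep(0.5, 2000)), 100, 129, p), 0)
})

test_that("raising the pursuit threshold never increases pursuit coverage", {
  set.seed(21)
  v <- abs(2 + cumsum(rnorm(3000, 0, 0.05)))
  dur <- function(th) {
    ev <- classify_pursuit_fixation(vs(v), 1, 3000,
                                    gaze_params(pursuit_velthresh = th))
    sum(vapply(ev, function(e)
      if (e$label == "PURS") e$offset - e$onset + 1L else 0L, integer(1)))
  }
  d <- vapply(c(1, 2, 4, 8), dur, numeric(1))
  expect_true(all(diff(d) <= 0))
})

test_that("event properties follow from the event window", {
  coords <- gaze_series(c(0, 100, 200, 300), c(0, 150, 300, 400),
                        sampling_rate = 1000, px2deg = 0.01)
  v <- velocity_series(c(NA, 10, 20, 90), 1000)
  row <- compute_event_properties("SACC", 1, 4, coords, v)
  expect_equal(row$amplitude, 5)          # 3-4-5 triangle in degrees
  expect_equal(row$peak_vel, 90)
  expect_equal(row$median_vel, 20)
  expect_equal(row$avg_vel, 40)
  expect_equal(row$onset_time, 0)
  expect_equal(row$offset_time, 0.004)
  # single finite velocity: all three statistics coincide
  r1 <- compute_event_properties("FIXA", 3, 3, coords,
                                 velocity_series(c(NA, 1, 7, 2), 1000))
  expect_equal(r1$peak_vel, r1$median_vel)
  expect_equal(r1$peak_vel, r1$avg_vel)
  # fully masked windows drop the event
  expect_warning(
    r2 <- compute_event_properties("FIXA", 1, 2, coords,
                                   velocity_series(c(NA, NA, 1, 1), 1000)),
    "masked")
  expect_null(r2)
})

test_that("classification is deterministic and handles degenerate input", {
  rec <- generate_recording(
    sg_fixation(sg_saccade(sg_fixation(gaze_script(seed = 3), 1.5), 6), 1.5))
  e1 <- classify_recording(rec$series)
  e2 <- classify_recording(rec$series)
  expect_identical(e1, e2)
  allna <- gaze_series(rep(NA_real_, 100), rep(NA_real_, 100), 1000, 0.01)
  expect_warning(e3 <- classify_recording(allna), "no usable samples")
  expect_equal(nrow(e3), 0)
})

test_that("one clean saccade is recovered with tight boundaries", {
  sc <- gaze_script(seed = 14)
  sc <- sg_fixation(sc, 1.5)
  sc <- sg_saccade(sc, 6)
  sc <- sg_fixation(sc, 1.5)
  rec <- generate_recording(sc)
  ev <- classify_recording(rec$series)
  sacc <- ev[collapse_labels(ev$label) == "SACC", ]
  tr <- rec$truth$events[rec$truth$events$label == "SACC", ]
  expect_equal(nrow(sacc), 1)
  expect_lte(abs(sacc$onset_sample - tr$onset_sample), 5)
  expect_lte(abs(sacc$offset_sample - tr$offset_sample), 5)
})

test_that("events never cross blink gaps and blink margins stay unlabeled", {
  sc <- gaze_script(seed = 31)
  sc <- sg_fixation(sc, 1.5)
  sc <- sg_blink(sc, 0.12)
  sc <- sg_fixation(sc, 1.5)
  rec <- generate_recording(sc)
  ev <- classify_recording(rec$series)
  gap <- range(which(is.na(rec$series$x)))
  for (i in seq_len(nrow(ev)))
    expect_true(ev$offset_sample[i] < gap[1] || ev$onset_sample[i] > gap[2])
})
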