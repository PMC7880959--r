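test_that("gaze TSV round-trips and extra columns are ignored", {
  tf <- tempfile(fileext = ".tsv")
  sc <- sg_fixation(gaze_script(seed = 9), 0.2)
  rec <- generate_recording(sc)
  write_gaze(rec$series, tf)
  back <- read_gaze(tf, px2deg = rec$series$px2deg,
                    sampling_rate = rec$series$sampling_rate)
  expect_equal(back$x, round(rec$series$x, 3))
  expect_equal(back$y, round(rec$series$y, 3))
  # third column is ignored
  writeLines(c("1.0\t2.0\tfoo", "3.0\t4.0\tbar"), tf)
  s3 <- read_gaze(tf, 0.01, 1000)
  expect_equal(s3$x, c(1, 3))
  expect_equal(s3$y, c(2, 4))
})

test_that("non-numeric tokens become missing samples", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("1.0\t2.0", "nan\tnan", "3.0\t4.0"), tf)
  s <- read_gaze(tf, 0.01, 1000)
  expect_true(is.na(s$x[2]) && is.na(s$y[2]))
  expect_false(anyNA(s$x[c(1, 3)]))
})

test_that("malformed input files are rejected with a line reference", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("1.0\t2.0", "loneval", "3.0\t4.0"), tf)
  expect_error(read_gaze(tf, 0.01, 1000), "line 2")
  writeLines(character(0), tf)
  expect_error(read_gaze(tf, 0.01, 1000), "empty")
})

test_that("event tables serialize in the BIDS onset/duration dialect", {
  tf <- tempfile(fileext = ".tsv")
  ev <- as.data.frame(list(
    label = "FIXA", onset_time = 0.1, offset_time = 0.25,
    onset_sample = 101L, offset_sample = 250L,
    start_x = 1.23456, start_y = 2, end_x = 3, end_y = 4,
    amplitude = 0.5, peak_vel = 12.345, median_vel = 5.5, avg_vel = 6.25))
  write_events(ev, tf)
  lines <- readLines(tf)
  expect_length(lines, 2)
  expect_match(lines[1], "^onset\tduration\tlabel\t")
  f <- strsplit(lines[2], "\t")[[1]]
  expect_equal(f[1], "0.100")
  expect_equal(f[2], "0.150")          # duration = offset - onset
  expect_equal(f[3], "FIXA")
  expect_equal(f[9], "12.35")          # velocities at 2 decimals
  back <- read_events(tf)
  expect_equal(back$onset, 0.1)
  expect_equal(back$offset, 0.25)
  # empty tables keep the header
  write_events(ev[0, ], tf)
  expect_length(readLines(tf), 1)
})

test_that("per-sample label files round-trip", {
  tf <- tempfile(fileext = ".tsv")
  lab <- c("FIXA", "FIXA", "SACC", "NONE")
  write_labels(lab, tf)
  expect_equal(read_labels(tf), lab)
})

test_that("the CLI classifies a recording end to end, reproducibly", {
  td <- tempdir()
  infile <- file.path(td, "rec.tsv")
  outfile <- file.path(td, "events.tsv")
  fig <- file.path(td, "diag.png")
  sc <- gaze_script(seed = 17)
  sc <- sg_fixation(sc, 1.2)
  sc <- sg_saccade(sc, 6)
  sc <- sg_fixation(sc, 1.2)
  rec <- generate_recording(sc)
  write_gaze(rec$series, infile)
  argv <- c(infile, outfile, "0.0177", "1000", "--figure", fig)
  st <- suppressMessages(run_cli(argv))
  expect_equal(st, 0L)
  expect_true(file.exists(outfile))
  expect_true(file.exists(fig))
  ev <- read_events(outfile)
  expect_true("SACC" %in% ev$label)
  first <- readLines(outfile)
  st2 <- suppressMessages(run_cli(argv))
  expect_identical(readLines(outfile), first)   # byte-identical rerun
  # parameter overrides are accepted under both flag spellings
  expect_equal(suppressMessages(
    run_cli(c(argv, "--noise-factor", "6"))), 0L)
  expect_equal(suppressMessages(
    run_cli(c(argv, "--noise_factor", "6"))), 0L)
})

test_that("the CLI rejects bad invocations with a nonzero status", {
  expect_equal(suppressMessages(run_cli(c("a", "b"))), 1L)
  expect_equal(suppressMessages(run_cli(c("a", "b", "x", "1000"))), 1L)
  td <- tempdir()
  expect_equal(suppressMessages(
    run_cli(c(file.path(td, "rec.tsv"), file.path(td, "o.tsv"),
              "0.01", "1000", "--frobnicate", "1"))), 1L)
})

test_that("diagnostic rendering produces a figure even without events", {
  sc <- sg_fixation(gaze_script(seed = 23), 0.5)
  rec <- generate_recording(sc)
  pp <- preprocess_gaze(rec$series)
  f <- tempfile(fileext = ".png")
  render_diagnostics(pp$sg, pp$v_sg, classify_recording(rec$series)[0, ], f)
  expect_true(file.exists(f) && file.size(f) > 0)
})
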