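test_that("misclassification counts disagreements over the included universe", {
  a <- c("FIXA", "FIXA", "SACC", "SACC")
  expect_equal(misclassification(a, a), 0)
  expect_equal(misclassification(c("FIXA", "SACC"), c("SACC", "FIXA")), 1)
  expect_equal(
    misclassification(c("FIXA", "FIXA", "SACC", "SACC"),
                      c("FIXA", "SACC", "SACC", "PURS")), 0.5)
  # excluded labels are invisible unless the other rater includes the sample
  expect_equal(
    misclassification(c("FIXA", "NONE", "NONE"), c("FIXA", "NONE", "SACC")),
    0.5)
  expect_error(misclassification(c("FIXA"), c("FIXA", "SACC")), "length")
  expect_error(misclassification(c("NONE"), c("NONE")), "no samples")
})

test_that("PSO and saccade sub-labels collapse before comparison", {
  a <- c("HPSO", "LPSO", "IHPS", "ILPS", "ISAC")
  b <- c("LPSO", "HPSO", "ILPS", "IHPS", "SACC")
  expect_equal(misclassification(a, b), 0)
  expect_equal(jaccard(a, b, "PSO"), 1)
  expect_equal(cohens_kappa(a, b), 1)
})

test_that("Jaccard index follows set arithmetic", {
  a <- rep("X", 100); a[1:90] <- "FIXA"
  b <- rep("X", 100); b[c(1:84, 95:100)] <- "FIXA"
  expect_equal(jaccard(a, b, "FIXA"), 84 / 96)
  expect_equal(jaccard(a, a, "FIXA"), 1)
  expect_equal(jaccard(a, rep("X", 100), "FIXA"), 0)
  expect_warning(j <- jaccard(rep("X", 5), rep("X", 5), "FIXA"), "convention")
  expect_equal(j, 1)
  # symmetry
  expect_equal(jaccard(a, b, "FIXA"), jaccard(b, a, "FIXA"))
})

test_that("Cohen's kappa matches its defining identity", {
  a <- c("F", "F", "S", "S")
  expect_equal(cohens_kappa(a, a), 1)
  # observed agreement 0.5 equals chance agreement 0.5 -> kappa 0
  expect_equal(cohens_kappa(a, c("F", "S", "F", "S")), 0)
  # long independent sequences sit at chance level
  set.seed(77)
  x <- sample(c("F", "S", "P", "O"), 20000, replace = TRUE)
  y <- sample(c("F", "S", "P", "O"), 20000, replace = TRUE)
  expect_lt(abs(cohens_kappa(x, y)), 0.05)
  expect_lte(cohens_kappa(x, y), 1)
  # symmetry and the binary one-vs-rest variant
  expect_equal(cohens_kappa(x, y), cohens_kappa(y, x))
  expect_equal(cohens_kappa(a, a, category = "F"), 1)
  expect_error(cohens_kappa(c("F", "F"), c("F", "F")), "undefined")
})

test_that("the agreement report combines the three metrics coherently", {
  a <- c(rep("FIXA", 60), rep("SACC", 25), rep("PSO", 10), rep("PURS", 5))
  rep_ <- agreement_report(a, a)
  expect_equal(rep_$misclassification, 0)
  expect_equal(rep_$kappa, 1)
  expect_equal(unname(diag(rep_$confusion)), rep(1, 4))
})

test_that("duration-statistics RMSD is zero at the rater average and monotone", {
  mk <- function(m, s, n, lab = "FIXA") {
    raw <- seq_len(n)
    d <- (raw - mean(raw)) / sd(raw) * s + m
    data.frame(label = lab, duration = d)
  }
  r1 <- mk(0.08, 0.05, 10)
  r2 <- mk(0.12, 0.05, 10)
  avg <- mk(0.10, 0.05, 10)     # exactly the rater average on all three stats
  expect_equal(unname(duration_stats_rmsd(avg, r1, r2, labels = "FIXA")), 0)
  # printed toy case: candidate (200 ms, 50 ms, 10) vs average (100 ms, 50 ms, 10);
  # normalizing each characteristic by its maximum across the entities gives
  # deviations (0.5, 0, 0) -> RMSD = 0.5 / sqrt(3)
  cand <- mk(0.2, 0.05, 10)
  ra <- mk(0.1, 0.05, 10)
  expect_equal(unname(duration_stats_rmsd(cand, ra, ra, labels = "FIXA")),
               0.5 / sqrt(3), tolerance = 1e-12)
  # a candidate strictly farther on every normalized characteristic scores worse
  near <- mk(0.12, 0.06, 12)
  far <- mk(0.18, 0.09, 18)
  expect_lt(duration_stats_rmsd(near, ra, ra, labels = "FIXA")[["FIXA"]],
            duration_stats_rmsd(far, ra, ra, labels = "FIXA")[["FIXA"]])
  # event type absent everywhere: flagged, score from the one available
  # characteristic (the event count, 0 for all entities -> 0)
  expect_warning(
    out <- duration_stats_rmsd(mk(0.1, 0.05, 10), r1, r2,
                               labels = c("FIXA", "PURS")),
    "undefined")
  expect_equal(out[["PURS"]], 0)
  # candidate misses a type the raters produced: count deviation -> 1
  expect_warning(
    out2 <- duration_stats_rmsd(mk(0.1, 0.05, 10),
                                rbind(r1, mk(0.5, 0.1, 5, "PURS")),
                                rbind(r2, mk(0.5, 0.1, 5, "PURS")),
                                labels = "PURS"),
    "undefined")
  expect_equal(out2[["PURS"]], 1)
})

test_that("events rasterize to per-sample labels for metric input", {
  ev <- data.frame(label = c("FIXA", "SACC"),
                   onset_sample = c(1L, 11L), offset_sample = c(10L, 15L))
  lab <- events_to_samples(ev, 20)
  expect_equal(lab, c(rep("FIXA", 10), rep("SACC", 5), rep("NONE", 5)))
})
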