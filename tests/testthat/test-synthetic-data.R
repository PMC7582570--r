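test_that("profile drawing is seeded, index-addressable and separation-scaled", {
  cfg <- cohort_config(n_subjects = 5, duration_s = 60, seed = 1)
  expect_identical(draw_profile(cfg, 1), draw_profile(cfg, 1))
  p1 <- draw_profile(cfg, 1)
  p2 <- draw_profile(cfg, 2)
  expect_false(isTRUE(all.equal(p1$baseline, p2$baseline)))
  expect_false(isTRUE(all.equal(p1$noise_sd, p2$noise_sd)))

  cfg0 <- cohort_config(n_subjects = 5, duration_s = 60, seed = 1,
                        separation = 0)
  q1 <- draw_profile(cfg0, 1)
  q2 <- draw_profile(cfg0, 2)
  expect_equal(unclass(q1)[-1], unclass(q2)[-1])  # all but subject_id

  expect_error(draw_profile(cfg, 6), "1\\.\\.5")
  expect_error(draw_profile(cfg, 0), "1\\.\\.5")
})

test_that("profile invariants hold across seeds and separations", {
  for (seed in 1:5) {
    for (sep in c(0, 0.5, 1, 2)) {
      cfg <- cohort_config(n_subjects = 4, duration_s = 60, seed = seed,
                           separation = sep)
      for (i in 1:4) {
        p <- draw_profile(cfg, i)
        expect_true(p$lf_freq < p$hf_freq)
        expect_true(p$hf_freq < cfg$sampling_rate / 2)
        expect_true(p$noise_sd >= 0 && p$lf_amp >= 0 && p$hf_amp >= 0)
      }
    }
  }
})

test_that("synthesized signals have the configured geometry", {
  cfg <- cohort_config(n_subjects = 2, duration_s = 7200, seed = 3)
  sig <- synthesize_signal(draw_profile(cfg, 1), cfg)
  expect_length(sig$samples, 57600)
  expect_true(all(is.finite(sig$samples)))

  cfg2 <- cohort_config(n_subjects = 2, duration_s = 3600, seed = 3)
  expect_length(synthesize_signal(draw_profile(cfg2, 1), cfg2)$samples,
                28800)
})

test_that("degenerate profiles give closed-form signals", {
  cfg <- cohort_config(n_subjects = 2, duration_s = 40, seed = 1)
  const <- structure(list(subject_id = 1, baseline = 65, lf_amp = 0,
                          lf_freq = 0.1, hf_amp = 0, hf_freq = 0.25,
                          drift_scale = 0, noise_sd = 0),
                     class = "subject_profile")
  expect_equal(synthesize_signal(const, cfg)$samples, rep(65, 320))

  # pure LF sinusoid over an integer number of periods averages to baseline
  lf <- const
  lf$lf_amp <- 1
  x <- synthesize_signal(lf, cfg)$samples  # 40 s = 4 LF periods
  expect_equal(mean(x), 65, tolerance = 1e-9)
})

test_that("cohorts are reproducible bitwise and cover the study geometry", {
  cfg <- cohort_config(n_subjects = 12, duration_s = 3600, seed = 7)
  coh <- generate_cohort(cfg)
  expect_length(coh$signals, 12)
  expect_true(all(vapply(coh$signals,
                         function(s) length(s$samples), numeric(1)) ==
                    28800))

  cfg2 <- cohort_config(n_subjects = 2, duration_s = 120, seed = 11)
  expect_identical(generate_cohort(cfg2), generate_cohort(cfg2))
})

test_that("pure-HF profiles put the periodogram peak at hf_freq", {
  cfg <- cohort_config(n_subjects = 2, duration_s = 128, seed = 5)
  hf <- structure(list(subject_id = 1, baseline = 0, lf_amp = 0,
                       lf_freq = 0.1, hf_amp = 2, hf_freq = 0.25,
                       drift_scale = 0, noise_sd = 0),
                  class = "subject_profile")
  x <- synthesize_signal(hf, cfg)$samples
  n <- length(x)
  p <- Mod(fft(x))^2
  k <- which.max(p[2:(n %/% 2)])          # skip DC
  peak_freq <- k * cfg$sampling_rate / n
  expect_lt(abs(peak_freq - 0.25), cfg$sampling_rate / n + 1e-12)
})

test_that("between-subject feature distance grows with separation", {
  seg_cfg <- segmentation_config()
  centroid_dist <- function(sep, seed) {
    coh <- tiny_cohort(seed = seed, n_subjects = 4, duration_s = 300,
                       separation = sep)
    segs <- segment_cohort(coh, seg_cfg)
    mat <- t(apply(as.matrix(segs[, -(1:2)]), 1, compute_features,
                   sampling_rate = 8))
    mat <- mat[, apply(mat, 2, function(cc) sd(cc) > 0), drop = FALSE]
    mat <- scale(mat)
    cent <- aggregate(mat, list(segs$subject_id), mean)[, -1]
    mean(dist(cent))
  }
  seps <- c(0, 0.5, 1)
  means <- sapply(seps, function(sp) {
    mean(sapply(1:5, function(sd_) centroid_dist(sp, sd_)))
  })
  expect_true(all(diff(means) >= 0))
})

test_that("cohort CSV + manifest round-trips", {
  coh <- tiny_cohort(seed = 2, n_subjects = 2, duration_s = 60)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "subject_1.csv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_cohort(dir)
  expect_equal(back$config, coh$config)
  expect_equal(back$signals[[2]]$samples, coh$signals[[2]]$samples,
               tolerance = 1e-12)
})

test_that("config validation rejects impossible cohorts", {
  expect_error(cohort_config(n_subjects = 1), "n_subjects")
  expect_error(cohort_config(duration_s = -5), "duration_s")
  expect_error(cohort_config(duration_s = 10.3, sampling_rate = 7),
               "whole number")
  expect_error(cohort_config(separation = -1), "separation")
})
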