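test_that("compute_eer handles the canonical score configurations", {
  perfect <- list(genuine = c(0.9, 0.8, 0.7), impostor = c(0.1, 0.2))
  expect_equal(compute_eer(perfect)$eer, 0)

  same <- list(genuine = c(0.1, 0.4, 0.8), impostor = c(0.1, 0.4, 0.8))
  expect_equal(compute_eer(same)$eer, 50)

  crossed <- list(genuine = c(0.6, 0.4), impostor = c(0.5, 0.3))
  r <- compute_eer(crossed)
  expect_equal(r$eer, 50)
  expect_true(r$eer_threshold > 0.4 && r$eer_threshold <= 0.5)

  expect_error(compute_eer(list(genuine = numeric(0), impostor = 1)),
               "non-empty")
})

test_that("compute_eer agrees with the exhaustive sweep oracle", {
  withr::local_seed(31)
  for (i in 1:25) {
    g <- runif(sample(2:40, 1))
    im <- runif(sample(2:40, 1), max = runif(1, 0.5, 1))
    got <- compute_eer(list(genuine = g, impostor = im))$eer
    expect_equal(got, oracle_eer(g, im), tolerance = 1e-9)
  }
  # ties between genuine and impostor scores
  g <- c(0.2, 0.5, 0.5, 0.9)
  im <- c(0.5, 0.5, 0.1, 0.3)
  expect_equal(compute_eer(list(genuine = g, impostor = im))$eer,
               oracle_eer(g, im), tolerance = 1e-9)
})

test_that("FAR is non-increasing and FRR non-decreasing in the threshold", {
  withr::local_seed(32)
  for (i in 1:10) {
    r <- compute_eer(list(genuine = rnorm(30, 1), impostor = rnorm(30)))
    expect_true(all(diff(r$far) <= 0))
    expect_true(all(diff(r$frr) >= 0))
    expect_true(r$eer >= 0 && r$eer <= 100)
  }
})

test_that("mean_eer is the rounded arithmetic mean", {
  expect_equal(mean_eer(c(0, 100)), 50)
  withr::local_seed(33)
  x <- runif(30, 0, 40)
  acc <- 0
  for (v in x) acc <- acc + v
  expect_equal(mean_eer(x), round(acc / 30, 2))
  expect_error(mean_eer(numeric(0)), "empty")
})

test_that("published per-subject fusion EERs aggregate to the printed means", {
  ref <- reference_table("fusion_eer_per_subject")
  expect_equal(nrow(ref), 30L)
  expect_equal(mean_eer(ref$detail_fusion_eer), 12.42)
})

test_that("success rates follow the accepted/attempts convention", {
  expect_equal(success_rates(84, 100, 8, 2000),
               c(patient_pct = 84, nonpatient_pct = 0.4))
  expect_equal(success_rates(54, 100, 0, 2000),
               c(patient_pct = 54, nonpatient_pct = 0))
  expect_equal(success_rates(0, 1, 0, 1),
               c(patient_pct = 0, nonpatient_pct = 0))
  expect_error(success_rates(2, 1, 0, 1), "\\[0, attempts\\]")
  expect_error(success_rates(0, 0, 0, 1), "positive")
})

test_that("a one-cell experiment equals the direct pipeline invocation", {
  coh <- tiny_cohort(seed = 4, n_subjects = 3, duration_s = 300)
  clf <- classifier_config(hidden_nodes = 4, seed = 2)
  rep <- run_subband_experiment(coh, families = "bior1.1",
                                subbands = "D3", clf_config = clf)
  expect_equal(dim(as.data.frame(rep)), c(1L, 3L))

  segs <- segment_cohort(coh)
  decs <- decompose_segments(segs, "bior1.1")
  feats <- extract_feature_table(decs, subbands = "D3")
  sp <- split_train_test(feats, clf)
  models <- lapply(1:3, function(s) train_subject_model(sp$train, s, clf))
  eers <- vapply(collect_scores(models, sp$test),
                 function(s) compute_eer(s)$eer, numeric(1))
  expect_equal(rep$mean_eer, mean_eer(eers))
  expect_equal(attr(rep, "per_subject")[["bior1.1/D3"]], eers)
})

test_that("experiment reports cover the family-by-subband grid", {
  coh <- tiny_cohort(seed = 5, n_subjects = 3, duration_s = 300)
  clf <- classifier_config(hidden_nodes = 3, seed = 2)
  rep <- run_subband_experiment(coh, families = c("bior1.1", "bior2.2"),
                                subbands = c("A1", "D3"),
                                clf_config = clf)
  df <- as.data.frame(rep)
  expect_equal(nrow(df), 4L)
  expect_setequal(df$family, c("bior1.1", "bior2.2"))
  expect_setequal(df$subband, c("A1", "D3"))
  expect_true(all(df$mean_eer >= 0 & df$mean_eer <= 100))
  # aggregate recomputes from its own per-subject rows
  for (k in seq_len(nrow(df))) {
    key <- paste(df$family[k], df$subband[k], sep = "/")
    expect_equal(df$mean_eer[k], mean_eer(attr(rep, "per_subject")[[key]]))
  }
})

test_that("fusion reports pair approximation and detail fusion per family", {
  coh <- tiny_cohort(seed = 6, n_subjects = 3, duration_s = 300)
  clf <- classifier_config(hidden_nodes = 3, seed = 2)
  rep <- run_fusion_experiment(coh, families = c("bior1.1", "bior1.3"),
                               clf_config = clf)
  df <- as.data.frame(rep)
  expect_equal(nrow(df), 4L)
  expect_setequal(df$subband, c("approx_fusion", "detail_fusion"))
  # a single-band "fusion" equals the plain sub-band evaluation
  single <- run_fusion_experiment(coh, families = "bior1.1",
                                  sets = list(only_D3 = "D3"),
                                  clf_config = clf)
  plain <- run_subband_experiment(coh, families = "bior1.1",
                                  subbands = "D3", clf_config = clf)
  expect_equal(single$mean_eer, plain$mean_eer)
})

test_that("the use case counts attempts and calibrates thresholds sensibly", {
  coh <- tiny_cohort(seed = 7, n_subjects = 6, duration_s = 600)
  uc <- usecase_config(patient_ids = 1:2, nonpatient_ids = 3:6,
                       attempts_per_patient = 4,
                       thresholds_pct = c(10, 30))
  clf <- classifier_config(hidden_nodes = 4, seed = 2)
  rep <- run_usecase(coh, uc, clf)
  expect_equal(attr(rep, "patient_attempts"), 8L)
  expect_equal(attr(rep, "nonpatient_attempts"), 32L)
  df <- as.data.frame(rep)
  expect_equal(df$patients_accepted + df$patients_rejected, c(8, 8))
  expect_equal(df$nonpatients_accepted + df$nonpatients_rejected,
               c(32, 32))
  expect_equal(df$patient_success_rate,
               100 * df$patients_accepted / 8)
  expect_equal(df$nonpatient_success_rate,
               100 * df$nonpatients_accepted / 32)
  # a laxer FAR operating point can only accept more
  expect_gte(df$patients_accepted[2], df$patients_accepted[1])
  expect_gte(df$nonpatients_accepted[2], df$nonpatients_accepted[1])

  expect_error(usecase_config(patient_ids = 1:3, nonpatient_ids = 3:5),
               "disjoint")
  expect_error(usecase_config(thresholds_pct = c(0, 50)), "\\(0, 100\\)")
  expect_error(run_usecase(coh, usecase_config(patient_ids = 1:2,
                                               nonpatient_ids = 3:7),
                           clf), "does not cover")
})
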