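#' FAR/FRR curves and the equal error rate of a score set
#'
#' With decision rule "accept when score >= t", the false-acceptance rate
#' `FAR(t)` is the fraction of impostor scores `>= t` and the
#' false-rejection rate `FRR(t)` the fraction of genuine scores `< t`.
#' Both step curves are evaluated on the sorted distinct scores (plus one
#' threshold above the maximum); the equal error rate is their crossing,
#' linearly interpolated between the two adjacent thresholds bracketing
#' the sign change of `FAR - FRR`, with ties broken toward the lower
#' threshold.
#'
#' @param score_set a `score_set` (list with non-empty numeric `genuine`
#'   and `impostor`), e.g. one element of [collect_scores()].
#' @return an object of class `eer_result`: `thresholds`, `far`, `frr`
#'   (fractions in \[0, 1\] per threshold), `eer` (percent) and
#'   `eer_threshold`.
#' @export
#' @examples
#' compute_eer(list(genuine = c(0.9, 0.8), impostor = c(0.1, 0.2)))$eer  # 0
compute_eer <- function(score_set) {
  g <- score_set$genuine
  i <- score_set$impostor
  if (length(g) == 0 || length(i) == 0) {
    stop("both genuine and impostor score lists must be non-empty")
  }
  if (!all(is.finite(g)) || !all(is.finite(i))) {
    stop("scores must be finite")
  }
  s <- sort(unique(c(g, i)))
  thr <- c(s, s[length(s)] + 1)
  far <- vapply(thr, function(t) mean(i >= t), numeric(1))
  frr <- vapply(thr, function(t) mean(g < t), numeric(1))
  d <- far - frr
  j <- which(d <= 0)[1]           # first threshold at/after the crossing
  if (j == 1) {
    eer <- if (d[1] == 0) far[1] else max(far[1], frr[1])
    eer_thr <- thr[1]
  } else if (d[j] == 0) {
    eer <- far[j]
    eer_thr <- thr[j]
  } else {
    a <- d[j - 1] / (d[j - 1] - d[j])
    eer <- far[j - 1] + a * (far[j] - far[j - 1])
    eer_thr <- thr[j - 1] + a * (thr[j] - thr[j - 1])
  }
  structure(
    list(thresholds = thr, far = far, frr = frr,
         eer = 100 * eer, eer_threshold = eer_thr),
    class = "eer_result"
  )
}

#' @export
print.eer_result <- function(x, ...) {
  cat(sprintf("<eer_result> EER %.2f%% at threshold %.4f (%d thresholds)\n",
              x$eer, x$eer_threshold, length(x$thresholds)))
  invisible(x)
}

#' Aggregate per-subject equal error rates
#'
#' @param eers non-empty numeric vector of per-subject EERs in percent.
#' @return their arithmetic mean, rounded to 2 decimals.
#' @export
mean_eer <- function(eers) {
  if (length(eers) == 0) stop("mean_eer: empty input")
  round(mean(eers), 2)
}

# Shared backend: split, train one model per subject, collect scores,
# compute per-subject EERs.
evaluate_features <- function(features, clf_config) {
  split <- split_train_test(features, clf_config)
  subjects <- sort(unique(features$subject_id))
  models <- lapply(subjects, function(sid) {
    train_subject_model(split$train, sid, clf_config)
  })
  sets <- collect_scores(models, split$test)
  eers <- vapply(sets, function(s) compute_eer(s)$eer, numeric(1))
  list(per_subject = eers, mean_eer = mean_eer(eers),
       score_sets = sets, models = models, split = split)
}

#' Sub-band comparison experiment
#'
#' Runs the full chain (segment, decompose, per-sub-band features,
#' per-subject networks, EER) for every requested family and sub-band:
#' the 15-family x 6-sub-band comparison grid.
#'
#' @param cohort an `hrv_cohort`.
#' @param families character vector of biorthogonal family names.
#' @param subbands sub-bands to compare (default all of A1..A3, D1..D3).
#' @param seg_config a [segmentation_config()].
#' @param selection feature selection (default the 12-feature set).
#' @param clf_config a [classifier_config()].
#' @return an object of class `experiment_report`: a data.frame with
#'   columns `family`, `subband`, `mean_eer`, plus attribute
#'   `per_subject` (named list of per-subject EER vectors keyed
#'   `family/subband`).
#' @export
run_subband_experiment <- function(cohort, families = bior_families(),
                                   subbands = c("A1", "A2", "A3",
                                                "D1", "D2", "D3"),
                                   seg_config = segmentation_config(),
                                   selection = default_feature_selection(),
                                   clf_config = classifier_config()) {
  stopifnot(inherits(cohort, "hrv_cohort"))
  segments <- segment_cohort(cohort, seg_config)
  rows <- list()
  per_subject <- list()
  for (fam in families) {
    decs <- decompose_segments(segments, fam)
    for (sb in subbands) {
      feats <- extract_feature_table(decs, selection, sb,
                                     seg_config$sampling_rate)
      res <- evaluate_features(feats, clf_config)
      key <- paste(fam, sb, sep = "/")
      per_subject[[key]] <- res$per_subject
      rows[[key]] <- data.frame(family = fam, subband = sb,
                                mean_eer = res$mean_eer)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, per_subject = per_subject, class = c("experiment_report",
                                                      "data.frame"))
}

#' Sub-band fusion experiment
#'
#' For each family, evaluates feature-level fusion of the approximation
#' sub-bands (A1+A2+A3) and of the detail sub-bands (D1+D2+D3): features
#' are extracted per sub-band first and concatenated before
#' classification.
#'
#' @inheritParams run_subband_experiment
#' @param sets named list of sub-band groups to fuse (default
#'   approximation and detail fusion).
#' @return an `experiment_report` data.frame with columns `family`,
#'   `subband` (the fused set label), `mean_eer`, and a `per_subject`
#'   attribute as in [run_subband_experiment()].
#' @export
run_fusion_experiment <- function(cohort, families = c("bior1.1", "bior1.3"),
                                  sets = list(
                                    approx_fusion = c("A1", "A2", "A3"),
                                    detail_fusion = c("D1", "D2", "D3")),
                                  seg_config = segmentation_config(),
                                  selection = default_feature_selection(),
                                  clf_config = classifier_config()) {
  stopifnot(inherits(cohort, "hrv_cohort"))
  segments <- segment_cohort(cohort, seg_config)
  rows <- list()
  per_subject <- list()
  for (fam in families) {
    decs <- decompose_segments(segments, fam)
    for (set_name in names(sets)) {
      feats <- extract_feature_table(decs, selection, sets[[set_name]],
                                     seg_config$sampling_rate)
      res <- evaluate_features(feats, clf_config)
      key <- paste(fam, set_name, sep = "/")
      per_subject[[key]] <- res$per_subject
      rows[[key]] <- data.frame(family = fam, subband = set_name,
                                mean_eer = res$mean_eer)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, per_subject = per_subject, class = c("experiment_report",
                                                      "data.frame"))
}

#' Use-case configuration for threshold-based authentication
#'
#' @param patient_ids subjects acting as patients (default 1..10).
#' @param nonpatient_ids subjects acting as non-patients (default 11..30);
#'   must be disjoint from `patient_ids`.
#' @param attempts_per_patient authentication attempts per patient and per
#'   (patient, non-patient) pair (default 10: 10 patients give 100 patient
#'   attempts and 20 non-patients give 2000 non-patient attempts).
#' @param thresholds_pct operating FAR levels in percent at which the
#'   score threshold is calibrated (default 9, 10, 11, 12).
#' @return an object of class `usecase_config`.
#' @export
usecase_config <- function(patient_ids = 1:10, nonpatient_ids = 11:30,
                           attempts_per_patient = 10,
                           thresholds_pct = c(9, 10, 11, 12)) {
  if (length(intersect(patient_ids, nonpatient_ids)) > 0) {
    stop("patient and non-patient sets must be disjoint")
  }
  if (any(thresholds_pct <= 0 | thresholds_pct >= 100)) {
    stop("thresholds_pct must lie in (0, 100)")
  }
  if (attempts_per_patient < 1) stop("attempts_per_patient must be >= 1")
  structure(
    list(patient_ids = patient_ids, nonpatient_ids = nonpatient_ids,
         attempts_per_patient = as.integer(attempts_per_patient),
         thresholds_pct = thresholds_pct),
    class = "usecase_config"
  )
}

#' Patient / non-patient authentication success rates
#'
#' Patient success rate is the percentage of patient attempts accepted;
#' non-patient "success" rate is the percentage of non-patient attempts
#' (incorrectly) accepted — lower is better for the second.
#'
#' @param accepted_patients,patient_attempts accepted and total patient
#'   attempts.
#' @param accepted_nonpatients,nonpatient_attempts accepted and total
#'   non-patient attempts.
#' @return named numeric: `patient_pct`, `nonpatient_pct`.
#' @export
#' @examples
#' success_rates(84, 100, 8, 2000)  # 84% and 0.4%
success_rates <- function(accepted_patients, patient_attempts,
                          accepted_nonpatients, nonpatient_attempts) {
  if (patient_attempts <= 0 || nonpatient_attempts <= 0) {
    stop("attempt counts must be positive")
  }
  if (accepted_patients < 0 || accepted_patients > patient_attempts ||
      accepted_nonpatients < 0 ||
      accepted_nonpatients > nonpatient_attempts) {
    stop("accepted counts must lie in [0, attempts]")
  }
  c(patient_pct = 100 * accepted_patients / patient_attempts,
    nonpatient_pct = 100 * accepted_nonpatients / nonpatient_attempts)
}

#' Threshold-based authentication use case
#'
#' Trains one verification network per patient (one-vs-rest over all
#' subjects' training windows) on detail-fusion features of the chosen
#' family. For each operating level `f` in `thresholds_pct`, the score
#' threshold is calibrated per patient model so that its FAR on the
#' training impostor scores equals `f` percent, and each attempt is
#' accepted when its score is at or above the calibrated threshold.
#' Attempts are seeded draws from the held-out test windows:
#' `attempts_per_patient` genuine attempts per patient and
#' `attempts_per_patient` attempts per (patient, non-patient) pair.
#'
#' @param cohort an `hrv_cohort` covering all configured subject ids.
#' @param usecase a [usecase_config()].
#' @param clf_config a [classifier_config()] (the use case default is 75
#'   hidden nodes; pass `classifier_config(hidden_nodes = 75)`).
#' @param family biorthogonal family (default `"bior1.1"`, the best
#'   performer of the fusion comparison).
#' @param subbands sub-bands fused for the verification features
#'   (default detail fusion `D1+D2+D3`).
#' @param seg_config a [segmentation_config()].
#' @param selection feature selection.
#' @return an object of class `auth_report`: a data.frame with one row
#'   per operating level and columns `threshold_pct`, `patients_accepted`,
#'   `patients_rejected`, `patient_success_rate`, `nonpatients_accepted`,
#'   `nonpatients_rejected`, `nonpatient_success_rate`, plus attributes
#'   `patient_attempts` and `nonpatient_attempts`.
#' @export
run_usecase <- function(cohort, usecase = usecase_config(),
                        clf_config = classifier_config(hidden_nodes = 75),
                        family = "bior1.1",
                        subbands = c("D1", "D2", "D3"),
                        seg_config = segmentation_config(),
                        selection = default_feature_selection()) {
  stopifnot(inherits(cohort, "hrv_cohort"), inherits(usecase, "usecase_config"))
  ids <- vapply(cohort$signals, `[[`, numeric(1), "subject_id")
  need <- c(usecase$patient_ids, usecase$nonpatient_ids)
  if (!all(need %in% ids)) {
    stop("cohort does not cover configured subject ids: ",
         paste(setdiff(need, ids), collapse = ", "))
  }
  segments <- segment_cohort(cohort, seg_config)
  segments <- segments[segments$subject_id %in% need, , drop = FALSE]
  decs <- decompose_segments(segments, family)
  feats <- extract_feature_table(decs, selection, subbands,
                                 seg_config$sampling_rate)
  split <- split_train_test(feats, clf_config)

  models <- lapply(usecase$patient_ids, function(pid) {
    train_subject_model(split$train, pid, clf_config)
  })
  names(models) <- as.character(usecase$patient_ids)

  # Per-model calibration scores: the model's view of non-target training
  # windows (its validation impostor distribution).
  cal <- lapply(models, function(m) {
    rows <- split$train$subject_id != m$subject_id
    score(m, split$train[rows, , drop = FALSE])
  })

  # Seeded attempt draws from held-out windows (with replacement when a
  # subject has fewer test windows than attempts).
  draw_rows <- function(sid, k, tag) {
    rows <- which(split$test$subject_id == sid)
    if (length(rows) == 0) stop("no test windows for subject ", sid)
    withr::with_seed(derive_seed(clf_config$seed, 30L, tag, sid),
                     rows[sample.int(length(rows), k, replace = k > length(rows))])
  }
  ap <- usecase$attempts_per_patient
  patient_scores <- unlist(lapply(usecase$patient_ids, function(pid) {
    score(models[[as.character(pid)]],
          split$test[draw_rows(pid, ap, pid), , drop = FALSE])
  }), use.names = FALSE)
  patient_model_of_score <- rep(usecase$patient_ids, each = ap)
  np_scores <- list()
  np_model_of_score <- list()
  for (pid in usecase$patient_ids) {
    for (nid in usecase$nonpatient_ids) {
      key <- paste(pid, nid)
      np_scores[[key]] <- score(models[[as.character(pid)]],
                                split$test[draw_rows(nid, ap, pid), ,
                                           drop = FALSE])
      np_model_of_score[[key]] <- rep(pid, ap)
    }
  }
  np_scores <- unlist(np_scores, use.names = FALSE)
  np_model_of_score <- unlist(np_model_of_score, use.names = FALSE)

  n_pat <- length(patient_scores)
  n_np <- length(np_scores)
  out <- lapply(usecase$thresholds_pct, function(f) {
    thr <- vapply(models, function(m) {
      as.numeric(quantile(cal[[as.character(m$subject_id)]],
                          probs = 1 - f / 100, type = 8))
    }, numeric(1))
    names(thr) <- names(models)
    acc_p <- sum(patient_scores >=
                   thr[as.character(patient_model_of_score)])
    acc_n <- sum(np_scores >= thr[as.character(np_model_of_score)])
    rates <- success_rates(acc_p, n_pat, acc_n, n_np)
    data.frame(threshold_pct = f,
               patients_accepted = acc_p,
               patients_rejected = n_pat - acc_p,
               patient_success_rate = rates[["patient_pct"]],
               nonpatients_accepted = acc_n,
               nonpatients_rejected = n_np - acc_n,
               nonpatient_success_rate = rates[["nonpatient_pct"]])
  })
  out <- do.call(rbind, out)
  structure(out, patient_attempts = n_pat, nonpatient_attempts = n_np,
            class = c("auth_report", "data.frame"))
}
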