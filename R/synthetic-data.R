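#' Cohort configuration for the HRV simulator
#'
#' Describes a simulated multi-subject HRV recording campaign: how many
#' subjects, how long each recording runs, the sampling rate of the
#' smartwatch-style HRV stream, the master seed, and a `separation` scalar
#' that controls how far apart the per-subject signal-generating parameters
#' are drawn (0 = every subject shares the same profile).
#'
#' @param n_subjects number of subjects (>= 2); the study scale is 30.
#' @param duration_s recording length per subject in seconds (study values:
#'   3600, 7200 or 14400). `duration_s * sampling_rate` must be a whole
#'   number of samples.
#' @param sampling_rate samples per second of the HRV stream (default 8).
#' @param seed master seed; every profile and signal derives from it.
#' @param separation non-negative scalar scaling the spread of per-subject
#'   profile parameters. The default of 1 is calibrated so a default cohort
#'   lands in the 5--25% fusion-EER regime typical of short-window HRV
#'   verification.
#' @return an object of class `cohort_config`.
#' @export
#' @examples
#' cohort_config(n_subjects = 3, duration_s = 300)
cohort_config <- function(n_subjects = 30, duration_s = 7200,
                          sampling_rate = 8, seed = 1, separation = 1) {
  if (!is.numeric(n_subjects) || n_subjects < 2) {
    stop("n_subjects must be >= 2")
  }
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop("duration_s must be positive")
  }
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be positive")
  }
  n_samples <- duration_s * sampling_rate
  if (abs(n_samples - round(n_samples)) > 1e-9) {
    stop("duration_s * sampling_rate must be a whole number of samples")
  }
  if (!is.numeric(separation) || separation < 0) {
    stop("separation must be >= 0")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      duration_s = duration_s,
      sampling_rate = sampling_rate,
      seed = as.integer(seed),
      separation = separation
    ),
    class = "cohort_config"
  )
}

# Population-level centres of the subject profile parameters.  Units are
# arbitrary "beats-per-minute-like" amplitude units; LF/HF frequencies sit
# at the canonical HRV band centres (~0.1 Hz and ~0.25 Hz).
.profile_centres <- list(
  baseline = 70, lf_amp = 3, lf_freq = 0.1, hf_amp = 2, hf_freq = 0.25,
  drift_scale = 0.2, noise_sd = 2
)

#' Draw one subject's signal-generating profile
#'
#' Profiles are deterministic in `(seed, subject_index)`: re-drawing the
#' same subject from the same config reproduces it bitwise, and drawing
#' subject k does not depend on having drawn subjects 1..k-1. The spread of
#' every parameter scales with `config$separation`; at `separation = 0` all
#' subjects share the population-centre profile exactly.
#'
#' @param config a [cohort_config()].
#' @param subject_index subject number in `1..n_subjects`.
#' @return an object of class `subject_profile` with fields `subject_id`,
#'   `baseline`, `lf_amp`, `lf_freq`, `hf_amp`, `hf_freq`, `drift_scale`
#'   and `noise_sd`.
#' @export
draw_profile <- function(config, subject_index) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.numeric(subject_index) || subject_index < 1 ||
      subject_index > config$n_subjects) {
    stop(sprintf("subject_index must be in 1..%d", config$n_subjects))
  }
  subject_index <- as.integer(subject_index)
  sep <- config$separation
  ctr <- .profile_centres
  z <- withr::with_seed(derive_seed(config$seed, 1L, subject_index),
                        rnorm(7))
  clamp <- function(x, lo, hi) min(max(x, lo), hi)
  prof <- list(
    subject_id  = subject_index,
    baseline    = ctr$baseline + sep * 6 * z[1],
    lf_amp      = ctr$lf_amp * exp(sep * 0.35 * z[2]),
    lf_freq     = clamp(ctr$lf_freq * exp(sep * 0.18 * z[3]), 0.05, 0.16),
    hf_amp      = ctr$hf_amp * exp(sep * 0.35 * z[4]),
    hf_freq     = clamp(ctr$hf_freq * exp(sep * 0.15 * z[5]), 0.18, 0.40),
    drift_scale = ctr$drift_scale * exp(sep * 0.25 * z[6]),
    noise_sd    = ctr$noise_sd * exp(sep * 0.7 * z[7])
  )
  stopifnot(prof$lf_freq < prof$hf_freq,
            prof$hf_freq < config$sampling_rate / 2)
  structure(prof, class = "subject_profile")
}

#' Synthesize one subject's HRV-like signal
#'
#' The signal model is
#' `baseline + lf_amp*sin(2*pi*lf_freq*t + phi_lf) +
#'  hf_amp*sin(2*pi*hf_freq*t + phi_hf) + drift + noise`,
#' where the LF/HF phases are drawn once per subject from the seeded
#' stream (with spread scaled by `config$separation`, like every other
#' between-subject degree of freedom), `drift` is a Gaussian random walk
#' normalised to amplitude
#' `drift_scale` over the recording (a bounded slow wander, so a subject's
#' identity is carried by the profile, not by where its walk happens to
#' sit), and `noise` is white Gaussian with standard deviation `noise_sd`.
#' Deterministic given `(config$seed, subject_id)`.
#'
#' @param profile a [draw_profile()] result (or a hand-built profile with
#'   the same fields).
#' @param config the [cohort_config()] providing duration, rate and seed.
#' @return an object of class `subject_signal` with fields `subject_id`,
#'   `sampling_rate` and `samples`.
#' @export
synthesize_signal <- function(profile, config) {
  stopifnot(inherits(config, "cohort_config"))
  req <- c("subject_id", "baseline", "lf_amp", "lf_freq", "hf_amp",
           "hf_freq", "drift_scale", "noise_sd")
  if (!all(req %in% names(profile))) {
    stop("profile is missing fields: ",
         paste(setdiff(req, names(profile)), collapse = ", "))
  }
  fs <- config$sampling_rate
  n <- as.integer(round(config$duration_s * fs))
  if (n <= 0) stop("duration_s and sampling_rate must be positive")

  draws <- withr::with_seed(
    derive_seed(config$seed, 2L, profile$subject_id),
    list(
      phi = 2 * pi * ((config$separation * runif(2)) %% 1),
      steps = rnorm(n),
      noise = rnorm(n)
    )
  )
  t <- (seq_len(n) - 1) / fs
  drift <- profile$drift_scale / sqrt(n) * cumsum(draws$steps)
  x <- profile$baseline +
    profile$lf_amp * sin(2 * pi * profile$lf_freq * t + draws$phi[1]) +
    profile$hf_amp * sin(2 * pi * profile$hf_freq * t + draws$phi[2]) +
    drift +
    profile$noise_sd * draws$noise
  structure(
    list(subject_id = profile$subject_id, sampling_rate = fs, samples = x),
    class = "subject_signal"
  )
}

#' Generate a full synthetic cohort
#'
#' Draws every subject's profile and synthesizes every signal from the
#' single cohort seed. Two calls with identical configs produce bitwise
#' identical cohorts.
#'
#' @param config a [cohort_config()].
#' @return an object of class `hrv_cohort`: a list with `config`,
#'   `profiles` (list of `subject_profile`) and `signals` (list of
#'   `subject_signal`).
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n_subjects = 2, duration_s = 60))
#' length(coh$signals[[1]]$samples)  # 480
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  profiles <- lapply(seq_len(config$n_subjects),
                     function(i) draw_profile(config, i))
  signals <- lapply(profiles, synthesize_signal, config = config)
  structure(list(config = config, profiles = profiles, signals = signals),
            class = "hrv_cohort")
}

#' @export
print.hrv_cohort <- function(x, ...) {
  cat(sprintf(
    "<hrv_cohort> %d subjects, %g s at %g Hz (%d samples each), seed %d, separation %g\n",
    x$config$n_subjects, x$config$duration_s, x$config$sampling_rate,
    length(x$signals[[1]]$samples), x$config$seed, x$config$separation))
  invisible(x)
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf(
    "<subject_profile> id %d: baseline %.2f, LF %.2f @ %.3f Hz, HF %.2f @ %.3f Hz, drift %.2f, noise sd %.2f\n",
    x$subject_id, x$baseline, x$lf_amp, x$lf_freq, x$hf_amp, x$hf_freq,
    x$drift_scale, x$noise_sd))
  invisible(x)
}

#' Write a cohort to disk as per-subject CSVs plus a JSON manifest
#'
#' Each subject is written as `subject_<id>.csv` with columns `t_s,value`;
#' `manifest.json` records the config and every profile.
#'
#' @param cohort an `hrv_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "hrv_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sig in cohort$signals) {
    t_s <- (seq_along(sig$samples) - 1) / sig$sampling_rate
    write.csv(data.frame(t_s = t_s, value = sig$samples),
              file.path(dir, sprintf("subject_%d.csv", sig$subject_id)),
              row.names = FALSE)
  }
  manifest <- list(
    config = unclass(cohort$config),
    profiles = lapply(cohort$profiles, unclass)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `manifest.json` and per-subject CSVs.
#' @return an `hrv_cohort`.
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  config <- do.call(cohort_config, manifest$config)
  profiles <- lapply(seq_len(nrow(manifest$profiles)), function(i) {
    structure(as.list(manifest$profiles[i, ]), class = "subject_profile")
  })
  signals <- lapply(profiles, function(p) {
    df <- read.csv(file.path(dir, sprintf("subject_%d.csv", p$subject_id)))
    structure(list(subject_id = p$subject_id,
                   sampling_rate = config$sampling_rate,
                   samples = df$value),
              class = "subject_signal")
  })
  structure(list(config = config, profiles = profiles, signals = signals),
            class = "hrv_cohort")
}
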