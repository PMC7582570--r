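#' Segmentation configuration
#'
#' Windows are short (default 3 s, i.e. 24 samples at 8 Hz) so that
#' authentication decisions are fast; window starts are spaced `stride_s`
#' seconds apart (default 24 s: one 3-s window per 24 s of recording, which
#' reproduces the study geometry of 150/300/600 windows for 3600/7200/14400
#' second recordings).
#'
#' @param window_s window length in seconds (> 0); `window_s *
#'   sampling_rate` must be an integer.
#' @param stride_s spacing between window starts in seconds (>= window_s).
#' @param sampling_rate samples per second (default 8).
#' @return an object of class `segmentation_config`.
#' @export
segmentation_config <- function(window_s = 3, stride_s = 24,
                                sampling_rate = 8) {
  if (!is.numeric(window_s) || window_s <= 0) stop("window_s must be > 0")
  if (!is.numeric(stride_s) || stride_s < window_s) {
    stop("stride_s must be >= window_s")
  }
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be positive")
  }
  ws <- window_s * sampling_rate
  if (abs(ws - round(ws)) > 1e-9) {
    stop("window_s * sampling_rate must be an integer number of samples")
  }
  structure(
    list(window_s = window_s, stride_s = stride_s,
         sampling_rate = sampling_rate,
         window_samples = as.integer(round(ws))),
    class = "segmentation_config"
  )
}

#' Number of full windows in a recording of given duration
#'
#' One window is taken per complete stride period: the k-th window starts
#' at `(k-1) * stride_s`, and the count is `floor(duration_s / stride_s)`
#' (a 7200-s recording at the 3 s / 24 s defaults yields 300 windows).
#' Because `stride_s >= window_s`, every counted window fits entirely
#' inside the recording; trailing partial periods are dropped, never
#' padded.
#'
#' @param duration_s recording duration in seconds (>= 0).
#' @param config a [segmentation_config()].
#' @return integer window count.
#' @export
#' @examples
#' count_segments(7200, segmentation_config())   # 300
#' count_segments(14400, segmentation_config())  # 600
count_segments <- function(duration_s, config = segmentation_config()) {
  stopifnot(inherits(config, "segmentation_config"))
  if (!is.numeric(duration_s) || duration_s < 0) {
    stop("duration_s must be >= 0")
  }
  as.integer(floor(duration_s / config$stride_s))
}

#' Slice a signal into fixed-length authentication windows
#'
#' Sample indexing is 0-based with half-open windows: the window starting
#' at `start_s` covers samples `[start_s*rate, start_s*rate + window_samples)`.
#' A signal shorter than one window yields zero rows (not an error).
#'
#' @param signal a `subject_signal` (or any list with `subject_id`,
#'   `sampling_rate`, `samples`).
#' @param config a [segmentation_config()]; its sampling rate must match
#'   the signal's.
#' @return a data.frame with columns `subject_id`, `start_s` and sample
#'   columns `s0 ... s<k-1>` (`k = window_samples`), one row per window.
#' @export
segment_signal <- function(signal, config = segmentation_config()) {
  stopifnot(inherits(config, "segmentation_config"))
  if (!all(c("subject_id", "sampling_rate", "samples") %in% names(signal))) {
    stop("signal must have subject_id, sampling_rate and samples")
  }
  if (abs(signal$sampling_rate - config$sampling_rate) > 1e-9) {
    stop("signal sampling_rate does not match segmentation config")
  }
  fs <- config$sampling_rate
  w <- config$window_samples
  duration_s <- length(signal$samples) / fs
  n_seg <- count_segments(duration_s, config)
  starts_s <- (seq_len(n_seg) - 1) * config$stride_s
  mat <- matrix(0, nrow = n_seg, ncol = w)
  for (i in seq_len(n_seg)) {
    i0 <- as.integer(round(starts_s[i] * fs))
    mat[i, ] <- signal$samples[(i0 + 1):(i0 + w)]
  }
  colnames(mat) <- paste0("s", seq_len(w) - 1)
  out <- data.frame(subject_id = rep(signal$subject_id, n_seg),
                    start_s = starts_s)
  cbind(out, as.data.frame(mat))
}

#' Segment every signal of a cohort
#'
#' @param cohort an `hrv_cohort`.
#' @param config a [segmentation_config()].
#' @return row-bound data.frame of [segment_signal()] outputs.
#' @export
segment_cohort <- function(cohort, config = segmentation_config()) {
  stopifnot(inherits(cohort, "hrv_cohort"))
  do.call(rbind, lapply(cohort$signals, segment_signal, config = config))
}

# Extract the sample matrix from a segment data.frame.
segment_matrix <- function(segments) {
  scols <- grep("^s[0-9]+$", names(segments), value = TRUE)
  as.matrix(segments[, scols, drop = FALSE])
}
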