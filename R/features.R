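#' Names of all computable window features
#'
#' @return character vector of the 14 feature names.
#' @export
feature_names <- function() {
  c("variance", "mean_energy", "min_energy", "max_energy", "mean",
    "min_amplitude", "std", "max_amplitude", "range", "peak2peak",
    "rms", "peak_mag_to_rms", "average_frequency", "mid_frequency")
}

#' The default 12-feature selection
#'
#' The screening experiment on first-level detail coefficients found the
#' minimum energy and the average frequency carried little between-subject
#' discrimination; the remaining 12 features are the default selection used
#' by every experiment runner.
#'
#' @return ordered character vector of 12 feature names.
#' @export
default_feature_selection <- function() {
  c("mean", "mean_energy", "variance", "min_amplitude", "max_energy",
    "std", "max_amplitude", "range", "peak2peak", "peak_mag_to_rms",
    "mid_frequency", "rms")
}

# One-sided periodogram (positive frequencies, DC excluded).
periodogram <- function(x, sampling_rate) {
  n <- length(x)
  k <- seq_len(n %/% 2)
  if (n < 2 || length(k) == 0) {
    return(list(freq = numeric(0), power = numeric(0)))
  }
  p <- Mod(fft(x))^2 / n
  list(freq = k * sampling_rate / n, power = p[k + 1])
}

#' Compute the statistical feature set of one window or sub-band
#'
#' Implements the window descriptors used throughout the pipeline:
#' population-convention variance and standard deviation, per-sample
#' energies `E_r = x_r^2` summarised by min/max and a Boltzmann-weighted
#' mean `sum(exp(-beta*E)*E) / sum(exp(-beta*E))` (`beta = 0` gives the
#' plain arithmetic mean of energies), amplitude extremes, range and
#' peak-to-peak (identical by construction; both kept because the standard
#' descriptor set lists both), root-mean-square, crest factor
#' (`max|x| / rms`), and two spectral summaries from the one-sided
#' periodogram: the power-weighted mean frequency (`average_frequency`)
#' and the median frequency below which half the spectral power lies
#' (`mid_frequency`), both 0 for signals with no power off DC.
#'
#' @param x non-empty numeric vector (window samples or sub-band
#'   coefficients).
#' @param sampling_rate sampling rate in Hz used for the spectral
#'   features; for level-k sub-band coefficients pass the decimated rate
#'   if physical frequencies are wanted (features are used comparatively,
#'   so a shared nominal rate is also fine).
#' @param beta Boltzmann weight for the energy mean (default 0).
#' @return named numeric vector over [feature_names()]. `peak_mag_to_rms`
#'   is `NA` (with a warning) when `rms` is 0.
#' @export
#' @examples
#' compute_features(c(1, 2, 3, 4), sampling_rate = 8)
compute_features <- function(x, sampling_rate = 8, beta = 0) {
  if (length(x) == 0) stop("compute_features: input must be non-empty")
  if (!all(is.finite(x))) stop("compute_features: input must be finite")
  if (!is.finite(beta)) stop("beta must be finite")
  n <- length(x)
  mu <- mean(x)
  e <- x^2
  w <- exp(-beta * e)
  rms <- sqrt(mean(e))
  if (rms > 0) {
    crest <- max(abs(x)) / rms
  } else {
    warning("rms is 0; peak_mag_to_rms is undefined and reported as NA")
    crest <- NA_real_
  }
  pg <- periodogram(x, sampling_rate)
  tot <- sum(pg$power)
  if (tot > 0) {
    avg_f <- sum(pg$freq * pg$power) / tot
    cum <- cumsum(pg$power)
    j <- which(cum >= tot / 2)[1]
    prev <- if (j > 1) cum[j - 1] else 0
    f_lo <- if (j > 1) pg$freq[j - 1] else 0
    mid_f <- f_lo + (tot / 2 - prev) / pg$power[j] * (pg$freq[j] - f_lo)
  } else {
    avg_f <- 0
    mid_f <- 0
  }
  c(
    variance = mean((x - mu)^2),
    mean_energy = sum(w * e) / sum(w),
    min_energy = min(e),
    max_energy = max(e),
    mean = mu,
    min_amplitude = min(x),
    std = sqrt(mean((x - mu)^2)),
    max_amplitude = max(x),
    range = max(x) - min(x),
    peak2peak = max(x) - min(x),
    rms = rms,
    peak_mag_to_rms = crest,
    average_frequency = avg_f,
    mid_frequency = mid_f
  )
}

#' Build a per-window feature table from decompositions
#'
#' For each decomposition and each requested sub-band, computes the
#' selected features and lays them out as one row per window with fused
#' columns named `<feature>_<subband>` (sub-band-major order: all selected
#' features of the first sub-band, then the second, ...).
#'
#' @param decompositions list of `wavelet_decomposition` sharing family
#'   and levels (e.g. from [decompose_segments()]).
#' @param selection ordered character vector of feature names (default
#'   [default_feature_selection()]).
#' @param subbands character vector from A1..A3, D1..D3 (default `"D3"`).
#' @param sampling_rate nominal rate passed to [compute_features()].
#' @param beta energy-mean weight, see [compute_features()].
#' @return data.frame with columns `subject_id`, `start_s`, `family` and
#'   `length(selection) * length(subbands)` feature columns.
#' @export
extract_feature_table <- function(decompositions,
                                  selection = default_feature_selection(),
                                  subbands = "D3",
                                  sampling_rate = 8, beta = 0) {
  if (length(decompositions) == 0) {
    cols <- as.vector(t(outer(subbands, selection,
                              function(s, f) paste0(f, "_", s))))
    out <- as.data.frame(matrix(numeric(0), nrow = 0,
                                ncol = 3 + length(cols)))
    names(out) <- c("subject_id", "start_s", "family", cols)
    return(out)
  }
  bad <- setdiff(selection, feature_names())
  if (length(bad) > 0) {
    stop("unknown feature names: ", paste(bad, collapse = ", "))
  }
  fam <- unique(vapply(decompositions, `[[`, "", "family"))
  if (length(fam) != 1) stop("decompositions must share one family")
  per_band <- lapply(subbands, function(sb) {
    level <- substring(sb, 2)
    kind <- substring(sb, 1, 1)
    rows <- t(vapply(decompositions, function(d) {
      bands <- if (kind == "A") d$A else d$D
      if (!sb %in% names(bands)) {
        stop(sprintf("subband %s not present in decomposition (levels %d)",
                     sb, d$levels))
      }
      compute_features(bands[[sb]], sampling_rate, beta)[selection]
    }, numeric(length(selection))))
    colnames(rows) <- paste0(selection, "_", sb)
    as.data.frame(rows)
  })
  meta <- data.frame(
    subject_id = vapply(decompositions, `[[`, numeric(1), "subject_id"),
    start_s = vapply(decompositions, `[[`, numeric(1), "start_s"),
    family = fam
  )
  do.call(cbind, c(list(meta), per_band))
}

#' Feature-level fusion of sub-band tables
#'
#' Column-binds per-sub-band feature tables that describe the same windows
#' in the same order; the shared metadata columns (`subject_id`,
#' `start_s`, `family`) are kept once.
#'
#' @param tables list of [extract_feature_table()] data.frames.
#' @return one fused data.frame with the row count preserved.
#' @export
fuse_subbands <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1)
  n <- nrow(tables[[1]])
  meta_cols <- intersect(c("subject_id", "start_s", "family"),
                         names(tables[[1]]))
  for (tb in tables[-1]) {
    if (nrow(tb) != n) stop("fuse_subbands: row-count mismatch")
    if (length(meta_cols) > 0 && n > 0 &&
        !isTRUE(all.equal(tb[meta_cols[1]], tables[[1]][meta_cols[1]],
                          check.attributes = FALSE))) {
      stop("fuse_subbands: tables describe different windows")
    }
  }
  feats <- lapply(tables, function(tb) {
    tb[, setdiff(names(tb), meta_cols), drop = FALSE]
  })
  do.call(cbind, c(list(tables[[1]][, meta_cols, drop = FALSE]), feats))
}

# Names of the feature columns of a feature table.
feature_columns <- function(features) {
  setdiff(names(features), c("subject_id", "start_s", "family"))
}

#' Write / read a feature table CSV
#'
#' @param features an [extract_feature_table()] data.frame.
#' @param path CSV path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_features <- function(features, path) {
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) read.csv(path)
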