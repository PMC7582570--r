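#' Biorthogonal wavelet family names supported by the package
#'
#' @return character vector of the 15 spline biorthogonal family members.
#' @export
bior_families <- function() names(.bior_filters)

# Trim leading/trailing zeros of a filter to its true support.
trim_filter <- function(v) {
  nz <- which(abs(v) > 0)
  v[nz[1]:nz[length(nz)]]
}

#' Look up the four filters of a biorthogonal family member
#'
#' Returns the standard spline (CDF) biorthogonal filter bank: analysis
#' low/high-pass (`lo_d`, `hi_d`) and synthesis low/high-pass (`lo_r`,
#' `hi_r`), trimmed to their true support. Internally the transform uses
#' the same filters zero-padded to a common even length
#' (`filter_length`) so that the analysis/synthesis lattices stay aligned
#' and approximation/detail outputs have equal length. Filters are
#' normalised so `sum(lo_d) = sqrt(2)`.
#'
#' @param family one of [bior_families()] (case-insensitive, e.g.
#'   `"bior1.1"` or `"Bior4.4"`).
#' @return an object of class `wavelet_filter_bank` with fields `family`,
#'   `lo_d`, `hi_d`, `lo_r`, `hi_r`, `filter_length` and `padded` (the
#'   aligned filters actually convolved).
#' @export
#' @examples
#' fb <- get_filter_bank("bior1.1")
#' fb$lo_d  # c(1, 1) / sqrt(2)
get_filter_bank <- function(family) {
  if (!is.character(family) || length(family) != 1) {
    stop("family must be a single family name")
  }
  key <- tolower(family)
  if (!key %in% names(.bior_filters)) {
    stop(sprintf("unknown wavelet family '%s'; valid families: %s",
                 family, paste(names(.bior_filters), collapse = ", ")))
  }
  padded <- .bior_filters[[key]]
  structure(
    list(
      family = key,
      lo_d = trim_filter(padded$lo_d),
      hi_d = trim_filter(padded$hi_d),
      lo_r = trim_filter(padded$lo_r),
      hi_r = trim_filter(padded$hi_r),
      filter_length = length(padded$lo_d),
      padded = padded
    ),
    class = "wavelet_filter_bank"
  )
}

#' @export
print.wavelet_filter_bank <- function(x, ...) {
  cat(sprintf(
    "<wavelet_filter_bank> %s: lo_d %d taps, hi_d %d taps, lo_r %d taps, hi_r %d taps (aligned length %d)\n",
    x$family, length(x$lo_d), length(x$hi_d), length(x$lo_r),
    length(x$hi_r), x$filter_length))
  invisible(x)
}

# Half-sample symmetric extension indices: 1-based indices into x for an
# extension of e samples on each side.  The modulo folding handles
# extensions longer than the signal (repeated reflections).
sym_ext_index <- function(n, e) {
  idx <- (-e):(n + e - 1)          # 0-based positions into the extended axis
  m <- idx %% (2 * n)
  ifelse(m < n, m, 2 * n - 1 - m) + 1
}

# Full (open) convolution.
conv_full <- function(x, h) {
  nx <- length(x)
  out <- numeric(nx + length(h) - 1)
  for (i in seq_along(h)) {
    if (h[i] != 0) {
      out[i:(i + nx - 1)] <- out[i:(i + nx - 1)] + h[i] * x
    }
  }
  out
}

#' One analysis step of the discrete wavelet transform
#'
#' Extends the input half-sample symmetrically by `filter_length - 1` on
#' each side, convolves with the aligned analysis filters, and keeps every
#' second coefficient. Both outputs have length
#' `floor((n + filter_length - 1) / 2)`.
#'
#' @param x non-empty numeric input.
#' @param bank a [get_filter_bank()] result.
#' @return list with `approx` and `detail` coefficient vectors.
#' @export
dwt_step <- function(x, bank) {
  stopifnot(inherits(bank, "wavelet_filter_bank"))
  if (length(x) == 0) stop("dwt_step: input must be non-empty")
  if (!all(is.finite(x))) stop("dwt_step: input must be finite")
  n <- length(x)
  F <- bank$filter_length
  L <- (n + F - 1) %/% 2
  ext <- x[sym_ext_index(n, F - 1)]
  keep <- seq(F + 1, by = 2, length.out = L)
  list(
    approx = conv_full(ext, bank$padded$lo_d)[keep],
    detail = conv_full(ext, bank$padded$hi_d)[keep]
  )
}

#' One synthesis step of the discrete wavelet transform
#'
#' Upsamples both coefficient vectors, convolves with the aligned
#' synthesis filters, sums, and crops the boundary so that
#' `idwt_step(dwt_step(x, fb), fb, length(x))` reproduces `x` (perfect
#' reconstruction, the defining biorthogonality property).
#'
#' @param approx,detail equal-length coefficient vectors.
#' @param bank a [get_filter_bank()] result.
#' @param n_out length of the reconstructed signal.
#' @return numeric vector of length `n_out`.
#' @export
idwt_step <- function(approx, detail, bank, n_out) {
  stopifnot(inherits(bank, "wavelet_filter_bank"))
  if (length(approx) != length(detail)) {
    stop("approx and detail must have equal length")
  }
  L <- length(approx)
  F <- bank$filter_length
  full_len <- 2 * L - F + 2
  if (n_out > full_len) {
    stop(sprintf("n_out (%d) exceeds reconstructable length (%d)",
                 n_out, full_len))
  }
  up <- function(cv) {
    u <- numeric(2 * L - 1)
    u[seq(1, by = 2, length.out = L)] <- cv
    u
  }
  s <- conv_full(up(approx), bank$padded$lo_r) +
    conv_full(up(detail), bank$padded$hi_r)
  start <- F - 1                    # 1-based: drop F - 2 boundary samples
  s[start:(start + n_out - 1)]
}

#' Multi-level (Mallat cascade) decomposition of a window
#'
#' Level 1 coefficients `A1`/`D1` are computed from the raw window, `A2`/`D2`
#' from `A1`, and `A3`/`D3` from `A2`.
#'
#' @param x numeric window of samples (e.g. one row of
#'   [segment_signal()] output), at least `filter_length` samples long.
#' @param family a biorthogonal family name, see [bior_families()].
#' @param levels number of cascade levels (default 3).
#' @param subject_id,start_s optional window metadata carried through to
#'   feature extraction.
#' @return an object of class `wavelet_decomposition` with fields
#'   `family`, `levels`, `A` (list `A1..A<levels>`), `D` (list
#'   `D1..D<levels>`), `subject_id`, `start_s`.
#' @export
#' @examples
#' d <- decompose(sin(1:24), "bior1.1")
#' lengths(d$A)  # 12 6 3
decompose <- function(x, family, levels = 3, subject_id = NA,
                      start_s = NA) {
  bank <- get_filter_bank(family)
  if (length(x) < bank$filter_length) {
    stop(sprintf(
      "window of %d samples is too short for family %s: minimum length is %d",
      length(x), bank$family, bank$filter_length))
  }
  A <- vector("list", levels)
  D <- vector("list", levels)
  cur <- as.numeric(x)
  for (k in seq_len(levels)) {
    step <- dwt_step(cur, bank)
    A[[k]] <- step$approx
    D[[k]] <- step$detail
    cur <- step$approx
  }
  names(A) <- paste0("A", seq_len(levels))
  names(D) <- paste0("D", seq_len(levels))
  structure(
    list(family = bank$family, levels = levels, A = A, D = D,
         subject_id = as.numeric(subject_id), start_s = as.numeric(start_s)),
    class = "wavelet_decomposition"
  )
}

#' Decompose every window of a segment table
#'
#' @param segments a [segment_signal()] / [segment_cohort()] data.frame.
#' @param family biorthogonal family name.
#' @param levels cascade depth (default 3).
#' @return list of `wavelet_decomposition`, one per row, carrying each
#'   row's `subject_id` and `start_s`.
#' @export
decompose_segments <- function(segments, family, levels = 3) {
  mat <- segment_matrix(segments)
  lapply(seq_len(nrow(mat)), function(i) {
    decompose(mat[i, ], family, levels,
              subject_id = segments$subject_id[i],
              start_s = segments$start_s[i])
  })
}

#' Flatten a decomposition to long format
#'
#' One row per coefficient with columns `subject_id`, `start_s`, `family`,
#' `subband` (A1..A3, D1..D3), `index`, `value` — the long CSV layout used
#' for coefficient export.
#'
#' @param x a `wavelet_decomposition`.
#' @param row.names,optional,... standard [as.data.frame()] arguments
#'   (unused).
#' @return a data.frame.
#' @export
as.data.frame.wavelet_decomposition <- function(x, row.names = NULL,
                                                optional = FALSE, ...) {
  sub <- c(x$A, x$D)
  do.call(rbind, lapply(names(sub), function(nm) {
    data.frame(subject_id = x$subject_id, start_s = x$start_s,
               family = x$family, subband = nm,
               index = seq_along(sub[[nm]]), value = sub[[nm]])
  }))
}

#' @export
print.wavelet_decomposition <- function(x, ...) {
  cat(sprintf("<wavelet_decomposition> %s, %d levels; lengths A: %s; D: %s\n",
              x$family, x$levels,
              paste(lengths(x$A), collapse = "/"),
              paste(lengths(x$D), collapse = "/")))
  invisible(x)
}
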