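# Independent brute-force oracles: deliberately naive (explicit loops,
# no shared code with the implementation under test).

# Half-sample symmetric extension by e samples each side, via explicit
# repeated reflection.
oracle_sym_ext <- function(x, e) {
  n <- length(x)
  sapply((-e):(n + e - 1), function(p) {
    m <- p %% (2 * n)
    if (m < 0) m <- m + 2 * n
    if (m < n) x[m + 1] else x[2 * n - m]
  })
}

# One analysis step: extend, convolve (explicit double loop), keep every
# second coefficient starting at position filter_length (0-based).
oracle_dwt <- function(x, lo_d, hi_d) {
  stopifnot(length(lo_d) == length(hi_d))
  F <- length(lo_d)
  n <- length(x)
  ext <- oracle_sym_ext(x, F - 1)
  conv <- function(h) {
    out <- numeric(length(ext) + F - 1)
    for (k in seq_along(out)) {
      acc <- 0
      for (j in seq_len(F)) {
        i <- k - j + 1
        if (i >= 1 && i <= length(ext)) acc <- acc + h[j] * ext[i]
      }
      out[k] <- acc
    }
    out
  }
  L <- (n + F - 1) %/% 2
  keep <- F + 1 + 2 * (seq_len(L) - 1)
  list(approx = conv(lo_d)[keep], detail = conv(hi_d)[keep])
}

# Feature oracle: plain loops and a naive DFT.
oracle_features <- function(x, fs, beta = 0) {
  n <- length(x)
  mu <- 0
  for (v in x) mu <- mu + v / n
  va <- 0
  for (v in x) va <- va + (v - mu)^2 / n
  e <- x^2
  wsum <- 0
  wesum <- 0
  for (v in e) {
    w <- exp(-beta * v)
    wsum <- wsum + w
    wesum <- wesum + w * v
  }
  ms <- 0
  for (v in x) ms <- ms + v^2 / n
  rms <- sqrt(ms)
  # naive DFT periodogram, positive freqs excluding DC
  ks <- seq_len(n %/% 2)
  pow <- numeric(length(ks))
  for (idx in seq_along(ks)) {
    k <- ks[idx]
    re <- 0
    im <- 0
    for (t in 0:(n - 1)) {
      ang <- -2 * pi * k * t / n
      re <- re + x[t + 1] * cos(ang)
      im <- im + x[t + 1] * sin(ang)
    }
    pow[idx] <- (re^2 + im^2) / n
  }
  freqs <- ks * fs / n
  tot <- sum(pow)
  if (length(pow) > 0 && tot > 0) {
    avg_f <- sum(freqs * pow) / tot
    cum <- 0
    j <- 0
    repeat {
      j <- j + 1
      cum <- cum + pow[j]
      if (cum >= tot / 2) break
    }
    prev <- cum - pow[j]
    f_lo <- if (j > 1) freqs[j - 1] else 0
    mid_f <- f_lo + (tot / 2 - prev) / pow[j] * (freqs[j] - f_lo)
  } else {
    avg_f <- 0
    mid_f <- 0
  }
  c(variance = va, mean_energy = wesum / wsum, min_energy = min(e),
    max_energy = max(e), mean = mu, min_amplitude = min(x),
    std = sqrt(va), max_amplitude = max(x), range = max(x) - min(x),
    peak2peak = max(x) - min(x), rms = rms,
    peak_mag_to_rms = if (rms > 0) max(abs(x)) / rms else NA_real_,
    average_frequency = avg_f, mid_frequency = mid_f)
}

# EER oracle: exhaustive sweep over all midpoints between consecutive
# distinct pooled scores (plus outer thresholds), then interpolate the
# FAR/FRR crossing between the bracketing sweep points.
oracle_eer <- function(genuine, impostor) {
  s <- sort(unique(c(genuine, impostor)))
  mids <- if (length(s) > 1) (s[-1] + s[-length(s)]) / 2 else numeric(0)
  thr <- sort(unique(c(s[1] - 1, s, mids, s[length(s)] + 1)))
  far <- sapply(thr, function(t) sum(impostor >= t) / length(impostor))
  frr <- sapply(thr, function(t) sum(genuine < t) / length(genuine))
  d <- far - frr
  j <- which(d <= 0)[1]
  if (is.na(j)) return(100 * far[length(far)])
  if (j == 1 || d[j] == 0) return(100 * far[j])
  a <- d[j - 1] / (d[j - 1] - d[j])
  100 * (far[j - 1] + a * (far[j] - far[j - 1]))
}

# Small cohorts shared by the statistical tests.
tiny_cohort <- function(seed = 1, n_subjects = 3, duration_s = 300,
                        separation = 1) {
  generate_cohort(cohort_config(n_subjects = n_subjects,
                                duration_s = duration_s, seed = seed,
                                separation = separation))
}
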