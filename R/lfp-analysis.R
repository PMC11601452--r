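# Theta-band LFP analysis: filtering, Morlet spectrograms, normalized
# spatial frames, electrode lag matrices and lag clustering.

#' Zero-phase Butterworth band-pass filter
#'
#' Fourth-order Butterworth applied forward and backward (`filtfilt`) so the
#' output has no group delay — essential when the filtered signal feeds
#' wave-timing analyses.
#'
#' @param trace Numeric vector.
#' @param low_hz,high_hz Band edges in Hz.
#' @param sample_rate Sampling rate in Hz.
#' @param order Filter order (default 4).
#' @return Filtered numeric vector.
#' @export
bandpass <- function(trace, low_hz, high_hz, sample_rate, order = 4) {
  ny <- sample_rate / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < ny)) {
    abort("Band must satisfy 0 < low < high < Nyquist.")
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / ny, type = "pass")
  as.numeric(signal::filtfilt(bf, as.numeric(trace)))
}

# Theta-filter every electrode of an lfp_recording; returns electrodes x
# samples matrix.
theta_filter <- function(lfp, band = c(4, 8)) {
  out <- t(apply(lfp$traces, 1, bandpass, low_hz = band[1], high_hz = band[2],
                 sample_rate = lfp$sample_rate))
  if (nrow(lfp$traces) == 1L) out <- matrix(out, nrow = 1)
  out
}

#' Continuous wavelet transform spectrogram
#'
#' Complex Morlet CWT (unit bandwidth and centre frequency, the `cmor1-1`
#' convention) over a logarithmic frequency grid covering the conventional
#' LFP sub-bands: delta (0.5-4 Hz), theta (4-8), alpha (8-13), beta (13-30),
#' gamma (30-50). Power is the squared coefficient magnitude, Gaussian
#' smoothed. The input is expected to be a broadband (0.1-100 Hz) trace at
#' ~1 kHz; see [downsample_lfp()].
#'
#' @param trace Numeric vector.
#' @param sample_rate Sampling rate in Hz.
#' @param freq_lim Frequency range in Hz (default `c(0.5, 50)`).
#' @param n_freqs Number of logarithmically spaced frequencies (default 60).
#' @param smoothing_sigma Gaussian smoothing SD in bins applied to the power
#'   map in both axes (default 2).
#' @param time_step Keep every `time_step`-th sample of the power map
#'   (default 1).
#' @return Object of class `cwt_spectrogram`: list with `power`
#'   (frequencies x time), `freqs_hz`, `times_s`. Use `tidy()` for a long
#'   tibble.
#' @export
spectrogram_cwt <- function(trace, sample_rate, freq_lim = c(0.5, 50),
                            n_freqs = 60, smoothing_sigma = 2,
                            time_step = 1) {
  trace <- as.numeric(trace)
  n <- length(trace)
  freqs <- exp(seq(log(freq_lim[1]), log(freq_lim[2]), length.out = n_freqs))
  # Morlet at frequency f: envelope SD 1/(f*sqrt(2)) seconds, support 4 SD
  max_half <- ceiling(4 / (min(freqs) * sqrt(2)) * sample_rate)
  if (n <= 2 * max_half) {
    abort("Trace shorter than the largest wavelet support; need a longer window.")
  }
  nfft <- stats::nextn(n + 2 * max_half + 1, 2)
  ft <- fft(c(trace, rep(0, nfft - n)))
  keep <- seq(1L, n, by = as.integer(time_step))
  power <- matrix(NA_real_, nrow = n_freqs, ncol = length(keep))
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    half <- ceiling(4 / (f * sqrt(2)) * sample_rate)
    tt <- (-half:half) / sample_rate
    psi <- sqrt(f) * pi^(-0.5) * exp(-(tt * f)^2) * exp(2i * pi * f * tt)
    psi <- psi / sqrt(sum(Mod(psi)^2))  # unit L2 norm per scale
    kf <- fft(c(psi, rep(0, nfft - length(psi))))
    conv <- fft(ft * kf, inverse = TRUE) / nfft
    coef <- conv[half + keep]
    power[i, ] <- Mod(coef)^2
  }
  if (smoothing_sigma > 0) power <- gauss_smooth2d(power, smoothing_sigma)
  structure(list(power = power, freqs_hz = freqs,
                 times_s = (keep - 1) / sample_rate),
            class = "cwt_spectrogram")
}

#' @export
print.cwt_spectrogram <- function(x, ...) {
  cat(sprintf("<cwt_spectrogram> %d freqs (%.2g-%.2g Hz) x %d time bins\n",
              length(x$freqs_hz), min(x$freqs_hz), max(x$freqs_hz),
              length(x$times_s)))
  invisible(x)
}

#' @rdname spectrogram_cwt
#' @param x A `cwt_spectrogram`.
#' @param ... Unused.
#' @export
tidy.cwt_spectrogram <- function(x, ...) {
  tibble(time_s = rep(x$times_s, each = length(x$freqs_hz)),
         freq_hz = rep(x$freqs_hz, times = length(x$times_s)),
         power = as.numeric(x$power))
}

#' Normalized theta-band spatial frames
#'
#' Band-passes every electrode in the theta band, then normalizes each
#' electrode's trace to `[-1, 1]` by its own maximum absolute value over the
#' analysis window (an all-zero electrode stays zero). Frames are sampled at
#' a fixed step (default 5 ms), matching the cadence of the wave-activity
#' videos.
#'
#' @param lfp An [lfp_recording()].
#' @param window Optional `c(start, end)` window in seconds (default whole
#'   recording).
#' @param step_ms Frame step in milliseconds (default 5).
#' @param band Theta band in Hz (default `c(4, 8)`).
#' @return Object of class `theta_frames`: list with `values` (electrodes x
#'   frames, in `[-1, 1]`), `times_s`, `electrodes` tibble. `tidy()` gives a
#'   long tibble for plotting.
#' @export
theta_frames <- function(lfp, window = NULL, step_ms = 5, band = c(4, 8)) {
  stopifnot(inherits(lfp, "lfp_recording"))
  if (!is.null(window)) {
    if (diff(window) <= 0) abort("Empty window.")
    lfp <- crop_lfp(lfp, window[1], window[2])
    t0 <- window[1]
  } else {
    t0 <- 0
  }
  th <- theta_filter(lfp, band)
  mx <- apply(abs(th), 1, max)
  scale <- ifelse(mx > 0, mx, 1)  # all-zero electrodes stay zero
  th <- th / scale
  step <- max(1L, round(step_ms / 1000 * lfp$sample_rate))
  idx <- seq(1L, ncol(th), by = step)
  structure(list(values = th[, idx, drop = FALSE],
                 times_s = t0 + (idx - 1) / lfp$sample_rate,
                 electrodes = lfp$electrodes),
            class = "theta_frames")
}

#' @export
print.theta_frames <- function(x, ...) {
  cat(sprintf("<theta_frames> %d electrodes x %d frames (%.3f-%.3f s)\n",
              nrow(x$values), ncol(x$values), min(x$times_s), max(x$times_s)))
  invisible(x)
}

#' @rdname theta_frames
#' @param x A `theta_frames` object.
#' @param ... Unused.
#' @export
tidy.theta_frames <- function(x, ...) {
  nf <- ncol(x$values)
  ne <- nrow(x$values)
  tibble(time_s = rep(x$times_s, each = ne),
         electrode_id = rep(x$electrodes$electrode_id, times = nf),
         x_um = rep(x$electrodes$x_um, times = nf),
         y_um = rep(x$electrodes$y_um, times = nf),
         value = as.numeric(x$values))
}

#' Pairwise theta-wave lag matrix
#'
#' For every electrode pair, finds the delay (within `max_lag_ms`) that
#' maximizes the cross-correlation of the two traces. Correlation at lag
#' `tau` is the mean product of the globally mean-centred, variance-scaled
#' traces over their overlap. `lag[i, j] > 0` means electrode `j` lags
#' (repeats later than) electrode `i`; the matrix is antisymmetric when the
#' maximizer is unique. Ties are broken toward the smallest `|lag|`, then
#' toward the negative lag.
#'
#' `method = "abs"` maximizes the absolute correlation; `method = "signed"`
#' maximizes the signed correlation, which maps anticorrelated (antiphase)
#' electrode pairs to the window edge instead of collapsing them to zero lag
#' — see the methods vignette for when each is appropriate.
#'
#' @param traces Electrodes x samples numeric matrix (theta-filtered), or an
#'   [lfp_recording()].
#' @param sample_rate Sampling rate in Hz (taken from the recording if one
#'   is supplied).
#' @param max_lag_ms Lag window in ms (default 40).
#' @param method `"abs"` (default) or `"signed"`.
#' @return Object of class `lag_matrix`: list with `lags_ms` (square
#'   matrix), `electrode_ids`, `max_lag_ms`, `method`.
#' @export
lag_matrix <- function(traces, sample_rate = NULL, max_lag_ms = 40,
                       method = c("abs", "signed")) {
  method <- match.arg(method)
  ids <- NULL
  if (inherits(traces, "lfp_recording")) {
    sample_rate <- traces$sample_rate
    ids <- traces$electrodes$electrode_id
    traces <- traces$traces
  }
  stopifnot(is.matrix(traces))
  if (is.null(sample_rate)) abort("`sample_rate` is required for a bare matrix.")
  ne <- nrow(traces)
  if (ne < 2) abort("Need at least two electrodes.")
  if (is.null(ids)) ids <- rownames(traces) %||% paste0("e", seq_len(ne))
  n <- ncol(traces)
  L <- round(max_lag_ms / 1000 * sample_rate)
  if (L >= n) abort("Traces shorter than the lag window.")
  lags_samp <- -L:L
  # order of preference for ties: smallest |lag|, then negative
  tie_rank <- order(abs(lags_samp), lags_samp)
  xc <- traces - rowMeans(traces)
  sds <- sqrt(rowMeans(xc^2))
  nfft <- stats::nextn(2 * n, 2)
  FT <- t(apply(xc, 1, function(v) fft(c(v, rep(0, nfft - n)))))
  lagm <- matrix(0, ne, ne)
  zero_warned <- FALSE
  overlap <- n - abs(lags_samp)
  for (i in seq_len(ne - 1)) {
    for (j in (i + 1):ne) {
      if (sds[i] == 0 || sds[j] == 0) {
        if (!zero_warned) {
          warn("All-zero trace in a pair; lag defined as 0.")
          zero_warned <- TRUE
        }
        next
      }
      # S(tau) = sum_t x_i[t] * x_j[t + tau]
      conv <- Re(fft(FT[i, ] * Conj(FT[j, ]), inverse = TRUE)) / nfft
      s_pos <- conv[1:(L + 1)]              # m = 0..L of sum x_i[t+m] x_j[t]
      s_neg <- conv[(nfft - L + 1):nfft]    # m = -L..-1
      # r(tau) = sum_t x_i[t] x_j[t+tau]: a copy of i delayed by d in j
      # maximizes r at tau = +d, matching lag(i,j) = +d ("j lags i")
      S <- rev(c(s_neg, s_pos))
      r <- S / (overlap * sds[i] * sds[j])
      score <- if (method == "abs") abs(r) else r
      best <- tie_rank[which.max(score[tie_rank])]
      lagm[i, j] <- lags_samp[best] / sample_rate * 1000
      lagm[j, i] <- -lagm[i, j]
    }
  }
  dimnames(lagm) <- list(ids, ids)
  structure(list(lags_ms = lagm, electrode_ids = ids,
                 max_lag_ms = max_lag_ms, method = method),
            class = "lag_matrix")
}

#' @export
print.lag_matrix <- function(x, ...) {
  cat(sprintf("<lag_matrix> %d electrodes, window +/-%g ms, method %s\n",
              length(x$electrode_ids), x$max_lag_ms, x$method))
  invisible(x)
}

#' K-means clustering of electrodes by wave lag
#'
#' Clusters the rows of a [lag_matrix()] with k-means (fixed seed, multiple
#' restarts). By default rows are taken in absolute value: the magnitude of
#' a pair's delay carries the wave-timing offset, while the sign of a
#' near-tied maximizer is noise-dominated for oscillatory signals.
#'
#' @param lags A `lag_matrix`.
#' @param k Number of clusters (default 2, one per wavefront mode).
#' @param seed RNG seed for the k-means restarts.
#' @param nstart Number of random restarts (default 10).
#' @param use_abs Cluster on `|lag|` rows (default `TRUE`).
#' @return Tibble with `electrode_id`, `cluster`; attributes `inertia`
#'   (total within-cluster sum of squares) and `degenerate` (all-equal
#'   rows).
#' @export
cluster_electrodes <- function(lags, k = 2, seed = 1, nstart = 10,
                               use_abs = TRUE) {
  stopifnot(inherits(lags, "lag_matrix"))
  m <- lags$lags_ms
  if (k > nrow(m)) abort("More clusters than electrodes.")
  if (use_abs) m <- abs(m)
  degenerate <- all(abs(m - m[1, 1]) < 1e-12) ||
    max(apply(m, 2, function(col) diff(range(col)))) < 1e-12
  if (degenerate) {
    out <- tibble(electrode_id = lags$electrode_ids,
                  cluster = rep_len(seq_len(k), nrow(m)))
    attr(out, "inertia") <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  km <- kmeans(m, centers = k, nstart = nstart)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  out <- tibble(electrode_id = lags$electrode_ids,
                cluster = as.integer(km$cluster))
  attr(out, "inertia") <- km$tot.withinss
  attr(out, "degenerate") <- FALSE
  out
}

#' Stage-level electrode clustering by theta-wave timing
#'
#' Convenience wrapper used by the pipeline: theta-filters the recording
#' over a window, computes the pairwise lag matrix with signed-correlation
#' maximization (so antiphase standing-wave halves are separable; see the
#' methods vignette), and k-means clusters the electrodes.
#'
#' @param lfp An [lfp_recording()].
#' @param window Optional `c(start, end)` seconds.
#' @param band Theta band (default 4-8 Hz).
#' @param max_lag_ms Lag window (default 40 ms).
#' @param k Clusters (default 2).
#' @param seed RNG seed.
#' @return As [cluster_electrodes()], with the `lag_matrix` attached as
#'   attribute `lags`.
#' @export
theta_lag_clusters <- function(lfp, window = NULL, band = c(4, 8),
                               max_lag_ms = 40, k = 2, seed = 1) {
  stopifnot(inherits(lfp, "lfp_recording"))
  if (!is.null(window)) lfp <- crop_lfp(lfp, window[1], window[2])
  th <- theta_filter(lfp, band)
  rownames(th) <- lfp$electrodes$electrode_id
  lm <- lag_matrix(th, sample_rate = lfp$sample_rate, max_lag_ms = max_lag_ms,
                   method = "signed")
  out <- cluster_electrodes(lm, k = k, seed = seed)
  out <- left_join(out, lfp$electrodes, by = "electrode_id")
  attr(out, "lags") <- lm
  out
}
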