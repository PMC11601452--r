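# Spike-theta phase locking: analytic signal, envelope-gated spike phases,
# per-unit Rayleigh statistics, phase-difference heatmaps and the Kuiper
# cluster comparison.

#' Instantaneous phase and envelope via the analytic signal
#'
#' Computes the analytic signal of a (theta-band-filtered) trace with the
#' FFT-based Hilbert transform; the phase is the angle between real and
#' imaginary parts, the envelope the magnitude.
#'
#' @param theta_trace Band-passed numeric vector.
#' @return Tibble with columns `phase` (radians, (-pi, pi]) and `envelope`.
#' @export
phase_and_envelope <- function(theta_trace) {
  x <- as.numeric(theta_trace)
  n <- length(x)
  if (n < 2 || diff(range(x)) == 0) {
    abort("Constant trace: phase is undefined.")
  }
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  z <- fft(X * h, inverse = TRUE) / n
  tibble(phase = wrap_angle(Arg(z)), envelope = Mod(z))
}

#' Envelope-gated spike phases
#'
#' Keeps the spikes that occur while the theta envelope exceeds the RMS of
#' the whole theta trace (i.e. during genuine theta epochs) and returns
#' their instantaneous phases.
#'
#' @param spike_times Spike times in seconds.
#' @param phase,envelope Phase/envelope series from [phase_and_envelope()].
#' @param sample_rate Sampling rate of the series in Hz.
#' @param theta_rms RMS of the theta trace used for gating. If `NULL`, it is
#'   reconstructed as the RMS of `envelope * cos(phase)`.
#' @return Tibble `time_s`, `phase` of the retained spikes (possibly
#'   empty).
#' @export
gated_spike_phases <- function(spike_times, phase, envelope, sample_rate,
                               theta_rms = NULL) {
  spike_times <- as.numeric(spike_times)
  if (is.null(theta_rms)) {
    theta_rms <- sqrt(mean((envelope * cos(phase))^2))
  }
  idx <- round(spike_times * sample_rate) + 1L
  ok <- idx >= 1L & idx <= length(phase)
  idx <- idx[ok]
  spike_times <- spike_times[ok]
  keep <- envelope[idx] > theta_rms
  tibble(time_s = spike_times[keep], phase = phase[idx[keep]])
}

#' Phase locking of every unit to the theta rhythm
#'
#' For each unit: takes the theta-filtered LFP of its reference electrode
#' (by default the electrode nearest the unit), extracts envelope-gated
#' spike phases, and computes the Rayleigh statistic, p-value and circular
#' mean phase.
#'
#' @param spikes A [spike_train_set()].
#' @param lfp An [lfp_recording()].
#' @param band Theta band in Hz (default `c(4, 8)`).
#' @param window Optional `c(start, end)` restriction in seconds (e.g. one
#'   stage of a [segment_stages()] result), applied to both spikes and LFP.
#' @param reference `"nearest"` (default) uses each unit's nearest
#'   electrode; an electrode id uses that fixed electrode for all units.
#' @param alpha Rayleigh significance level (default 0.05).
#' @return Object of class `phase_locking`: tibble with one row per unit —
#'   `unit_id`, `electrode_id`, `n_selected`, `R`, `r_bar`, `p_value`,
#'   `mean_phase`, `significant`, `x_um`, `y_um`.
#' @export
phase_locking <- function(spikes, lfp, band = c(4, 8), window = NULL,
                          reference = "nearest", alpha = 0.05) {
  stopifnot(inherits(spikes, "spike_train_set"), inherits(lfp, "lfp_recording"))
  if (!is.null(window)) {
    spikes <- crop_spikes(spikes, window[1], window[2], rebase = TRUE)
    lfp <- crop_lfp(lfp, window[1], window[2])
  }
  th <- theta_filter(lfp, band)
  # per-electrode phase/envelope computed lazily (most units share electrodes)
  cache <- new.env(parent = emptyenv())
  get_pe <- function(e_idx) {
    key <- as.character(e_idx)
    if (!is.null(cache[[key]])) return(cache[[key]])
    pe <- phase_and_envelope(th[e_idx, ])
    pe$rms <- sqrt(mean(th[e_idx, ]^2))
    cache[[key]] <- pe
    pe
  }
  ex <- lfp$electrodes$x_um
  ey <- lfp$electrodes$y_um
  tr <- spike_list(spikes)
  rows <- imap(tr, function(times, uid) {
    u <- spikes$units[spikes$units$unit_id == uid, ]
    e_idx <- if (identical(reference, "nearest")) {
      which.min((ex - u$x_um)^2 + (ey - u$y_um)^2)
    } else {
      match(reference, lfp$electrodes$electrode_id)
    }
    if (is.na(e_idx)) abort("Reference electrode not found.")
    pe <- get_pe(e_idx)
    sel <- gated_spike_phases(times, pe$phase, pe$envelope, lfp$sample_rate,
                              theta_rms = pe$rms[1])
    if (nrow(sel) == 0) {
      return(tibble(unit_id = uid,
                    electrode_id = lfp$electrodes$electrode_id[e_idx],
                    n_selected = 0L, R = NA_real_, r_bar = NA_real_,
                    p_value = NA_real_, mean_phase = NA_real_,
                    significant = FALSE, x_um = u$x_um, y_um = u$y_um))
    }
    rt <- rayleigh_test(sel$phase)
    cm <- circular_mean_std(sel$phase)
    tibble(unit_id = uid,
           electrode_id = lfp$electrodes$electrode_id[e_idx],
           n_selected = nrow(sel), R = rt$R, r_bar = rt$r_bar,
           p_value = rt$p_value, mean_phase = cm$mean,
           significant = rt$p_value < alpha,
           x_um = u$x_um, y_um = u$y_um)
  })
  out <- list_rbind(rows)
  attr(out, "alpha") <- alpha
  attr(out, "band") <- band
  class(out) <- c("phase_locking", class(out))
  out
}

#' Spatial heatmap and clustering of phase-locked angles
#'
#' Considers only significantly phase-locked units. The polar mode is the
#' centre of the fullest 10-degree bin of mean phases; each unit's value is
#' its wrapped absolute angular difference from the mode (in `[0, pi]`),
#' gridded and smoothed into a spatial heatmap. Units split into two
#' clusters at an angular difference of `split` (default pi/2, the natural
#' bipolar separator), and the two clusters' phase distributions are
#' compared with the two-sample Kuiper test.
#'
#' @param results A [phase_locking()] tibble (or any tibble with
#'   `mean_phase`, `significant`, `x_um`, `y_um`, `unit_id`).
#' @param sigma_um Heatmap smoothing SD in micrometres (default 70).
#' @param bin_deg Polar-mode bin width in degrees (default 10).
#' @param split Cluster split threshold in radians (default `pi/2`).
#' @param n_grid Heatmap cells per axis (default 30).
#' @return Object of class `phase_heatmap`: list with `heatmap` (a
#'   [spatial_heatmap()] of angular differences), `units` (tibble with
#'   `angle_diff` and `cluster`), `polar_mode` (radians), `kuiper` (tibble
#'   from [kuiper_test()]; `p_value` is `NA` when either cluster has fewer
#'   than 2 units).
#' @export
phase_heatmap <- function(results, sigma_um = 70, bin_deg = 10,
                          split = pi / 2, n_grid = 30) {
  res <- dplyr::filter(as_tibble(results), .data$significant,
                       !is.na(.data$mean_phase))
  if (nrow(res) < 2) abort("Need at least two significantly phase-locked units.")
  nb <- round(360 / bin_deg)
  breaks <- seq(-pi, pi, length.out = nb + 1)
  bin <- pmin(nb, pmax(1L, findInterval(wrap_angle(res$mean_phase), breaks,
                                        rightmost.closed = TRUE)))
  counts <- tabulate(bin, nbins = nb)
  mode_bin <- which.max(counts)
  polar_mode <- (breaks[mode_bin] + breaks[mode_bin + 1]) / 2
  res$angle_diff <- angle_diff_abs(res$mean_phase, polar_mode)
  res$cluster <- ifelse(res$angle_diff < split, 1L, 2L)
  hm <- spatial_heatmap(dplyr::rename(res, value = "angle_diff"),
                        value = "value", n_grid = n_grid, sigma_um = sigma_um)
  k1 <- res$mean_phase[res$cluster == 1L]
  k2 <- res$mean_phase[res$cluster == 2L]
  kp <- kuiper_test(k1, k2)
  structure(list(heatmap = hm,
                 units = res[, c("unit_id", "mean_phase", "angle_diff",
                                 "cluster", "x_um", "y_um")],
                 polar_mode = polar_mode,
                 kuiper = kp),
            class = "phase_heatmap")
}

#' @export
print.phase_heatmap <- function(x, ...) {
  cat(sprintf("<phase_heatmap> %d units, polar mode %.2f rad, Kuiper p = %s\n",
              nrow(x$units), x$polar_mode,
              format(x$kuiper$p_value, digits = 3)))
  invisible(x)
}
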