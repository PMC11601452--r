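# Spatial footprint of a unit: mean spike-aligned waveform on its best
# electrodes.

#' Extract a unit's spatial footprint
#'
#' Averages spike-aligned voltage windows on every electrode and keeps the
#' 12 channels (or all, if fewer exist) with the largest peak-to-peak mean
#' waveform, sorted by descending amplitude.
#'
#' @param lfp An [lfp_recording()] (raw or filtered traces).
#' @param spike_times Spike times in seconds.
#' @param window_ms Window length in milliseconds centred on each spike
#'   (default 3 ms, the conventional action-potential window).
#' @param n_channels Number of channels to keep (default 12).
#' @return An object of class `footprint`: tibble with one row per kept
#'   channel (`electrode_id`, `x_um`, `y_um`, `p2p_uv`) plus attributes
#'   `waveforms` (channels x samples matrix) and `time_ms` (sample times
#'   relative to the spike).
#' @export
extract_footprint <- function(lfp, spike_times, window_ms = 3, n_channels = 12) {
  stopifnot(inherits(lfp, "lfp_recording"))
  spike_times <- as.numeric(spike_times)
  if (length(spike_times) < 1) abort("Need at least one spike.")
  fs <- lfp$sample_rate
  half <- floor(window_ms / 2 / 1000 * fs)
  wlen <- 2L * half + 1L
  centre <- round(spike_times * fs) + 1L
  keep <- centre - half >= 1L & centre + half <= ncol(lfp$traces)
  centre <- centre[keep]
  if (length(centre) == 0) abort("No spikes with a full window inside the traces.")
  offs <- -half:half
  acc <- matrix(0, nrow = nrow(lfp$traces), ncol = wlen)
  for (c0 in centre) {
    acc <- acc + lfp$traces[, c0 + offs, drop = FALSE]
  }
  meanwf <- acc / length(centre)
  p2p <- apply(meanwf, 1, function(w) max(w) - min(w))
  k <- min(n_channels, nrow(lfp$traces))
  ord <- order(p2p, decreasing = TRUE)[seq_len(k)]
  out <- lfp$electrodes[ord, ]
  out$p2p_uv <- p2p[ord]
  out <- as_tibble(out)
  attr(out, "waveforms") <- meanwf[ord, , drop = FALSE]
  attr(out, "time_ms") <- offs / fs * 1000
  attr(out, "n_spikes") <- length(centre)
  class(out) <- c("footprint", class(out))
  out
}

#' @export
print.footprint <- function(x, ...) {
  cat(sprintf("<footprint> %d channels, %d spikes averaged, peak channel %s\n",
              nrow(x), attr(x, "n_spikes"), x$electrode_id[1]))
  NextMethod()
}
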