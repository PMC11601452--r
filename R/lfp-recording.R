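# Local field potential container: per-electrode voltage traces + positions.

#' Construct an LFP recording
#'
#' Per-electrode voltage traces (microvolts) with electrode positions
#' (micrometres) and a common sample rate.
#'
#' @param traces Numeric matrix, electrodes x samples (rows are electrodes).
#' @param positions Data frame with columns `electrode_id`, `x_um`, `y_um`,
#'   one row per electrode, in the row order of `traces`.
#' @param sample_rate Sampling rate in Hz.
#' @return An object of class `lfp_recording` with elements `traces`,
#'   `electrodes` (tibble), `sample_rate`.
#' @export
lfp_recording <- function(traces, positions, sample_rate) {
  if (is.vector(traces)) traces <- matrix(traces, nrow = 1)
  stopifnot(is.matrix(traces), is.numeric(traces))
  positions <- as_tibble(positions)
  if (!all(c("electrode_id", "x_um", "y_um") %in% names(positions))) {
    abort("`positions` needs columns `electrode_id`, `x_um`, `y_um`.")
  }
  positions$electrode_id <- as.character(positions$electrode_id)
  if (nrow(positions) != nrow(traces)) {
    abort("`positions` must have one row per trace row.")
  }
  if (!all(is.finite(positions$x_um)) || !all(is.finite(positions$y_um))) {
    abort("Electrode positions must be finite.")
  }
  sample_rate <- as.numeric(sample_rate)
  if (!is.finite(sample_rate) || sample_rate <= 0) {
    abort("`sample_rate` must be > 0.")
  }
  rownames(traces) <- positions$electrode_id
  structure(
    list(traces = traces,
         electrodes = positions[, c("electrode_id", "x_um", "y_um")],
         sample_rate = sample_rate),
    class = "lfp_recording"
  )
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %d electrodes, %d samples @ %g Hz (%.2f s)\n",
              nrow(x$traces), ncol(x$traces), x$sample_rate,
              ncol(x$traces) / x$sample_rate))
  invisible(x)
}

# duration in seconds
lfp_duration <- function(lfp) ncol(lfp$traces) / lfp$sample_rate

#' Restrict an LFP recording to a time window
#' @param lfp An `lfp_recording`.
#' @param start,end Window bounds in seconds.
#' @return An `lfp_recording` covering the window (time rebased to 0).
#' @export
crop_lfp <- function(lfp, start, end) {
  stopifnot(inherits(lfp, "lfp_recording"), end > start)
  i0 <- max(1L, floor(start * lfp$sample_rate) + 1L)
  i1 <- min(ncol(lfp$traces), ceiling(end * lfp$sample_rate))
  if (i1 <= i0) abort("Empty window.")
  lfp_recording(lfp$traces[, i0:i1, drop = FALSE], lfp$electrodes,
                lfp$sample_rate)
}

#' Anti-aliased downsampling of an LFP recording
#'
#' Low-pass filters each trace (4th-order Butterworth, zero phase) at
#' `cutoff_hz` and decimates to `new_rate`. Used to bring 20 kHz raw traces
#' to the 1 kHz rate at which spectral analyses operate.
#'
#' @param lfp An `lfp_recording`.
#' @param new_rate Target rate in Hz; must divide the current rate.
#' @param cutoff_hz Anti-aliasing cutoff; default 400 Hz.
#' @return An `lfp_recording` at `new_rate`.
#' @export
downsample_lfp <- function(lfp, new_rate = 1000, cutoff_hz = 400) {
  stopifnot(inherits(lfp, "lfp_recording"))
  r <- lfp$sample_rate / new_rate
  if (abs(r - round(r)) > 1e-9 || r < 1) {
    abort("`new_rate` must evenly divide the current sample rate.")
  }
  r <- as.integer(round(r))
  if (r == 1L) return(lfp)
  ny <- lfp$sample_rate / 2
  bf <- signal::butter(4, min(cutoff_hz, 0.9 * new_rate / 2) / ny, type = "low")
  idx <- seq(1L, ncol(lfp$traces), by = r)
  out <- t(apply(lfp$traces, 1, function(tr) {
    signal::filtfilt(bf, tr)[idx]
  }))
  if (nrow(lfp$traces) == 1L) out <- matrix(out, nrow = 1)
  lfp_recording(out, lfp$electrodes, new_rate)
}
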