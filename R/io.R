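# Readers/writers: delimited spike tables, HDF5 LFP fixtures, NWB (units +
# electrical series), ground-truth tables.

#' Read a recording
#'
#' Reads spike trains (and, when present, LFP traces) from one of the
#' supported on-disk formats:
#'
#' * `"spike_table"`: delimited text with header
#'   `unit_id,time_s,x_um,y_um`, one row per spike.
#' * `"nwb"`: an NWB (HDF5) file; the units table (`units/spike_times`) and
#'   electrode table are read, and the first `ElectricalSeries` under
#'   `acquisition/` becomes the LFP when present. Requires a `python` with
#'   `h5py` on the PATH.
#' * `"lfp_h5"`: a plain HDF5 fixture with datasets `traces`
#'   (electrodes x samples), `positions` (electrodes x 2, micrometres) and
#'   scalar `sample_rate`; spikes are absent.
#'
#' @param path File path.
#' @param format One of `"spike_table"`, `"nwb"`, `"lfp_h5"`.
#' @param duration Optional recording duration override (seconds).
#' @return A list with elements `spikes` (a [spike_train_set()] or `NULL`)
#'   and `lfp` (an [lfp_recording()] or `NULL`).
#' @export
read_recording <- function(path, format = c("spike_table", "nwb", "lfp_h5"),
                           duration = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  switch(format,
    spike_table = list(spikes = read_spike_table(path, duration = duration),
                       lfp = NULL),
    nwb = read_nwb(path, duration = duration),
    lfp_h5 = list(spikes = NULL, lfp = read_lfp_h5(path))
  )
}

#' Read a delimited spike table
#'
#' Expects header `unit_id,time_s,x_um,y_um`, one row per spike. Unsorted
#' spike times are sorted with a warning.
#'
#' @param path File path.
#' @param duration Optional duration (seconds); defaults to the smallest
#'   whole second containing all spikes.
#' @return A [spike_train_set()].
#' @export
read_spike_table <- function(path, duration = NULL) {
  tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("unit_id", "time_s", "x_um", "y_um")
  if (!all(need %in% names(tb))) {
    abort(paste0("Malformed spike table; need columns ",
                 paste(need, collapse = ", ")))
  }
  if (nrow(tb) == 0) abort("Empty spike table: no units.")
  unsorted <- any(vapply(split(tb$time_s, tb$unit_id), is.unsorted,
                         logical(1)))
  if (unsorted) warn("Spike times were not sorted per unit; sorting.")
  spike_train_set(tb, duration = duration)
}

#' Write a spike train set as a delimited spike table
#'
#' @param x A `spike_train_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spike_table <- function(x, path) {
  stopifnot(inherits(x, "spike_train_set"))
  tb <- left_join(x$spikes, x$units, by = "unit_id")
  readr::write_csv(tb, path, progress = FALSE)
  invisible(path)
}

# ---- HDF5 / NWB via the bundled h5py bridge ---------------------------------

h5_bridge <- function() {
  script <- system.file("python", "h5_bridge.py", package = "meacircuit")
  if (script == "") abort("h5_bridge.py not found in the installed package.")
  py <- Sys.which("python")
  if (py == "") abort("No `python` on PATH; HDF5/NWB I/O unavailable.")
  list(python = py, script = script)
}

run_bridge <- function(args) {
  b <- h5_bridge()
  out <- suppressWarnings(system2(b$python, c(b$script, args),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    abort(paste0("HDF5 bridge failed: ", paste(out, collapse = "\n")))
  }
  invisible(out)
}

#' Read an HDF5 LFP fixture
#'
#' Layout: datasets `traces` (electrodes x samples, microvolts),
#' `positions` (electrodes x 2), `sample_rate` (scalar Hz), optional
#' `electrode_ids`.
#'
#' @param path HDF5 file path.
#' @return An [lfp_recording()].
#' @export
read_lfp_h5 <- function(path) {
  tmp <- tempfile("lfp_")
  run_bridge(c("read_lfp", path, tmp))
  on.exit(unlink(paste0(tmp, c("_traces.csv", "_meta.csv")), force = TRUE))
  tr <- as.matrix(readr::read_csv(paste0(tmp, "_traces.csv"),
                                  col_names = FALSE, show_col_types = FALSE,
                                  progress = FALSE))
  meta <- readr::read_csv(paste0(tmp, "_meta.csv"), show_col_types = FALSE,
                          progress = FALSE)
  lfp_recording(unname(tr),
                tibble(electrode_id = as.character(meta$electrode_id),
                       x_um = meta$x_um, y_um = meta$y_um),
                sample_rate = meta$sample_rate[1])
}

#' Write an LFP recording to an HDF5 fixture
#'
#' @param lfp An [lfp_recording()].
#' @param path Output HDF5 path.
#' @return `path`, invisibly.
#' @export
write_lfp_h5 <- function(lfp, path) {
  stopifnot(inherits(lfp, "lfp_recording"))
  tmp <- tempfile("lfp_")
  readr::write_csv(as.data.frame(lfp$traces), paste0(tmp, "_traces.csv"),
                   col_names = FALSE, progress = FALSE)
  meta <- lfp$electrodes
  meta$sample_rate <- lfp$sample_rate
  readr::write_csv(meta, paste0(tmp, "_meta.csv"), progress = FALSE)
  on.exit(unlink(paste0(tmp, c("_traces.csv", "_meta.csv")), force = TRUE))
  run_bridge(c("write_lfp", path, tmp))
  invisible(path)
}

read_nwb <- function(path, duration = NULL) {
  tmp <- tempfile("nwb_")
  run_bridge(c("read_nwb", path, tmp))
  files <- paste0(tmp, c("_spikes.csv", "_traces.csv", "_meta.csv"))
  on.exit(unlink(files, force = TRUE))
  spikes <- NULL
  if (file.exists(files[1])) {
    tb <- readr::read_csv(files[1], show_col_types = FALSE, progress = FALSE)
    if (nrow(tb) == 0) abort("NWB file contains an empty unit set.")
    tb$unit_id <- as.character(tb$unit_id)
    spikes <- spike_train_set(tb, duration = duration)
  }
  lfp <- NULL
  if (file.exists(files[2]) && file.exists(files[3])) {
    tr <- as.matrix(readr::read_csv(files[2], col_names = FALSE,
                                    show_col_types = FALSE, progress = FALSE))
    meta <- readr::read_csv(files[3], show_col_types = FALSE, progress = FALSE)
    lfp <- lfp_recording(unname(tr),
                         tibble(electrode_id = as.character(meta$electrode_id),
                                x_um = meta$x_um, y_um = meta$y_um),
                         sample_rate = meta$sample_rate[1])
  }
  if (is.null(spikes) && is.null(lfp)) abort("No units or traces found in NWB file.")
  list(spikes = spikes, lfp = lfp)
}
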