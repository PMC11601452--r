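# Core domain container: a set of sorted-unit spike trains with positions.

#' Construct a spike train set
#'
#' Bundles per-unit spike times (seconds) with unit positions (micrometres)
#' into the container used by all spiking analyses. Spike times are sorted
#' per unit; all times must lie within `[0, duration]`.
#'
#' The coordinate convention throughout the package is x increasing
#' rightward, y increasing upward, units in micrometres, angles measured
#' counterclockwise from +x via `atan2()`.
#'
#' @param spikes Data frame with columns `unit_id`, `time_s` (one row per
#'   spike).
#' @param units Data frame with columns `unit_id`, `x_um`, `y_um` (one row
#'   per unit). If `NULL`, positions are taken from `x_um`/`y_um` columns of
#'   `spikes` when present.
#' @param duration Recording length in seconds. If `NULL`, the smallest
#'   integer second not before the last spike is used.
#' @return An object of class `spike_train_set` with elements `spikes`
#'   (tibble `unit_id`, `time_s`), `units` (tibble `unit_id`, `x_um`,
#'   `y_um`), and `duration`.
#' @examples
#' sts <- spike_train_set(
#'   data.frame(unit_id = c("a", "a", "b"), time_s = c(0.1, 0.4, 0.2)),
#'   units = data.frame(unit_id = c("a", "b"), x_um = c(0, 50), y_um = c(0, 0)),
#'   duration = 1
#' )
#' n_units(sts)
#' @export
spike_train_set <- function(spikes, units = NULL, duration = NULL) {
  spikes <- as_tibble(spikes)
  if (!all(c("unit_id", "time_s") %in% names(spikes))) {
    abort("`spikes` needs columns `unit_id` and `time_s`.")
  }
  spikes$unit_id <- as.character(spikes$unit_id)
  spikes$time_s <- as.numeric(spikes$time_s)
  if (is.null(units)) {
    if (all(c("x_um", "y_um") %in% names(spikes))) {
      units <- dplyr::distinct(spikes, .data$unit_id, .data$x_um, .data$y_um)
    } else {
      abort("Provide `units` or position columns `x_um`, `y_um` in `spikes`.")
    }
  }
  units <- as_tibble(units)
  if (!all(c("unit_id", "x_um", "y_um") %in% names(units))) {
    abort("`units` needs columns `unit_id`, `x_um`, `y_um`.")
  }
  units$unit_id <- as.character(units$unit_id)
  if (anyDuplicated(units$unit_id)) abort("Duplicate unit ids in `units`.")
  if (nrow(units) < 1) abort("A spike train set needs at least one unit.")
  if (!all(is.finite(units$x_um)) || !all(is.finite(units$y_um))) {
    abort("Unit positions must be finite.")
  }
  missing_units <- setdiff(unique(spikes$unit_id), units$unit_id)
  if (length(missing_units) > 0) {
    abort(paste0("Spikes refer to unknown units: ",
                 paste(head(missing_units, 5), collapse = ", ")))
  }
  if (anyNA(spikes$time_s) || any(!is.finite(spikes$time_s))) {
    abort("Spike times must be finite.")
  }
  if (is.null(duration)) {
    duration <- if (nrow(spikes) > 0) ceiling(max(spikes$time_s)) else 1
  }
  duration <- as.numeric(duration)
  if (!is.finite(duration) || duration <= 0) abort("`duration` must be > 0.")
  if (nrow(spikes) > 0 && (min(spikes$time_s) < 0 || max(spikes$time_s) > duration)) {
    abort("Spike times must lie within [0, duration].")
  }
  if (is.unsorted(spikes$time_s, strictly = FALSE) ||
      is.unsorted(order(spikes$unit_id), strictly = FALSE)) {
    # canonical order: unit then time
  }
  spikes <- dplyr::arrange(spikes[, c("unit_id", "time_s")],
                           .data$unit_id, .data$time_s)
  structure(
    list(spikes = spikes,
         units = units[, c("unit_id", "x_um", "y_um")],
         duration = duration),
    class = "spike_train_set"
  )
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat(sprintf("<spike_train_set> %d units, %d spikes, duration %.3f s\n",
              nrow(x$units), nrow(x$spikes), x$duration))
  invisible(x)
}

#' Number of units in a spike train set
#' @param x A `spike_train_set`.
#' @return Integer unit count.
#' @export
n_units <- function(x) {
  stopifnot(inherits(x, "spike_train_set"))
  nrow(x$units)
}

#' Spike times of one unit
#' @param x A `spike_train_set`.
#' @param unit_id Unit identifier.
#' @return Sorted numeric vector of spike times in seconds.
#' @export
unit_spikes <- function(x, unit_id) {
  stopifnot(inherits(x, "spike_train_set"))
  x$spikes$time_s[x$spikes$unit_id == as.character(unit_id)]
}

# Named list of per-unit spike-time vectors (all units, including silent).
spike_list <- function(x) {
  sp <- split(x$spikes$time_s, factor(x$spikes$unit_id, levels = x$units$unit_id))
  lapply(sp, as.numeric)
}

#' Restrict a spike train set to a time window
#' @param x A `spike_train_set`.
#' @param start,end Window bounds in seconds.
#' @param rebase If `TRUE`, shift times so the window starts at 0 and set
#'   `duration` to the window length.
#' @return A `spike_train_set`.
#' @export
crop_spikes <- function(x, start, end, rebase = FALSE) {
  stopifnot(inherits(x, "spike_train_set"), end > start)
  sp <- dplyr::filter(x$spikes, .data$time_s >= start, .data$time_s <= end)
  if (rebase) {
    sp$time_s <- sp$time_s - start
    spike_train_set(sp, x$units, duration = end - start)
  } else {
    spike_train_set(sp, x$units, duration = x$duration)
  }
}

#' @rdname tidy.spike_train_set
#' @export
tidy.spike_train_set <- function(x, ...) {
  counts <- dplyr::count(x$spikes, .data$unit_id, name = "n_spikes")
  out <- left_join(x$units, counts, by = "unit_id")
  out$n_spikes[is.na(out$n_spikes)] <- 0L
  out$rate_hz <- out$n_spikes / x$duration
  as_tibble(out)
}

#' Per-unit summary of a spike train set
#'
#' `tidy()` returns one row per unit (position, spike count, mean rate);
#' `glance()` returns a one-row overall summary.
#'
#' @param x A `spike_train_set`.
#' @param ... Unused.
#' @return A tibble.
#' @export
glance.spike_train_set <- function(x, ...) {
  tibble(n_units = nrow(x$units),
         n_spikes = nrow(x$spikes),
         duration_s = x$duration,
         mean_rate_hz = nrow(x$spikes) / nrow(x$units) / x$duration)
}
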