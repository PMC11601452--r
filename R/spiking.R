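# Population firing rate, burst staging (baseline / initiation / seizure),
# sub-burst extrema, and spatial firing heatmaps.

#' Population firing rate
#'
#' Spike counts in 1 ms bins, Gaussian-smoothed, divided by the number of
#' neurons and scaled to Hz:
#' rate(Hz) = n_spikes / (n_neurons x time(s)).
#'
#' @param spikes A [spike_train_set()].
#' @param bin_ms Bin width in ms (default 1).
#' @param sigma_ms Gaussian smoothing SD in ms (default 15; the conventional
#'   range is 10-20 ms).
#' @return Object of class `population_rate`: tibble with `time_s` (bin
#'   centres) and `rate_hz`; attributes `bin_ms`, `sigma_ms`, `n_neurons`.
#' @export
population_rate <- function(spikes, bin_ms = 1, sigma_ms = 15) {
  stopifnot(inherits(spikes, "spike_train_set"))
  if (spikes$duration <= 0) abort("Zero-duration recording.")
  bin_s <- bin_ms / 1000
  n_bins <- ceiling(spikes$duration / bin_s)
  counts <- tabulate(pmin(n_bins, floor(spikes$spikes$time_s / bin_s) + 1L),
                     nbins = n_bins)
  smoothed <- gauss_smooth(counts, sigma_ms / bin_ms)
  rate <- smoothed / nrow(spikes$units) * (1000 / bin_ms)
  out <- tibble(time_s = (seq_len(n_bins) - 0.5) * bin_s, rate_hz = rate)
  attr(out, "bin_ms") <- bin_ms
  attr(out, "sigma_ms") <- sigma_ms
  attr(out, "n_neurons") <- nrow(spikes$units)
  class(out) <- c("population_rate", class(out))
  out
}

# prominence-based local extrema on a regularly sampled series; returns
# indices of peaks whose prominence >= min_prom
find_peaks <- function(x, min_prom = 0) {
  n <- length(x)
  if (n < 3) return(integer())
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  if (length(cand) == 0) return(integer())
  keep <- vapply(cand, function(i) {
    # prominence: height above the higher of the two valley floors between
    # this peak and the nearest higher ground on each side
    left <- x[seq_len(i - 1)]
    right <- x[seq(i + 1, n)]
    higher_l <- which(left >= x[i])
    base_l <- if (length(higher_l)) min(x[seq(max(higher_l), i - 1)]) else min(left)
    higher_r <- which(right >= x[i])
    base_r <- if (length(higher_r)) min(x[seq(i + 1, i + min(higher_r))]) else min(right)
    x[i] - max(base_l, base_r) >= min_prom
  }, logical(1))
  cand[keep]
}

#' Burst staging of a recording
#'
#' Segments the recording into the three canonical stages of chemically
#' provoked epileptiform activity: baseline (before burst activity),
#' initiation (the first burst) and seizure (all subsequent activity).
#' A burst is a contiguous region where the population rate exceeds
#' `mean + threshold_sd * SD` of the pre-burst segment for at least
#' `min_burst_ms`; the pre-burst segment and the threshold are determined
#' jointly by fixed-point iteration. Sub-burst peaks and troughs within the
#' initiation burst are local extrema of the smoothed rate with prominence
#' at least `prominence_frac` of the initiation peak.
#'
#' @param rate A [population_rate()].
#' @param threshold_sd Threshold in pre-burst SDs (default 2).
#' @param min_burst_ms Minimum burst duration in ms (default 200).
#' @param merge_gap_ms Sub-threshold gaps up to this length are absorbed
#'   into a burst (default 60 ms), so the within-burst dips between
#'   theta-paced sub-bursts (half a theta period apart) do not split a
#'   burst.
#' @param min_run_ms Supra-threshold runs shorter than this are treated as
#'   noise excursions and dropped before gap merging (default 20 ms, the
#'   rate-smoothing scale).
#' @param prominence_frac Sub-burst prominence as a fraction of the
#'   initiation peak rate (default 0.25).
#' @return Object of class `stage_segmentation`: list with `stages` (tibble
#'   `stage`, `start`, `end`), `bursts` (tibble of burst intervals),
#'   `subbursts` (tibble `peak_time`, `trough_time`), `threshold_hz`.
#'   Emits a warning and returns empty initiation/seizure when no burst is
#'   found.
#' @export
segment_stages <- function(rate, threshold_sd = 2, min_burst_ms = 200,
                           merge_gap_ms = 60, min_run_ms = 20,
                           prominence_frac = 0.25) {
  stopifnot(inherits(rate, "population_rate"))
  r <- rate$rate_hz
  t <- rate$time_s
  bin_s <- attr(rate, "bin_ms") / 1000
  # fixed point: threshold from the segment before the first crossing; the
  # pre-segment never shrinks below 1 s (or 5% of the trace) so a spurious
  # early excursion cannot collapse the noise estimate
  min_pre <- max(round(1000 / (attr(rate, "bin_ms"))),
                 round(0.05 * length(r)))
  min_pre <- min(min_pre, length(r))
  pre_end <- length(r)
  for (iter in 1:20) {
    mu <- mean(r[seq_len(pre_end)])
    s <- sd(r[seq_len(pre_end)])
    thr <- mu + threshold_sd * s
    cross <- which(r > thr)
    new_end <- if (length(cross)) max(min_pre, cross[1] - 1L) else length(r)
    if (new_end == pre_end) break
    pre_end <- new_end
  }
  above <- r > thr
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  iv <- tibble(start = starts[runs$values], end = ends[runs$values])
  iv <- dplyr::filter(iv, (.data$end - .data$start + 1) * bin_s * 1000 >= min_run_ms)
  # absorb short gaps
  if (nrow(iv) > 1) {
    keep <- list(iv[1, ])
    for (i in 2:nrow(iv)) {
      last <- keep[[length(keep)]]
      gap <- (iv$start[i] - last$end - 1) * bin_s * 1000
      if (gap <= merge_gap_ms) {
        keep[[length(keep)]]$end <- iv$end[i]
      } else {
        keep[[length(keep) + 1]] <- iv[i, ]
      }
    }
    iv <- bind_rows(keep)
  }
  # duration criterion on supra-threshold occupancy, so merged noise blips
  # separated by long sub-threshold gaps do not qualify
  if (nrow(iv) > 0) {
    occ <- vapply(seq_len(nrow(iv)), function(i) {
      sum(above[iv$start[i]:iv$end[i]]) * bin_s * 1000
    }, numeric(1))
    iv <- iv[occ >= min_burst_ms, , drop = FALSE]
  }
  bursts <- tibble(start = t[iv$start] - bin_s / 2, end = t[iv$end] + bin_s / 2)
  if (nrow(bursts) == 0) {
    warn("No burst found; the whole recording is labelled baseline.")
    out <- list(stages = tibble(stage = "baseline", start = 0,
                                end = t[length(t)] + bin_s / 2),
                bursts = bursts,
                subbursts = tibble(peak_time = numeric(), trough_time = numeric()),
                threshold_hz = thr)
    class(out) <- "stage_segmentation"
    return(out)
  }
  init <- bursts[1, ]
  stages <- tibble(
    stage = c("baseline", "initiation", "seizure"),
    start = c(0, init$start, init$end),
    end = c(init$start, init$end, t[length(t)] + bin_s / 2)
  )
  # sub-bursts within initiation
  sel <- which(t >= init$start & t <= init$end)
  seg <- r[sel]
  prom <- prominence_frac * max(seg)
  pk <- find_peaks(seg, min_prom = prom)
  trough <- if (length(pk) > 1) {
    vapply(seq_len(length(pk) - 1), function(i) {
      j <- pk[i] + which.min(seg[pk[i]:pk[i + 1]]) - 1L
      t[sel[j]]
    }, numeric(1))
  } else numeric()
  sub <- tibble(peak_time = t[sel[pk]],
                trough_time = c(trough, NA_real_)[seq_along(pk)])
  out <- list(stages = stages, bursts = bursts, subbursts = sub,
              threshold_hz = thr)
  class(out) <- "stage_segmentation"
  out
}

#' @export
print.stage_segmentation <- function(x, ...) {
  cat(sprintf("<stage_segmentation> %d bursts, %d sub-burst peaks, threshold %.2f Hz\n",
              nrow(x$bursts), nrow(x$subbursts), x$threshold_hz))
  print(x$stages)
  invisible(x)
}

#' @rdname segment_stages
#' @param x A `stage_segmentation`.
#' @param ... Unused.
#' @export
tidy.stage_segmentation <- function(x, ...) x$stages

# ---- spatial heatmaps -------------------------------------------------------

#' Spatial heatmap of a per-unit quantity
#'
#' Maps unit values onto a square grid anchored to the bounding box of unit
#' positions, averages per cell, and applies NA-aware 2-D Gaussian smoothing
#' (weights renormalized over occupied cells; empty cells stay missing where
#' no weight reaches them).
#'
#' @param units Data frame with `x_um`, `y_um` and a value column.
#' @param value Name of the value column (default `"value"`).
#' @param n_grid Cells per axis (default 30, i.e. a 900-square grid of
#'   roughly 58 um cells on a standard array).
#' @param sigma_um Smoothing SD in micrometres (default 37.9).
#' @return Object of class `spatial_heatmap`: tibble `x_um`, `y_um`
#'   (cell centres), `value` (smoothed), `raw` (pre-smoothing cell mean);
#'   attributes `cell_um`, `sigma_um`.
#' @export
spatial_heatmap <- function(units, value = "value", n_grid = 30,
                            sigma_um = 37.9) {
  units <- as_tibble(units)
  stopifnot(all(c("x_um", "y_um", value) %in% names(units)))
  if (nrow(units) == 0) abort("No units to map.")
  v <- units[[value]]
  xr <- range(units$x_um)
  yr <- range(units$y_um)
  cell <- max(diff(xr), diff(yr)) / n_grid
  if (cell == 0) cell <- 1
  ix <- pmin(n_grid, pmax(1L, ceiling((units$x_um - xr[1]) / cell)))
  iy <- pmin(n_grid, pmax(1L, ceiling((units$y_um - yr[1]) / cell)))
  ix[units$x_um == xr[1]] <- 1L
  iy[units$y_um == yr[1]] <- 1L
  m <- matrix(NA_real_, n_grid, n_grid)
  cnt <- matrix(0, n_grid, n_grid)
  for (i in seq_along(v)) {
    if (is.na(m[iy[i], ix[i]])) m[iy[i], ix[i]] <- 0
    m[iy[i], ix[i]] <- m[iy[i], ix[i]] + v[i]
    cnt[iy[i], ix[i]] <- cnt[iy[i], ix[i]] + 1
  }
  raw <- ifelse(cnt > 0, m / cnt, NA_real_)
  sm <- gauss_smooth2d(raw, sigma_um / cell)
  centres_x <- xr[1] + (seq_len(n_grid) - 0.5) * cell
  centres_y <- yr[1] + (seq_len(n_grid) - 0.5) * cell
  out <- tibble(x_um = rep(centres_x, each = n_grid),
                y_um = rep(centres_y, times = n_grid),
                value = as.numeric(sm),
                raw = as.numeric(raw))
  attr(out, "cell_um") <- cell
  attr(out, "sigma_um") <- sigma_um
  class(out) <- c("spatial_heatmap", class(out))
  out
}

#' Spatial heatmap of mean firing rate
#'
#' Per-unit mean rate over a window, gridded and smoothed via
#' [spatial_heatmap()].
#'
#' @param spikes A [spike_train_set()].
#' @param window Optional `c(start, end)` seconds (default whole recording).
#' @param sigma_um Smoothing SD in micrometres (default 37.9).
#' @param n_grid Cells per axis (default 30).
#' @return A `spatial_heatmap` of rates in Hz.
#' @export
firing_heatmap <- function(spikes, window = NULL, sigma_um = 37.9,
                           n_grid = 30) {
  stopifnot(inherits(spikes, "spike_train_set"))
  if (is.null(window)) window <- c(0, spikes$duration)
  if (diff(window) <= 0) abort("Empty window.")
  sp <- dplyr::filter(spikes$spikes, .data$time_s >= window[1],
                      .data$time_s <= window[2])
  counts <- dplyr::count(sp, .data$unit_id, name = "n")
  u <- left_join(spikes$units, counts, by = "unit_id")
  u$n[is.na(u$n)] <- 0L
  u$value <- u$n / diff(window)
  spatial_heatmap(u, value = "value", n_grid = n_grid, sigma_um = sigma_um)
}
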