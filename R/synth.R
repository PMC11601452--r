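# Synthetic MEA-like recordings with planted circuit structure, theta
# dynamics and phase locking, so every downstream analysis has ground
# truth.

#' Synthetic recording configuration
#'
#' Assembles (and validates) the configuration of the synthetic generator.
#' The defaults emulate the epileptiform dentate-gyrus recordings the
#' analyses are built for: ~80 units along a curved cell layer, 2 Hz
#' Poisson background firing, theta-rhythmic (4-8 Hz) burst epochs in which
#' two sub-populations alternate half a theta period apart, a planted
#' ~10 ms directed inter-population latency, and per-electrode theta LFP as
#' standing or traveling waves plus noise.
#'
#' @param n_units_per_group Units per sub-population (default 40).
#' @param group_geometry `"bipolar_arc"` (two reciprocally active groups on
#'   the two halves of the layer), `"unimodal_arc"` (one population with a
#'   unidirectional propagation sweep), or `"uniform_disk"` (structureless
#'   null).
#' @param arc_coefficients Degree-2 polynomial `(a, b, c)` of the cell-layer
#'   curve `y = a x^2 + b x + c`, in micrometres.
#' @param arc_x_range x extent of the layer in micrometres (default 0-560,
#'   a 32-electrode span at 17.5 um pitch).
#' @param baseline_rate Background Poisson rate per unit in Hz (default 2).
#' @param duration Recording length in seconds (default 120).
#' @param burst_schedule Tibble `start` (s), `n_subbursts`, `theta_freq`
#'   (Hz, within 4-8). Each sub-burst is one group-level rate bump; bumps
#'   alternate between the groups at half the theta period. `NULL` gives
#'   eight 16-sub-burst bursts at 6 Hz for arc geometries (mirroring the
#'   6-8 per-group bursts per epoch seen in epileptiform slices) and no
#'   bursts for the uniform disk.
#' @param inter_group_latency_ms Planted directed latency between mirror
#'   partners (default 10 ms).
#' @param latency_jitter_ms SD of the planted latency jitter (default 2 ms).
#' @param echo_prob Probability that a leader spike is echoed by its partner
#'   (default 0.45).
#' @param spikes_per_subburst Expected spikes per unit per own-group
#'   sub-burst (default 0.9). Values up to 1 are a Bernoulli participation
#'   probability — a unit fires at most once per 15 ms sub-burst bump, as
#'   granule cells do at theta pace; larger values draw Poisson counts.
#' @param subburst_sigma_ms SD of the Gaussian sub-burst envelope (default
#'   15 ms).
#' @param phase_lock_kappa Von Mises concentration recorded as the planted
#'   phase-locking strength (default 4).
#' @param lfp_mode `"traveling"`, `"standing"`, or `"noise_only"`.
#' @param lfp_sample_rate LFP sample rate in Hz (default 1000; analyses
#'   operate at 1 kHz).
#' @param electrode_pitch_um Electrode pitch (default 17.5).
#' @param electrode_stride Keep every n-th electrode of the full grid
#'   (default 4, trimming the array to a tractable size).
#' @param theta_amp_uv Theta LFP amplitude in microvolts (default 50).
#' @param noise_sd LFP noise SD in microvolts (default 5).
#' @param include_lfp Generate the LFP at all (default `TRUE`).
#' @param seed Integer seed; the same configuration and seed give
#'   bit-identical output.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_units_per_group = 40,
                         group_geometry = c("bipolar_arc", "unimodal_arc",
                                            "uniform_disk"),
                         arc_coefficients = c(5e-4, 0.35, 0),
                         arc_x_range = c(0, 560),
                         baseline_rate = 2,
                         duration = 120,
                         burst_schedule = NULL,
                         inter_group_latency_ms = 10,
                         latency_jitter_ms = 2,
                         echo_prob = 0.45,
                         spikes_per_subburst = 0.9,
                         subburst_sigma_ms = 15,
                         phase_lock_kappa = 4,
                         lfp_mode = c("traveling", "standing", "noise_only"),
                         lfp_sample_rate = 1000,
                         electrode_pitch_um = 17.5,
                         electrode_stride = 4,
                         theta_amp_uv = 50,
                         noise_sd = 5,
                         include_lfp = TRUE,
                         seed = 1) {
  group_geometry <- match.arg(group_geometry)
  lfp_mode <- match.arg(lfp_mode)
  if (is.null(burst_schedule)) {
    burst_schedule <- if (group_geometry == "uniform_disk") {
      tibble(start = numeric(), n_subbursts = integer(), theta_freq = numeric())
    } else {
      tibble(start = seq(12, by = 13, length.out = 8), n_subbursts = 16,
             theta_freq = 6)
    }
  }
  burst_schedule <- as_tibble(burst_schedule)
  cfg <- list(
    n_units_per_group = n_units_per_group, group_geometry = group_geometry,
    arc_coefficients = as.numeric(arc_coefficients),
    arc_x_range = as.numeric(arc_x_range),
    baseline_rate = baseline_rate, duration = duration,
    burst_schedule = burst_schedule,
    inter_group_latency_ms = inter_group_latency_ms,
    latency_jitter_ms = latency_jitter_ms, echo_prob = echo_prob,
    spikes_per_subburst = spikes_per_subburst,
    subburst_sigma_ms = subburst_sigma_ms,
    phase_lock_kappa = phase_lock_kappa,
    lfp_mode = lfp_mode, lfp_sample_rate = lfp_sample_rate,
    electrode_pitch_um = electrode_pitch_um,
    electrode_stride = electrode_stride,
    theta_amp_uv = theta_amp_uv, noise_sd = noise_sd,
    include_lfp = include_lfp, seed = seed
  )
  stopifnot(cfg$baseline_rate >= 0, cfg$latency_jitter_ms >= 0,
            cfg$phase_lock_kappa >= 0, cfg$noise_sd >= 0,
            cfg$echo_prob >= 0, cfg$echo_prob <= 1,
            cfg$duration > 0, cfg$n_units_per_group >= 1)
  if (nrow(cfg$burst_schedule) > 0 &&
      any(cfg$burst_schedule$theta_freq < 4 | cfg$burst_schedule$theta_freq > 8)) {
    abort("theta_freq must lie within the theta band [4, 8] Hz.")
  }
  if (diff(cfg$arc_x_range) <= 0) abort("Degenerate (zero-length) arc.")
  class(cfg) <- "synth_config"
  cfg
}

draw_subburst_count <- function(mean_spikes) {
  if (mean_spikes <= 1) stats::rbinom(1, 1, mean_spikes) else rpois(1, mean_spikes)
}

arc_y <- function(cfg, x) {
  co <- cfg$arc_coefficients
  co[1] * x^2 + co[2] * x + co[3]
}

# normalized arc-length position of x along the layer curve
arc_pos <- function(cfg, x) {
  xs <- seq(cfg$arc_x_range[1], cfg$arc_x_range[2], length.out = 2001)
  ys <- arc_y(cfg, xs)
  arc <- c(0, cumsum(sqrt(diff(xs)^2 + diff(ys)^2)))
  stats::approx(xs, arc / max(arc), xout = x, rule = 2)$y
}

#' Generate a synthetic recording with ground truth
#'
#' See [synth_config()] for the construction. Returns the spike trains, the
#' (optional) LFP, and a ground-truth bundle recording group membership,
#' planted directed latencies, planted phase angles, true burst/sub-burst
#' intervals and the LFP wave mode.
#'
#' @param config A [synth_config()].
#' @return List with elements `spikes` ([spike_train_set()]), `lfp`
#'   ([lfp_recording()] or `NULL`), and `truth` (list of tibbles: `units`,
#'   `pairs`, `bursts`, `subbursts`, plus `lfp_mode`).
#' @export
generate_recording <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  set.seed(derive_seed(cfg$seed, "recording"))
  n_per <- cfg$n_units_per_group
  n_tot <- 2L * n_per
  x0 <- cfg$arc_x_range[1]
  x1 <- cfg$arc_x_range[2]
  mid <- (x0 + x1) / 2

  if (cfg$group_geometry == "bipolar_arc") {
    xa <- sort(runif(n_per, x0, mid - 0.05 * (x1 - x0)))
    xb <- sort(runif(n_per, mid + 0.05 * (x1 - x0), x1))
    xs <- c(xa, xb)
    ys <- arc_y(cfg, xs) + rnorm(n_tot, 0, 10)
    group <- rep(c("A", "B"), each = n_per)
  } else if (cfg$group_geometry == "unimodal_arc") {
    xs <- sort(runif(n_tot, x0, x1))
    ys <- arc_y(cfg, xs) + rnorm(n_tot, 0, 10)
    group <- rep("A", n_tot)
  } else {
    r <- (x1 - x0) / 2 * sqrt(runif(n_tot))
    th <- runif(n_tot, 0, 2 * pi)
    xs <- mid + r * cos(th)
    ys <- arc_y(cfg, mid) + r * sin(th)
    group <- rep("none", n_tot)
  }
  ids <- sprintf("u%03d", seq_len(n_tot))
  units <- tibble(unit_id = ids, x_um = xs, y_um = ys)
  qpos <- if (cfg$group_geometry == "uniform_disk") {
    rep(NA_real_, n_tot)
  } else {
    arc_pos(cfg, xs)
  }

  # mirror partners and planted per-pair direction (bipolar only)
  pairs_truth <- tibble(source = character(), target = character(),
                        latency_ms = numeric())
  sched <- cfg$burst_schedule
  burst_iv <- if (nrow(sched) > 0) {
    tibble(start = sched$start - 0.05,
           end = sched$start + (sched$n_subbursts - 1) / (2 * sched$theta_freq) + 0.05)
  } else {
    interval_tbl()
  }
  # background firing pauses during burst epochs: within a burst the
  # population is driven by the sub-burst process alone
  spike_times <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    n_bg <- rpois(1, cfg$baseline_rate * cfg$duration)
    tt <- runif(n_bg, 0, cfg$duration)
    if (nrow(burst_iv) > 0) {
      inb <- vapply(tt, function(s) any(s >= burst_iv$start & s <= burst_iv$end),
                    logical(1))
      tt <- tt[!inb]
    }
    spike_times[[i]] <- tt
  }

  sub_rows <- list()
  if (nrow(sched) > 0 && cfg$group_geometry == "bipolar_arc") {
    direction <- rep(c("AB", "BA"), length.out = n_per)  # per mirror pair
    pairs_truth <- tibble(
      source = ifelse(direction == "AB", ids[1:n_per], ids[n_per + 1:n_per]),
      target = ifelse(direction == "AB", ids[n_per + 1:n_per], ids[1:n_per]),
      latency_ms = cfg$inter_group_latency_ms
    )
    for (b in seq_len(nrow(sched))) {
      f <- sched$theta_freq[b]
      half <- 1 / (2 * f)
      for (s in seq_len(sched$n_subbursts[b]) - 1L) {
        centre <- sched$start[b] + s * half
        lead_A <- s %% 2 == 0
        lead_idx <- if (lead_A) 1:n_per else n_per + 1:n_per
        sub_rows[[length(sub_rows) + 1]] <-
          tibble(burst = b, time = centre, group = if (lead_A) "A" else "B")
        for (u in lead_idx) {
          partner <- if (u <= n_per) u + n_per else u - n_per
          pair_dir <- direction[if (u <= n_per) u else u - n_per]
          leads_pair <- (lead_A && pair_dir == "AB") ||
            (!lead_A && pair_dir == "BA")
          n_sp <- draw_subburst_count(cfg$spikes_per_subburst)
          if (n_sp == 0) next
          tt <- rnorm(n_sp, centre, cfg$subburst_sigma_ms / 1000)
          spike_times[[u]] <- c(spike_times[[u]], tt)
          if (leads_pair) {
            echo <- tt[runif(n_sp) < cfg$echo_prob]
            if (length(echo) > 0) {
              lat <- cfg$inter_group_latency_ms / 1000 +
                rnorm(length(echo), 0, cfg$latency_jitter_ms / 1000)
              spike_times[[partner]] <- c(spike_times[[partner]], echo + lat)
            }
          }
        }
      }
    }
  } else if (nrow(sched) > 0 && cfg$group_geometry == "unimodal_arc") {
    # unidirectional sweep: each sub-burst activates the layer left to right
    sweep_ms <- 25
    for (b in seq_len(nrow(sched))) {
      f <- sched$theta_freq[b]
      half <- 1 / (2 * f)
      for (s in seq_len(sched$n_subbursts[b]) - 1L) {
        centre <- sched$start[b] + s * half
        sub_rows[[length(sub_rows) + 1]] <-
          tibble(burst = b, time = centre, group = "A")
        for (u in seq_len(n_tot)) {
          n_sp <- draw_subburst_count(cfg$spikes_per_subburst)
          if (n_sp == 0) next
          tt <- centre + qpos[u] * sweep_ms / 1000 + rnorm(n_sp, 0, 0.003)
          spike_times[[u]] <- c(spike_times[[u]], tt)
        }
      }
    }
  }

  sp <- tibble(
    unit_id = rep(ids, lengths(spike_times)),
    time_s = unlist(spike_times)
  )
  sp <- dplyr::filter(sp, .data$time_s >= 0, .data$time_s <= cfg$duration)
  spikes <- spike_train_set(sp, units, duration = cfg$duration)

  subbursts <- if (length(sub_rows)) list_rbind(sub_rows) else
    tibble(burst = integer(), time = numeric(), group = character())

  truth <- list(
    units = tibble(unit_id = ids, group = group, arc_pos = qpos,
                   planted_phase = ifelse(group == "B", pi,
                                          ifelse(group == "A", 0, NA_real_))),
    pairs = pairs_truth,
    bursts = burst_iv,
    subbursts = subbursts,
    lfp_mode = cfg$lfp_mode
  )

  lfp <- if (cfg$include_lfp) synth_lfp(cfg, truth) else NULL
  list(spikes = spikes, lfp = lfp, truth = truth)
}

# Theta LFP over an electrode grid clipped to the arc's bounding box:
# traveling mode has a phase gradient spanning 2*pi along the arc;
# standing mode flips sign at the arc midpoint.
synth_lfp <- function(cfg, truth) {
  set.seed(derive_seed(cfg$seed, "lfp"))
  pitch <- cfg$electrode_pitch_um * cfg$electrode_stride
  gx <- seq(cfg$arc_x_range[1], cfg$arc_x_range[2], by = pitch)
  yr <- range(arc_y(cfg, gx))
  gy <- seq(yr[1] - 35, yr[2] + 35, by = pitch)
  grid <- expand.grid(x_um = gx, y_um = gy)
  ne <- nrow(grid)
  fs <- cfg$lfp_sample_rate
  n <- round(cfg$duration * fs)
  t <- (seq_len(n) - 1) / fs
  q <- arc_pos(cfg, grid$x_um)
  # theta envelope: on during bursts (smoothed box), small otherwise
  env <- rep(0.02, n)
  sched <- cfg$burst_schedule
  freq <- if (nrow(sched) > 0) sched$theta_freq[1] else 6
  phase_ref <- if (nrow(sched) > 0) sched$start[1] else 0
  if (nrow(sched) > 0) {
    for (b in seq_len(nrow(sched))) {
      dur_b <- (sched$n_subbursts[b] - 1) / (2 * sched$theta_freq[b]) + 0.05
      env[t >= sched$start[b] - 0.05 & t <= sched$start[b] + dur_b] <- 1
    }
    env <- gauss_smooth(env, 0.05 * fs)
  }
  carrier <- 2 * pi * freq * (t - phase_ref)
  traces <- matrix(0, ne, n)
  for (e in seq_len(ne)) {
    base <- switch(cfg$lfp_mode,
      traveling = cos(carrier - 2 * pi * q[e]),
      standing = ifelse(q[e] < 0.5, 1, -1) * cos(carrier),
      noise_only = rep(0, n)
    )
    traces[e, ] <- cfg$theta_amp_uv * env * base + rnorm(n, 0, cfg$noise_sd)
  }
  lfp_recording(traces,
                tibble(electrode_id = sprintf("e%04d", seq_len(ne)),
                       x_um = grid$x_um, y_um = grid$y_um),
                sample_rate = fs)
}

#' Generate a phase-locked spike train
#'
#' Draws spikes by thinning an inhomogeneous Poisson process whose
#' intensity is proportional to a von Mises density evaluated at the
#' instantaneous theta phase: \eqn{\lambda(t) = r \, 2\pi \,
#' f_{vM}(\phi(t); \mu, \kappa)}, so the long-run rate is `rate` when the
#' phase is uniformly distributed over time. `kappa = 0` gives a uniform
#' (unlocked) train.
#'
#' @param theta_trace Theta-band trace (numeric vector).
#' @param sample_rate Sampling rate of the trace in Hz.
#' @param kappa Von Mises concentration (>= 0).
#' @param mean_phase Preferred phase in radians.
#' @param rate Mean firing rate in Hz.
#' @param seed Integer seed.
#' @return Sorted spike time vector (seconds).
#' @export
generate_phase_locked_unit <- function(theta_trace, sample_rate, kappa,
                                       mean_phase, rate, seed = 1) {
  if (length(theta_trace) == 0) abort("Empty theta trace.")
  if (kappa < 0) abort("kappa must be >= 0.")
  if (rate == 0) return(numeric())
  set.seed(derive_seed(seed, "vonmises"))
  pe <- phase_and_envelope(theta_trace)
  dur <- length(theta_trace) / sample_rate
  dens_max <- exp(kappa) / (2 * pi * besselI(kappa, 0))
  lambda_max <- rate * 2 * pi * dens_max
  n_cand <- rpois(1, lambda_max * dur)
  cand <- sort(runif(n_cand, 0, dur))
  idx <- pmin(length(theta_trace), round(cand * sample_rate) + 1L)
  dens <- exp(kappa * cos(pe$phase[idx] - mean_phase)) /
    (2 * pi * besselI(kappa, 0))
  keep <- runif(n_cand) < rate * 2 * pi * dens / lambda_max
  cand[keep]
}
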