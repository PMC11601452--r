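# Directed pairwise-correlation circuit inference: nearest-spike latency
# distributions, significance filtering, propagation vectors, aggregation,
# angle histograms, and the circuit-geometry significance test.

#' Nearest-spike latency distribution for a neuron pair
#'
#' For every spike of the reference train `a`, the nearest spike of `b` (by
#' absolute time difference) defines a signed latency `t_b - t_a`; latencies
#' within the window are kept. A spike of `b` exactly equidistant before and
#' after keeps the negative (earlier) latency, deterministically.
#'
#' @param a,b Sorted spike time vectors in seconds (`a` is the reference).
#' @param window_ms Half-window in ms (default 30, the polysynaptic
#'   transmission timescale).
#' @return Object of class `latency_distribution`: tibble with one column
#'   `latency_ms`; attributes `n_events`, `mean_ms`, `window_ms`.
#' @examples
#' latency_distribution(c(0.1), c(0.11))$latency_ms  # +10 ms
#' @export
latency_distribution <- function(a, b, window_ms = 30) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) abort("Both trains must be nonempty.")
  idx <- findInterval(a, b)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(b))
  d_lo <- b[lo] - a   # <= 0 candidate (or nearest from one side)
  d_hi <- b[hi] - a
  # nearest by |dt|; ties (to within 1 ns) keep the negative latency
  use_lo <- abs(d_lo) <= abs(d_hi) + 1e-9
  lat <- ifelse(use_lo, d_lo, d_hi) * 1000
  lat <- lat[abs(lat) <= window_ms]
  out <- tibble(latency_ms = as.numeric(lat))
  attr(out, "n_events") <- length(lat)
  attr(out, "mean_ms") <- if (length(lat)) mean(lat) else NA_real_
  attr(out, "window_ms") <- window_ms
  class(out) <- c("latency_distribution", class(out))
  out
}

#' Significant directed pairs of a recording
#'
#' The circuit-inference protocol: every unordered unit pair with STTC above
#' `sttc_min` has its nearest-spike latency distribution computed (reference
#' = the lower unit id). Distributions with fewer than `min_events` events
#' or an absolute mean latency below `min_abs_mean_ms` are disregarded; the
#' rest get a two-tailed one-sample t-test of the mean latency against zero.
#' Pairs with `p < alpha` become directed propagation vectors: a positive
#' mean latency means the reference unit leads, so the vector points from it
#' toward the other unit; the vector's angle runs from the source position
#' toward the target position, and its weight is the number of latency
#' events.
#'
#' @param spikes A [spike_train_set()].
#' @param sttc_dt_ms STTC tiling half-window in ms (default 20).
#' @param sttc_min STTC screening threshold (default 0.01).
#' @param window_ms Latency half-window in ms (default 30).
#' @param min_events Minimum latency events (default 25).
#' @param min_abs_mean_ms Minimum absolute mean latency in ms (default 1).
#' @param alpha Significance level of the t-test (default 0.05; the
#'   protocol applies raw p-values).
#' @param p_adjust Optional multiple-testing correction method passed to
#'   [stats::p.adjust()] (e.g. `"BH"`); default `"none"`.
#' @param m Optional precomputed [sttc_matrix()] (saves recomputation).
#' @return Object of class `circuit_pairs`: tibble with one row per
#'   significant directed pair — `source`, `target`, `n_events`, `mean_ms`,
#'   `p_value`, `angle` (radians CCW from +x), `sttc`, and source/target
#'   positions. Attribute `n_candidates` counts screened pairs.
#' @export
significant_pairs <- function(spikes, sttc_dt_ms = 20, sttc_min = 0.01,
                              window_ms = 30, min_events = 25,
                              min_abs_mean_ms = 1, alpha = 0.05,
                              p_adjust = "none", m = NULL) {
  stopifnot(inherits(spikes, "spike_train_set"))
  if (n_units(spikes) < 2) abort("Need at least two units.")
  if (is.null(m)) m <- sttc_matrix(spikes, dt_ms = sttc_dt_ms)
  tr <- spike_list(spikes)
  ids <- names(tr)
  pos <- spikes$units
  idx <- which(upper.tri(m$values), arr.ind = TRUE)
  keep <- m$values[idx] > sttc_min
  idx <- idx[keep, , drop = FALSE]
  rows <- vector("list", nrow(idx))
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]
    j <- idx[r, 2]
    if (length(tr[[i]]) == 0 || length(tr[[j]]) == 0) next
    ld <- latency_distribution(tr[[i]], tr[[j]], window_ms = window_ms)
    ne <- attr(ld, "n_events")
    mu <- attr(ld, "mean_ms")
    if (ne < min_events || is.na(mu) || abs(mu) < min_abs_mean_ms) next
    if (sd(ld$latency_ms) == 0) next
    tt <- t.test(ld$latency_ms, mu = 0)
    # direction: positive mean -> reference (i) leads, vector i -> j
    src <- if (mu > 0) i else j
    tgt <- if (mu > 0) j else i
    rows[[r]] <- tibble(
      source = ids[src], target = ids[tgt],
      n_events = ne, mean_ms = mu, p_value = tt$p.value,
      sttc = m$values[i, j]
    )
  }
  out <- list_rbind(rows[!vapply(rows, is.null, logical(1))])
  n_candidates <- nrow(idx)
  if (nrow(out) > 0) {
    out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
    out <- dplyr::filter(out, .data$p_value < alpha)
  }
  if (nrow(out) > 0) {
    out <- left_join(out, setNames(pos, c("source", "x_source", "y_source")),
                     by = "source")
    out <- left_join(out, setNames(pos, c("target", "x_target", "y_target")),
                     by = "target")
    out$angle <- atan2(out$y_target - out$y_source,
                       out$x_target - out$x_source)
  } else {
    out <- tibble(source = character(), target = character(),
                  n_events = integer(), mean_ms = numeric(),
                  p_value = numeric(), sttc = numeric(),
                  x_source = numeric(), y_source = numeric(),
                  x_target = numeric(), y_target = numeric(),
                  angle = numeric())
  }
  attr(out, "n_candidates") <- n_candidates
  attr(out, "window_ms") <- window_ms
  attr(out, "sttc_dt_ms") <- m$dt_ms
  class(out) <- c("circuit_pairs", class(out))
  out
}

#' Aggregate propagation vectors by source neuron
#'
#' Replaces the multiple connections emanating from one neuron with a single
#' arrow: the weighted circular mean of the outgoing angles (weights = the
#' number of latency events). Aggregated arrows whose weighted circular
#' standard deviation reaches `std_max` are removed — averaging vectors that
#' point in opposite directions would fabricate a direction representative
#' of neither.
#'
#' @param pairs A [significant_pairs()] result (or tibble with `source`,
#'   `angle`, `n_events`).
#' @param std_max Circular SD threshold in radians (default 0.5).
#' @return Tibble `source`, `angle`, `circ_std`, `n_vectors`, `weight`
#'   (summed events), one row per retained source.
#' @export
aggregate_vectors <- function(pairs, std_max = 0.5) {
  pairs <- as_tibble(pairs)
  if (nrow(pairs) == 0) {
    return(tibble(source = character(), angle = numeric(),
                  circ_std = numeric(), n_vectors = integer(),
                  weight = numeric()))
  }
  out <- pairs |>
    group_by(.data$source) |>
    summarise(
      agg = list(circular_mean_std(.data$angle, .data$n_events)),
      n_vectors = n(),
      weight = sum(.data$n_events),
      .groups = "drop"
    ) |>
    tidyr::unnest_wider("agg") |>
    dplyr::rename(angle = "mean", circ_std = "std") |>
    dplyr::filter(.data$defined, .data$circ_std < std_max) |>
    select("source", "angle", "circ_std", "n_vectors", "weight")
  out
}

#' Weighted propagation-angle histogram
#'
#' Histogram of propagation angles over all significant pairwise
#' correlations (not only any displayed subset), each pair weighted by its
#' number of latency events.
#'
#' @param pairs A [significant_pairs()] result.
#' @param n_bins Number of angular bins (default 24, i.e. 15 degrees).
#' @return Object of class `angle_histogram`: tibble `bin_centre` (radians
#'   in (-pi, pi]), `count` (weighted); attributes `total` and `modes` (the
#'   one or two dominant circular modes, radians).
#' @export
angle_histogram <- function(pairs, n_bins = 24) {
  pairs <- as_tibble(pairs)
  breaks <- seq(-pi, pi, length.out = n_bins + 1)
  centres <- (head(breaks, -1) + tail(breaks, -1)) / 2
  if (nrow(pairs) == 0) {
    out <- tibble(bin_centre = centres, count = rep(0, n_bins))
    attr(out, "total") <- 0
    attr(out, "n_pairs") <- 0L
    attr(out, "modes") <- numeric()
    class(out) <- c("angle_histogram", class(out))
    return(out)
  }
  ang <- wrap_angle(pairs$angle)
  bin <- pmin(n_bins, pmax(1L, findInterval(ang, breaks, rightmost.closed = TRUE)))
  cnt <- vapply(seq_len(n_bins), function(bb) sum(pairs$n_events[bin == bb]),
                numeric(1))
  out <- tibble(bin_centre = centres, count = cnt)
  # dominant modes: top bin, plus the top bin more than 90 deg away if it
  # carries mass
  o <- order(cnt, decreasing = TRUE)
  m1 <- centres[o[1]]
  far <- o[angle_diff_abs(centres[o], m1) > pi / 2]
  modes <- m1
  if (length(far) > 0 && cnt[far[1]] > 0) modes <- c(m1, centres[far[1]])
  attr(out, "total") <- sum(cnt)
  attr(out, "n_pairs") <- nrow(pairs)
  attr(out, "modes") <- modes
  class(out) <- c("angle_histogram", class(out))
  out
}

#' Classify a circuit's angular structure
#'
#' Operationalizes the qualitative circuit classes: mass fractions are
#' computed in 30-degree sectors around the two dominant opposed modes.
#' `"bipolar"` if both sectors hold at least `bipolar_frac` of the mass and
#' the modes are 180 +/- 30 degrees apart; `"unimodal"` if one sector holds
#' at least `unimodal_frac`; otherwise `"diffuse"` (no coherent circuit).
#'
#' @param hist An [angle_histogram()].
#' @param bipolar_frac Sector mass fraction for the bipolar call (default
#'   0.25).
#' @param unimodal_frac Sector mass fraction for the unimodal call (default
#'   0.4).
#' @param min_pairs Fewer significant pairs than this is "no coherent
#'   circuit", i.e. `"diffuse"`, regardless of their angles (default 10).
#' @return One of `"bipolar"`, `"unimodal"`, `"diffuse"`.
#' @export
classify_circuit <- function(hist, bipolar_frac = 0.25, unimodal_frac = 0.4,
                             min_pairs = 10) {
  total <- attr(hist, "total")
  if (is.null(total) || total == 0) return("diffuse")
  if ((attr(hist, "n_pairs") %||% Inf) < min_pairs) return("diffuse")
  sector_mass <- function(centre) {
    sum(hist$count[angle_diff_abs(hist$bin_centre, centre) <= pi / 6])
  }
  m1 <- hist$bin_centre[which.max(hist$count)]
  f1 <- sector_mass(m1) / total
  # best opposed sector: within 180 +/- 30 deg of m1
  opp <- hist$bin_centre[angle_diff_abs(hist$bin_centre, wrap_angle(m1 + pi)) <= pi / 6]
  f2 <- if (length(opp)) max(vapply(opp, sector_mass, numeric(1))) / total else 0
  if (f1 >= bipolar_frac && f2 >= bipolar_frac) return("bipolar")
  if (f1 >= unimodal_frac) return("unimodal")
  "diffuse"
}

# ---- circuit geometry test --------------------------------------------------

# Fit the cell-layer curve y = c0 + c1 x + c2 x^2 to unit positions and
# return each query point's normalized arc-length position along it.
curve_positions <- function(units, query_x, query_y, n_samp = 2000) {
  fit <- stats::lm(y_um ~ x_um + I(x_um^2), data = units)
  co <- stats::coef(fit)
  xs <- seq(min(units$x_um), max(units$x_um), length.out = n_samp)
  ys <- co[1] + co[2] * xs + co[3] * xs^2
  # cumulative arc length along the sampled curve
  seg <- sqrt(diff(xs)^2 + diff(ys)^2)
  arc <- c(0, cumsum(seg))
  nearest <- vapply(seq_along(query_x), function(i) {
    which.min((xs - query_x[i])^2 + (ys - query_y[i])^2)
  }, integer(1))
  s <- arc[nearest]
  list(position = if (max(arc) > 0) s / max(arc) else rep(0, length(s)),
       coefficients = co, curve = tibble(x_um = xs, y_um = ys))
}

#' Statistical test of circuit geometry
#'
#' Checks whether the observed propagation-angle structure could be a bias
#' of the neurons' geometric layout. The cell layer is approximated by a
#' degree-2 polynomial fitted to all unit positions; each pair's source
#' neuron is projected to its nearest point on the curve and assigned a
#' normalized arc-length position (leftmost = 0, rightmost = 1). Pairs are
#' split by the sign of their propagation angle and the two groups'
#' positions are compared with a two-tailed two-sample t-test. A genuinely
#' reciprocal circuit — where opposite-going connections originate from
#' opposite ends of the layer — yields a far smaller p-value than layouts
#' where position does not determine direction.
#'
#' @param pairs A [significant_pairs()] result.
#' @param units Unit position tibble (`unit_id`, `x_um`, `y_um`); required
#'   so the curve is fitted to all units, not only connected ones.
#' @param index_by Which neuron's position indexes a pair: `"source"`
#'   (default) or `"target"`.
#' @return Object of class `geometry_test`: one-row tibble with `p_value`,
#'   `t_stat`, `n_positive`, `n_negative`, `mean_pos_positive`,
#'   `mean_pos_negative`, `defined`; attribute `pair_positions` holds the
#'   per-pair tibble (`source`, `angle`, `position`, `group`), attribute
#'   `curve` the fitted layer curve.
#' @export
geometry_bias_test <- function(pairs, units, index_by = c("source", "target")) {
  index_by <- match.arg(index_by)
  pairs <- as_tibble(pairs)
  units <- as_tibble(units)
  undefined <- function(pp = NULL) {
    out <- tibble(p_value = NA_real_, t_stat = NA_real_,
                  n_positive = if (is.null(pp)) 0L else sum(pp$group == "positive"),
                  n_negative = if (is.null(pp)) 0L else sum(pp$group == "negative"),
                  mean_pos_positive = NA_real_, mean_pos_negative = NA_real_,
                  defined = FALSE)
    attr(out, "pair_positions") <- pp
    class(out) <- c("geometry_test", class(out))
    out
  }
  if (nrow(pairs) < 4) return(undefined())
  key <- if (index_by == "source") "source" else "target"
  qx <- pairs[[paste0("x_", key)]]
  qy <- pairs[[paste0("y_", key)]]
  cp <- curve_positions(units, qx, qy)
  pp <- tibble(source = pairs$source, angle = pairs$angle,
               position = cp$position,
               group = ifelse(pairs$angle > 0, "positive", "negative"))
  n_pos <- sum(pp$group == "positive")
  n_neg <- sum(pp$group == "negative")
  if (n_pos < 2 || n_neg < 2) return(undefined(pp))
  xs <- pp$position[pp$group == "positive"]
  ys <- pp$position[pp$group == "negative"]
  if (sd(xs) == 0 && sd(ys) == 0) return(undefined(pp))
  tt <- t.test(xs, ys)
  out <- tibble(p_value = tt$p.value, t_stat = unname(tt$statistic),
                n_positive = n_pos, n_negative = n_neg,
                mean_pos_positive = mean(xs), mean_pos_negative = mean(ys),
                defined = TRUE)
  attr(out, "pair_positions") <- pp
  attr(out, "curve") <- cp$curve
  class(out) <- c("geometry_test", class(out))
  out
}

#' Assemble a circuit diagram
#'
#' Bundles the significant directed pairs, the per-source aggregated
#' vectors, the weighted propagation-angle histogram and its classification
#' into the package's headline result object.
#'
#' @param spikes A [spike_train_set()].
#' @param ... Passed to [significant_pairs()].
#' @param n_bins Histogram bins (default 24).
#' @param std_max Aggregation circular-SD threshold (default 0.5).
#' @return Object of class `circuit_diagram`: list with `pairs`,
#'   `aggregated`, `histogram`, `classification`, `geometry`.
#' @export
circuit_diagram <- function(spikes, ..., n_bins = 24, std_max = 0.5) {
  pairs <- significant_pairs(spikes, ...)
  hist <- angle_histogram(pairs, n_bins = n_bins)
  structure(
    list(pairs = pairs,
         aggregated = aggregate_vectors(pairs, std_max = std_max),
         histogram = hist,
         classification = classify_circuit(hist),
         geometry = geometry_bias_test(pairs, spikes$units)),
    class = "circuit_diagram"
  )
}

#' @export
print.circuit_diagram <- function(x, ...) {
  cat(sprintf("<circuit_diagram> %d significant pairs (%d aggregated sources), class: %s\n",
              nrow(x$pairs), nrow(x$aggregated), x$classification))
  if (isTRUE(x$geometry$defined)) {
    cat(sprintf("  geometry-bias test p = %.3g\n", x$geometry$p_value))
  }
  invisible(x)
}

#' @rdname circuit_diagram
#' @param x A `circuit_diagram`.
#' @param ... Unused.
#' @export
tidy.circuit_diagram <- function(x, ...) as_tibble(x$pairs)

#' @rdname circuit_diagram
#' @export
glance.circuit_diagram <- function(x, ...) {
  tibble(n_pairs = nrow(x$pairs),
         n_aggregated = nrow(x$aggregated),
         classification = x$classification,
         geometry_p = x$geometry$p_value,
         histogram_total = attr(x$histogram, "total"))
}

#' Type-I calibration of the geometry test on null layouts
#'
#' Draws `n_seeds` structureless recordsets: unit positions uniform on a
#' disk, `n_pairs` disjoint random pairs per seed, and propagation angles
#' assigned uniformly at random — i.e. independently of position, the null
#' the test is meant to hold under. Returns the fraction of seeds rejected
#' at `alpha`. Note that on fully 2-D layouts a direction derived from the
#' pair chord is *not* a clean null (the chord's vertical component couples
#' with the fitted-curve projection); see the methods vignette.
#'
#' @param n_seeds Number of simulated null layouts (default 200).
#' @param n_units Units per layout (default 40).
#' @param n_pairs Disjoint pairs per layout (default `n_units / 2`).
#' @param diameter_um Disk diameter (default 560).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed.
#' @return One-row tibble: `rejection_rate`, `n_defined`, `n_seeds`.
#' @export
geometry_null_calibration <- function(n_seeds = 200, n_units = 40,
                                      n_pairs = n_units %/% 2,
                                      diameter_um = 560, alpha = 0.05,
                                      seed = 1) {
  set.seed(derive_seed(seed, "geonull"))
  res <- vapply(seq_len(n_seeds), function(i) {
    r <- diameter_um / 2 * sqrt(runif(n_units))
    th <- runif(n_units, 0, 2 * pi)
    units <- tibble(unit_id = sprintf("u%03d", seq_len(n_units)),
                    x_um = r * cos(th), y_um = r * sin(th))
    per <- sample.int(n_units)
    ps <- per[seq_len(n_pairs)]
    pt <- per[n_pairs + seq_len(n_pairs)]
    pairs <- tibble(source = units$unit_id[ps], target = units$unit_id[pt],
                    n_events = 30L, mean_ms = 2, p_value = 0.01,
                    sttc = 0.1,
                    x_source = units$x_um[ps], y_source = units$y_um[ps],
                    x_target = units$x_um[pt], y_target = units$y_um[pt],
                    angle = runif(n_pairs, -pi, pi))
    g <- geometry_bias_test(pairs, units)
    if (!isTRUE(g$defined)) NA else as.numeric(g$p_value < alpha)
  }, numeric(1))
  tibble(rejection_rate = mean(res, na.rm = TRUE),
         n_defined = sum(!is.na(res)), n_seeds = n_seeds)
}
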