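# Latency distributions, significance filtering, vector aggregation, angle
# histograms, geometry-bias test.

test_that("latency distributions follow the nearest-spike rules", {
  expect_equal(latency_distribution(0.1, 0.11)$latency_ms, 10)
  expect_equal(attr(latency_distribution(0.1, 0.15), "n_events"), 0L)
  ld <- latency_distribution(c(0, 0.1), c(0.005, 0.095))
  expect_equal(sort(ld$latency_ms), c(-5, 5))
  expect_equal(attr(ld, "mean_ms"), 0)
  # exact tie (representable floats): keep the negative latency
  expect_equal(latency_distribution(1.0, c(0.75, 1.25), window_ms = 300)$latency_ms,
               -250)
  expect_equal(latency_distribution(1.0, c(0.875, 1.125), window_ms = 200)$latency_ms,
               -125)
  expect_error(latency_distribution(numeric(), 1), "nonempty")
})

test_that("latency distributions equal the exhaustive scan on random pairs", {
  set.seed(43)
  for (k in 1:50) {
    a <- poisson_train(runif(1, 1, 20), 5)
    b <- poisson_train(runif(1, 1, 20), 5)
    if (length(a) == 0 || length(b) == 0) next
    got <- latency_distribution(a, b)$latency_ms
    expect_equal(got, brute_latencies(a, b), tolerance = 1e-9)
    # role reversal flips every latency's sign (as multisets)
    rev <- latency_distribution(b, a)$latency_ms
    expect_equal(sort(brute_latencies(b, a)), sort(rev), tolerance = 1e-9)
  }
})

test_that("a planted 10 ms follower pair is detected with the right direction", {
  set.seed(47)
  a <- sort(runif(100, 0, 100))
  b <- sort(a + 0.010 + rnorm(100, 0, 0.002))
  sts <- spike_train_set(
    dplyr::bind_rows(tibble::tibble(unit_id = "A", time_s = a),
                     tibble::tibble(unit_id = "B", time_s = pmax(0, pmin(100, b)))),
    units = data.frame(unit_id = c("A", "B"), x_um = c(0, 100), y_um = 0),
    duration = 100)
  sp <- significant_pairs(sts)
  expect_equal(nrow(sp), 1)
  expect_equal(sp$source, "A")
  expect_equal(sp$target, "B")
  expect_gte(sp$mean_ms, 8)
  expect_lte(sp$mean_ms, 12)
  expect_equal(sp$angle, 0)
  expect_equal(sp$n_events, 100L)
})

test_that("pairs with 24 latency events are disregarded", {
  set.seed(53)
  a <- seq(1, 24, by = 1)
  b <- a + 0.01
  sts <- spike_train_set(
    dplyr::bind_rows(tibble::tibble(unit_id = "A", time_s = a),
                     tibble::tibble(unit_id = "B", time_s = b)),
    units = data.frame(unit_id = c("A", "B"), x_um = c(0, 100), y_um = 0),
    duration = 30)
  expect_equal(nrow(significant_pairs(sts)), 0)
  # 25 events pass
  a2 <- seq(1, 25, by = 1)
  sts2 <- spike_train_set(
    dplyr::bind_rows(tibble::tibble(unit_id = "A", time_s = a2),
                     tibble::tibble(unit_id = "B", time_s = a2 + 0.01)),
    units = data.frame(unit_id = c("A", "B"), x_um = c(0, 100), y_um = 0),
    duration = 30)
  expect_equal(nrow(significant_pairs(sts2)), 1)
})

test_that("independent Poisson pairs are rarely declared significant", {
  set.seed(59)
  hits <- vapply(1:200, function(k) {
    sts <- spike_train_set(
      dplyr::bind_rows(tibble::tibble(unit_id = "A", time_s = poisson_train(5, 100)),
                       tibble::tibble(unit_id = "B", time_s = poisson_train(5, 100))),
      units = data.frame(unit_id = c("A", "B"), x_um = c(0, 100), y_um = 0),
      duration = 100)
    nrow(significant_pairs(sts)) > 0
  }, logical(1))
  expect_lte(mean(hits), 0.10)
})

test_that("vector aggregation keeps coherent sources and drops opposed ones", {
  one <- tibble::tibble(source = "s", angle = 1.1, n_events = 30)
  ag <- aggregate_vectors(one)
  expect_equal(ag$angle, 1.1)
  expect_equal(ag$circ_std, 0)
  # opposite directions: resultant ~ 0, removed
  opp <- tibble::tibble(source = "s", angle = c(0, pi), n_events = c(30, 30))
  expect_equal(nrow(aggregate_vectors(opp)), 0)
  # right angle: std = sqrt(-2 ln cos(pi/4)) ~ 0.83 > 0.5, removed
  ra <- tibble::tibble(source = "s", angle = c(0, pi / 2), n_events = c(30, 30))
  expect_equal(nrow(aggregate_vectors(ra)), 0)
  expect_gt(sqrt(-2 * log(cos(pi / 4))), 0.5)
  # near-parallel: kept at the weighted circular mean
  ok <- tibble::tibble(source = "s", angle = c(0, 0.2), n_events = c(30, 10))
  ag2 <- aggregate_vectors(ok)
  expect_equal(ag2$angle, circular_mean_std(c(0, 0.2), c(30, 10))$mean)
})

test_that("angle histograms are event-weighted over all significant pairs", {
  pairs <- tibble::tibble(source = c("a", "b"), target = c("b", "c"),
                          n_events = c(40L, 10L), angle = c(0.01, pi - 0.01))
  h <- angle_histogram(pairs)
  expect_equal(attr(h, "total"), 50)
  expect_equal(sum(h$count), sum(pairs$n_events))
  expect_equal(h$count[which.max(h$count)], 40)
  # empty input
  h0 <- angle_histogram(pairs[0, ])
  expect_equal(attr(h0, "total"), 0)
  expect_equal(classify_circuit(h0), "diffuse")
})

test_that("circuit classification separates bipolar, unimodal and diffuse", {
  mk <- function(angles, w) {
    angle_histogram(tibble::tibble(source = "s", target = "t",
                                   n_events = w, angle = angles))
  }
  bi <- mk(c(rep(0.1, 10), rep(pi - 0.1, 10)), rep(20L, 20))
  expect_equal(classify_circuit(bi), "bipolar")
  uni <- mk(rep(0.4, 12), rep(20L, 12))
  expect_equal(classify_circuit(uni), "unimodal")
  set.seed(61)
  dif <- mk(runif(60, -pi, pi), rep(10L, 60))
  expect_equal(classify_circuit(dif), "diffuse")
})

test_that("the geometry test separates constructed groups and stays calibrated", {
  set.seed(67)
  n <- 60
  units <- tibble::tibble(unit_id = sprintf("u%02d", 1:n),
                          x_um = seq(0, 560, length.out = n),
                          y_um = 0.3 * seq(0, 560, length.out = n) + rnorm(n, 0, 5))
  src <- c(1:20, 41:60)
  tgt <- c(41:60, 1:20)
  pairs <- tibble::tibble(
    source = units$unit_id[src], target = units$unit_id[tgt],
    n_events = 30L, mean_ms = 5, p_value = 0.001, sttc = 0.1,
    x_source = units$x_um[src], y_source = units$y_um[src],
    x_target = units$x_um[tgt], y_target = units$y_um[tgt],
    angle = atan2(units$y_um[tgt] - units$y_um[src],
                  units$x_um[tgt] - units$x_um[src]))
  g <- geometry_bias_test(pairs, units)
  expect_true(g$defined)
  expect_lt(g$p_value, 1e-6)
  # positive-angle sources sit left, negative right
  expect_lt(g$mean_pos_positive, 0.35)
  expect_gt(g$mean_pos_negative, 0.65)

  # fewer than 2 pairs in a sign group: explicitly undefined
  g2 <- geometry_bias_test(pairs[1:5, ], units)
  expect_false(g2$defined)
  expect_true(is.na(g2$p_value))

  cal <- geometry_null_calibration(n_seeds = 100, seed = 5)
  expect_gte(cal$rejection_rate, 0.01)
  expect_lte(cal$rejection_rate, 0.10)
})

test_that("end-to-end bipolar inference is reciprocal and geometry-significant", {
  gen <- bipolar_fixture()
  m <- sttc_matrix(gen$spikes)
  sp <- significant_pairs(gen$spikes, m = m)
  expect_gt(nrow(sp), 50)
  # histogram bimodal at 180 degrees
  h <- angle_histogram(sp)
  modes <- attr(h, "modes")
  expect_length(modes, 2)
  sep <- abs(wrap_angle(modes[1] - modes[2])) * 180 / pi
  expect_gt(sep, 165)
  expect_equal(classify_circuit(h), "bipolar")
  # planted directed pairs that reach significance point the planted way
  pt <- gen$truth$pairs
  kk <- paste(sp$source, sp$target)
  fwd <- sum(kk %in% paste(pt$source, pt$target))
  bwd <- sum(kk %in% paste(pt$target, pt$source))
  expect_gte(fwd / max(1, fwd + bwd), 0.8)
  g <- geometry_bias_test(sp, gen$spikes$units)
  expect_lt(g$p_value, 1e-10)
})
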