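# Analytic-signal phase, envelope gating, Rayleigh / circular statistics,
# Kuiper, phase-difference heatmaps.

test_that("the analytic signal recovers phase and envelope of a tone", {
  fs <- 1000
  t <- seq(0, 5, by = 1 / fs)
  pe <- phase_and_envelope(cos(2 * pi * 6 * t))
  core <- 200:4800
  expect_lt(max(abs(pe$envelope[core] - 1)), 0.01)
  dp <- diff(pe$phase[core])
  wraps <- dp < -pi
  expect_true(all(dp[!wraps] > 0))                    # monotone advance
  expect_equal(mean(dp[!wraps]) * fs / (2 * pi), 6, tolerance = 0.01)

  # amplitude-modulated tone: envelope tracks the modulation within 2%
  a <- 1 + 0.4 * sin(2 * pi * 0.3 * t)
  pe2 <- phase_and_envelope(a * cos(2 * pi * 6 * t))
  expect_lt(max(abs(pe2$envelope[core] - a[core]) / a[core]), 0.02)

  expect_error(phase_and_envelope(rep(1, 100)), "Constant")
})

test_that("envelope gating keeps exactly the spikes the brute-force scan keeps", {
  fs <- 1000
  t <- seq(0, 10, by = 1 / fs)
  theta <- (1 + sin(2 * pi * 0.2 * t)) * cos(2 * pi * 6 * t)
  pe <- phase_and_envelope(theta)
  rms <- sqrt(mean(theta^2))
  set.seed(12)
  spk <- runif(300, 0, 10)
  got <- gated_spike_phases(spk, pe$phase, pe$envelope, fs)
  keep_brute <- vapply(spk, function(s) {
    pe$envelope[round(s * fs) + 1] > rms
  }, logical(1))
  expect_setequal(got$time_s, spk[keep_brute])
  # all kept during uniformly high envelope; none during silence
  hi <- gated_spike_phases(spk, pe$phase, rep(10 * rms, length(pe$phase)), fs)
  expect_equal(nrow(hi), length(spk))
  lo <- gated_spike_phases(spk, pe$phase, rep(0, length(pe$phase)), fs)
  expect_equal(nrow(lo), 0)
})

test_that("Rayleigh statistic matches closed forms and its Monte-Carlo null", {
  expect_equal(rayleigh_test(rep(pi / 3, 10))$R, 10)
  expect_equal(rayleigh_test(c(0, pi / 2, pi, 3 * pi / 2))$R, 0,
               tolerance = 1e-10)
  expect_error(rayleigh_test(numeric()), "at least one")

  # approximation vs direct Monte-Carlo null within p +/- 0.01
  set.seed(21)
  for (n in c(10, 50, 200)) {
    phases <- runif(n, -pi, pi)
    p_pkg <- rayleigh_test(phases)$p_value
    Rs <- replicate(1e4, {
      u <- runif(n, -pi, pi)
      sqrt(sum(cos(u))^2 + sum(sin(u))^2)
    })
    p_mc <- mean(Rs >= rayleigh_test(phases)$R)
    expect_lt(abs(p_pkg - p_mc), 0.01)
  }
})

test_that("circular mean/std follow resultant arithmetic and rotate", {
  expect_equal(circular_mean_std(c(0, pi / 2))$mean, pi / 4)
  expect_false(circular_mean_std(c(0, pi))$defined)
  w <- circular_mean_std(c(0, pi / 2), weights = c(3, 1))
  expect_equal(w$mean, atan2(1, 3))
  expect_equal(w$std, sqrt(-2 * log(sqrt(10) / 4)))
  expect_error(circular_mean_std(c(0, 1), weights = c(0, 0)), "zero")

  set.seed(14)
  for (k in 1:10) {
    ang <- runif(8, -pi, pi)
    shift <- runif(1, -pi, pi)
    m0 <- circular_mean_std(ang)$mean
    m1 <- circular_mean_std(ang + shift)$mean
    expect_lt(abs(wrap_angle(m1 - (m0 + shift))), 1e-10)
  }
})

test_that("the Kuiper test separates shifted samples and spares identical ones", {
  set.seed(31)
  x <- runif(40, -pi, pi)
  expect_equal(kuiper_test(x, x)$p_value, 1)
  a <- wrap_angle(rnorm(120, 0, 0.5))
  b <- wrap_angle(rnorm(120, pi, 0.5))
  expect_lt(kuiper_test(a, b)$p_value, 0.01)
  und <- kuiper_test(a, a[1])
  expect_true(is.na(und$p_value))
  # rotation invariance of the statistic (asymptotic branch, no permutation)
  v1 <- kuiper_test(a, b, exact_n = 0)$V
  v2 <- kuiper_test(wrap_angle(a + 1.1), wrap_angle(b + 1.1), exact_n = 0)$V
  expect_equal(v1, v2, tolerance = 0.05)
})

test_that("per-unit phase locking flags planted units via the nearest electrode", {
  fs <- 500
  dur <- 40
  t <- seq(0, dur, by = 1 / fs)
  theta <- 20 * cos(2 * pi * 6 * t)
  lfp <- lfp_recording(rbind(theta, rnorm(length(t), 0, 1)),
                       data.frame(electrode_id = c("near", "far"),
                                  x_um = c(0, 5000), y_um = 0), fs)
  locked <- generate_phase_locked_unit(theta, fs, kappa = 4, mean_phase = 1,
                                       rate = 6, seed = 2)
  set.seed(2)
  unlocked <- sort(runif(240, 0, dur))
  sts <- spike_train_set(
    dplyr::bind_rows(tibble::tibble(unit_id = "lock", time_s = locked),
                     tibble::tibble(unit_id = "rand", time_s = unlocked)),
    units = data.frame(unit_id = c("lock", "rand"), x_um = c(10, 20), y_um = 0),
    duration = dur)
  pl <- phase_locking(sts, lfp)
  expect_true(pl$significant[pl$unit_id == "lock"])
  expect_equal(pl$electrode_id, c("near", "near"))
  expect_lt(abs(wrap_angle(pl$mean_phase[pl$unit_id == "lock"] - 1)), 0.15)
})

test_that("phase heatmaps split planted phase groups and report Kuiper", {
  set.seed(41)
  n <- 24
  res <- tibble::tibble(
    unit_id = sprintf("u%02d", 1:n),
    mean_phase = wrap_angle(c(rnorm(n / 2, 0, 0.25), rnorm(n / 2, pi, 0.25))),
    significant = TRUE,
    x_um = c(runif(n / 2, 0, 200), runif(n / 2, 350, 550)),
    y_um = runif(n, 0, 80)
  )
  ph <- phase_heatmap(res)
  expect_equal(group_agreement(ph$units$cluster, rep(1:2, each = n / 2)), 1)
  expect_lt(ph$kuiper$p_value, 0.05)

  # all units at one phase: single cluster, heatmap near zero
  res1 <- res
  res1$mean_phase <- wrap_angle(rnorm(n, 0.5, 0.1))
  ph1 <- phase_heatmap(res1)
  expect_equal(length(unique(ph1$units$cluster)), 1)
  expect_lt(max(abs(ph1$heatmap$value), na.rm = TRUE), 0.4)
  expect_true(is.na(ph1$kuiper$p_value))

  # rotating every phase rotates the mode but not the partition
  res_rot <- res
  res_rot$mean_phase <- wrap_angle(res$mean_phase + 2)
  ph_rot <- phase_heatmap(res_rot)
  expect_equal(group_agreement(ph_rot$units$cluster, ph$units$cluster), 1)
})
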