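# Filtering, CWT spectrograms, theta frames, lag matrices, electrode
# clustering.

test_that("the theta band-pass is flat in-band and suppresses out-of-band", {
  fs <- 1000
  t <- seq(0, 10, by = 1 / fs)
  inband <- sin(2 * pi * 6 * t)
  out <- bandpass(inband, 4, 8, fs)
  ratio <- sd(out[1000:9000]) / sd(inband[1000:9000])
  expect_gt(ratio, 0.95)
  expect_lt(ratio, 1.05)
  far <- bandpass(sin(2 * pi * 50 * t), 4, 8, fs)
  expect_lt(sd(far[1000:9000]) / sd(inband), 0.05)
  expect_equal(bandpass(rep(0, 1000), 4, 8, fs), rep(0, 1000))
  expect_error(bandpass(inband, 4, 600, fs), "Nyquist")
})

test_that("the Morlet spectrogram localizes tones and is flat on white noise", {
  fs <- 1000
  t <- seq(0, 15, by = 1 / fs)
  sp <- spectrogram_cwt(cos(2 * pi * 6 * t), fs, time_step = 10)
  expect_true(all(sp$power >= 0, na.rm = TRUE))
  pk <- sp$freqs_hz[which.max(rowMeans(sp$power))]
  expect_gt(pk, 5)
  expect_lt(pk, 7)

  two <- cos(2 * pi * 2 * t) + cos(2 * pi * 40 * t)
  pw <- rowMeans(spectrogram_cwt(two, fs, time_step = 10)$power)
  ridges <- sp$freqs_hz[which(diff(sign(diff(pw))) < 0) + 1]
  bin_ratio <- (50 / 0.5)^(1 / 59)
  expect_true(any(ridges / 2 < bin_ratio & ridges / 2 > 1 / bin_ratio))
  expect_true(any(ridges / 40 < bin_ratio & ridges / 40 > 1 / bin_ratio))

  set.seed(2)
  pw_n <- rowMeans(spectrogram_cwt(rnorm(45000), fs, time_step = 10)$power)
  expect_lt((max(pw_n) - min(pw_n)) / mean(pw_n), 0.5)

  expect_error(spectrogram_cwt(rnorm(500), fs), "support")
})

test_that("theta frames are per-electrode normalized to [-1, 1]", {
  fs <- 1000
  t <- seq(0, 6, by = 1 / fs)
  tr <- rbind(30 * sin(2 * pi * 6 * t),   # clean theta
              rep(0, length(t)))          # dead electrode
  lfp <- lfp_recording(tr, data.frame(electrode_id = c("a", "b"),
                                      x_um = c(0, 100), y_um = 0), fs)
  fr <- theta_frames(lfp, step_ms = 5)
  expect_true(all(abs(fr$values) <= 1 + 1e-9))
  # frames subsample at 5 ms, so the sampled maximum sits just under the
  # normalization maximum of 1
  expect_gt(max(abs(fr$values[1, ])), 0.99)
  expect_lte(max(abs(fr$values[1, ])), 1)
  expect_equal(fr$values[2, ], rep(0, ncol(fr$values)))  # no division by zero
  # frame cadence: 5 ms
  expect_equal(diff(fr$times_s)[1], 0.005)
  long <- tidy(fr)
  expect_setequal(names(long), c("time_s", "electrode_id", "x_um", "y_um", "value"))
  expect_error(theta_frames(lfp, window = c(2, 2)), "window")
})

test_that("lag estimation matches the exhaustive-scan oracle", {
  fs <- 1000
  set.seed(11)
  # delayed copy: +20 ms with the j-lags-i sign convention
  x <- gauss_smooth(rnorm(8000), 8)
  y <- c(rep(0, 20), x[1:7980])
  lm <- lag_matrix(rbind(x, y), sample_rate = fs, max_lag_ms = 40)
  expect_equal(lm$lags_ms[1, 2], 20)
  expect_equal(lm$lags_ms[2, 1], -20)
  expect_equal(lag_matrix(rbind(x, x), sample_rate = fs)$lags_ms[1, 2], 0)

  # 6 Hz sine delayed 50 ms: |corr| maximizer aliases to 50 - 83.3 = -33 ms
  t <- seq(0, 8, by = 1 / fs)
  s1 <- sin(2 * pi * 6 * t)
  s2 <- c(rep(0, 50), s1[1:(length(s1) - 50)])
  expect_equal(lag_matrix(rbind(s1, s2), sample_rate = fs)$lags_ms[1, 2], -33)

  # random smooth traces: equality with the brute-force scan, both methods
  for (k in 1:15) {
    a <- gauss_smooth(rnorm(3000), 6)
    b <- gauss_smooth(rnorm(3000), 6)
    for (meth in c("abs", "signed")) {
      got <- lag_matrix(rbind(a, b), sample_rate = fs, method = meth)$lags_ms[1, 2]
      expect_equal(got, brute_lag(a, b, 40, meth), tolerance = 1e-9)
    }
  }

  expect_warning(lag_matrix(rbind(rep(0, 100), rnorm(100)), sample_rate = fs,
                            max_lag_ms = 10), "zero")
})

test_that("electrode clustering recovers planted lag structure", {
  # planted partition: intra-group lag 0, inter-group 30 ms
  fs <- 1000
  set.seed(4)
  base <- gauss_smooth(rnorm(6000), 10)
  tr <- rbind(base, base, base,
              c(rep(0, 30), base[1:5970]),
              c(rep(0, 30), base[1:5970]),
              c(rep(0, 30), base[1:5970]))
  lm <- lag_matrix(tr, sample_rate = fs)
  cl <- cluster_electrodes(lm, k = 2, seed = 1)
  expect_equal(length(unique(cl$cluster[1:3])), 1)
  expect_equal(length(unique(cl$cluster[4:6])), 1)
  expect_false(cl$cluster[1] == cl$cluster[4])

  # all-zero lags: degenerate, inertia 0
  lm0 <- lm
  lm0$lags_ms[] <- 0
  cl0 <- cluster_electrodes(lm0, k = 2, seed = 1)
  expect_true(attr(cl0, "degenerate"))
  expect_equal(attr(cl0, "inertia"), 0)

  # label assignment invariant to electrode reordering (up to permutation)
  perm <- c(4, 1, 5, 2, 6, 3)
  lmp <- lag_matrix(tr[perm, ], sample_rate = fs)
  clp <- cluster_electrodes(lmp, k = 2, seed = 1)
  same_orig <- outer(cl$cluster, cl$cluster, "==")
  same_perm <- outer(clp$cluster, clp$cluster, "==")
  expect_identical(same_perm, same_orig[perm, perm])

  expect_error(cluster_electrodes(lm, k = 10), "clusters")
})

test_that("standing-wave halves are separable via signed-lag clustering", {
  cfg <- synth_config(seed = 9, lfp_mode = "standing", duration = 14,
                      electrode_stride = 8,
                      burst_schedule = tibble::tibble(start = 2, n_subbursts = 60,
                                                      theta_freq = 6))
  gen <- generate_recording(cfg)
  cl <- theta_lag_clusters(gen$lfp, window = c(1.5, 8.5), seed = 2)
  q <- meacircuit:::arc_pos(cfg, cl$x_um)
  truthside <- ifelse(q < 0.5, 1L, 2L)
  expect_gte(group_agreement(cl$cluster, truthside), 0.95)
})
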