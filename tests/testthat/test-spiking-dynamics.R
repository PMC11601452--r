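# Population rate, burst staging, spatial heatmaps.

test_that("population rate implements spikes / (neurons x time)", {
  sts <- spike_train_set(
    data.frame(unit_id = rep(c("a", "b"), each = 5),
               time_s = seq(0.05, 0.95, length.out = 10)),
    units = data.frame(unit_id = c("a", "b"), x_um = 0:1, y_um = 0),
    duration = 1
  )
  pr <- population_rate(sts)
  expect_equal(mean(pr$rate_hz), 5, tolerance = 0.01)  # 10 spikes / 2 / 1 s

  silent <- spike_train_set(data.frame(unit_id = character(), time_s = numeric()),
                            units = data.frame(unit_id = "a", x_um = 0, y_um = 0),
                            duration = 1)
  expect_true(all(population_rate(silent)$rate_hz == 0))
})

test_that("rate integral conserves the spike count", {
  set.seed(6)
  for (k in 1:5) {
    n_u <- sample(3:10, 1)
    sp <- data.frame(unit_id = sample(paste0("u", 1:n_u), 400, replace = TRUE),
                     time_s = runif(400, 0, 10))
    sts <- spike_train_set(sp, units = data.frame(unit_id = paste0("u", 1:n_u),
                                                  x_um = seq_len(n_u), y_um = 0),
                           duration = 10)
    pr <- population_rate(sts)
    integral <- sum(pr$rate_hz) * 0.001 * n_u
    expect_lt(abs(integral - 400) / 400, 0.01)
  }
})

test_that("staging recovers planted bursts and sub-bursts", {
  gen <- bipolar_fixture()
  seg <- segment_stages(population_rate(gen$spikes))
  tb <- gen$truth$bursts
  expect_equal(nrow(seg$bursts), nrow(tb))
  expect_lt(max(abs(seg$bursts$start - tb$start)), 0.05)
  expect_lt(max(abs(seg$bursts$end - tb$end)), 0.05)
  expect_equal(seg$stages$stage, c("baseline", "initiation", "seizure"))
  # initiation is the first burst
  expect_equal(seg$stages$start[2], seg$bursts$start[1])
  # one sub-burst peak per planted bump, troughs interleaved
  n_true <- sum(gen$truth$subbursts$burst == 1)
  expect_equal(nrow(seg$subbursts), n_true)
  expect_equal(sum(!is.na(seg$subbursts$trough_time)), n_true - 1)
  pk_err <- abs(sort(seg$subbursts$peak_time) -
                  sort(gen$truth$subbursts$time[gen$truth$subbursts$burst == 1]))
  expect_lt(max(pk_err), 0.015)
})

test_that("a flat Poisson recording yields no bursts and stays baseline", {
  set.seed(8)
  sp <- data.frame(unit_id = sample(paste0("u", 1:20), 2000, replace = TRUE),
                   time_s = runif(2000, 0, 50))
  sts <- spike_train_set(sp, units = data.frame(unit_id = paste0("u", 1:20),
                                                x_um = 1:20, y_um = 0),
                         duration = 50)
  expect_warning(seg <- segment_stages(population_rate(sts)), "No burst")
  expect_equal(nrow(seg$bursts), 0)
  expect_equal(seg$stages$stage, "baseline")
})

test_that("staging is invariant to adding silent units", {
  gen <- bipolar_fixture()
  seg1 <- segment_stages(population_rate(gen$spikes))
  extra <- dplyr::bind_rows(gen$spikes$units,
                            tibble::tibble(unit_id = paste0("silent", 1:20),
                                           x_um = 0, y_um = 0))
  sts2 <- spike_train_set(gen$spikes$spikes, extra, duration = gen$spikes$duration)
  seg2 <- segment_stages(population_rate(sts2))
  expect_equal(seg2$bursts, seg1$bursts)
})

test_that("firing heatmaps are flat for uniform rates and translate rigidly", {
  set.seed(3)
  n <- 40
  units <- data.frame(unit_id = sprintf("u%02d", 1:n),
                      x_um = runif(n, 0, 500), y_um = runif(n, 0, 500))
  sp <- data.frame(unit_id = rep(units$unit_id, each = 20),
                   time_s = runif(20 * n, 0, 10))
  sts <- spike_train_set(sp, units, duration = 10)
  hm <- firing_heatmap(sts)
  vals <- hm$value[!is.na(hm$value)]
  expect_lt(max(abs(vals - 2)), 0.75)  # every unit fires at 2 Hz
  # smoothing preserves the mean over occupied support
  expect_lt(abs(mean(vals) - mean(hm$raw, na.rm = TRUE)) /
              mean(hm$raw, na.rm = TRUE), 0.05)

  shifted <- units
  shifted$x_um <- shifted$x_um + 300
  shifted$y_um <- shifted$y_um - 120
  sts2 <- spike_train_set(sp, shifted, duration = 10)
  hm2 <- firing_heatmap(sts2)
  expect_equal(hm2$value, hm$value)
  expect_equal(hm2$x_um, hm$x_um + 300)

  # single active unit: peak at its cell
  one <- spike_train_set(data.frame(unit_id = "u01", time_s = seq(0.1, 9.9, 0.1)),
                         units, duration = 10)
  hm1 <- firing_heatmap(one)
  cell <- attr(hm1, "cell_um")
  raw_pk <- hm1[which.max(hm1$raw), ]
  expect_lt(abs(raw_pk$x_um - units$x_um[1]), cell)
  expect_lt(abs(raw_pk$y_um - units$y_um[1]), cell)
  # occupancy-renormalized smoothing lets isolated neighbouring cells adopt
  # the donor value, so the smoothed peak is only pinned to within ~2 sigma
  pk <- hm1[which.max(hm1$value), ]
  expect_lt(abs(pk$x_um - units$x_um[1]), 2 * attr(hm1, "sigma_um"))
  expect_lt(abs(pk$y_um - units$y_um[1]), 2 * attr(hm1, "sigma_um"))
})

test_that("consecutive sub-burst difference maps flip sign across the arc", {
  gen <- bipolar_fixture()
  seg <- segment_stages(population_rate(gen$spikes))
  pk <- sort(seg$subbursts$peak_time)[1:2]
  w <- 0.04
  h1 <- firing_heatmap(gen$spikes, window = c(pk[1] - w, pk[1] + w))
  h2 <- firing_heatmap(gen$spikes, window = c(pk[2] - w, pk[2] + w))
  dif <- h1$value - h2$value
  left <- h1$x_um < 280
  m_left <- mean(dif[left], na.rm = TRUE)
  m_right <- mean(dif[!left], na.rm = TRUE)
  expect_true(sign(m_left) != sign(m_right))
  expect_gt(abs(m_left - m_right), 1)
})
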