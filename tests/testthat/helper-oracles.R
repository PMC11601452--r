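# Independent brute-force oracles and small fixture builders shared across
# the suite. The oracles deliberately use naive algorithms (explicit window
# merges, exhaustive scans) so they share no code path with the package.

# STTC by explicit window-merge and membership scan
brute_sttc <- function(a, b, dt, duration) {
  cover <- function(times) {
    if (length(times) == 0) return(0)
    iv <- cbind(pmax(0, times - dt), pmin(duration, times + dt))
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    total <- 0
    cur <- iv[1, ]
    for (i in seq_len(nrow(iv))[-1]) {
      if (iv[i, 1] <= cur[2]) {
        cur[2] <- max(cur[2], iv[i, 2])
      } else {
        total <- total + (cur[2] - cur[1])
        cur <- iv[i, ]
      }
    }
    (total + (cur[2] - cur[1])) / duration
  }
  prop <- function(x, y) {
    if (length(x) == 0) return(0)
    mean(vapply(x, function(t) any(abs(y - t) <= dt), logical(1)))
  }
  TA <- cover(a); TB <- cover(b)
  PA <- prop(a, b); PB <- prop(b, a)
  t1 <- if (abs(1 - PA * TB) < 1e-15) 0 else (PA - TB) / (1 - PA * TB)
  t2 <- if (abs(1 - PB * TA) < 1e-15) 0 else (PB - TA) / (1 - PB * TA)
  0.5 * (t1 + t2)
}

# exhaustive O(n*m) nearest-spike latency scan with the negative-tie rule
brute_latencies <- function(a, b, window_ms = 30) {
  out <- numeric(0)
  for (t in a) {
    d <- (b - t) * 1000
    best <- d[order(abs(d), d)][1]     # smallest |d|, ties -> negative
    if (abs(best) <= window_ms) out <- c(out, best)
  }
  out
}

# exhaustive lag scan of overlap-normalized cross-correlation (the lag_matrix
# definition): r(tau) = sum_t x[t] y[t+tau] / ((n-|tau|) sd_x sd_y), global
# mean-centring and population SDs
brute_lag <- function(x, y, max_lag, method = "abs") {
  n <- length(x)
  xc <- x - mean(x); yc <- y - mean(y)
  sx <- sqrt(mean(xc^2)); sy <- sqrt(mean(yc^2))
  lags <- -max_lag:max_lag
  r <- vapply(lags, function(m) {
    s <- if (m >= 0) sum(xc[1:(n - m)] * yc[(1 + m):n]) else
      sum(xc[(1 - m):n] * yc[1:(n + m)])
    s / ((n - abs(m)) * sx * sy)
  }, numeric(1))
  score <- if (method == "abs") abs(r) else r
  tie <- order(abs(lags), lags)
  lags[tie[which.max(score[tie])]]
}

poisson_train <- function(rate, duration) sort(runif(rpois(1, rate * duration), 0, duration))

tiny_sts <- function() {
  spike_train_set(
    data.frame(unit_id = c("a", "a", "b", "c"),
               time_s = c(0.1, 0.4, 0.2, 0.9)),
    units = data.frame(unit_id = c("a", "b", "c"),
                       x_um = c(0, 50, 100), y_um = c(0, 10, 0)),
    duration = 1
  )
}

# cached small bipolar recording used by several files
bipolar_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_recording(synth_config(seed = 13, include_lfp = FALSE))
    }
    cache
  }
})

group_agreement <- function(labels, truth) {
  tab <- table(labels, truth)
  max(sum(diag(tab)), sum(tab[cbind(1:2, 2:1)])) / sum(tab)
}
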