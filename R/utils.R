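# Shared numerical helpers: Gaussian smoothing, angle arithmetic, seeds.

#' Gaussian smoothing of a regularly sampled series
#'
#' Convolves `x` with a Gaussian kernel of standard deviation `sigma` (in
#' samples). Edge handling renormalises the kernel over the in-range support,
#' so a constant series is returned unchanged.
#'
#' @param x Numeric vector.
#' @param sigma Kernel standard deviation in samples; `0` returns `x`.
#' @return Numeric vector the same length as `x`.
#' @export
gauss_smooth <- function(x, sigma) {
  stopifnot(is.numeric(x), sigma >= 0)
  if (sigma == 0 || length(x) < 2) return(x)
  half <- max(1L, ceiling(4 * sigma))
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  n <- length(x)
  # pad with NA, renormalise over in-range weights
  xp <- c(rep(NA_real_, half), x, rep(NA_real_, half))
  out <- numeric(n)
  num <- stats::filter(ifelse(is.na(xp), 0, xp), k, sides = 2)
  den <- stats::filter(as.numeric(!is.na(xp)), k, sides = 2)
  out <- (num / den)[(half + 1):(half + n)]
  as.numeric(out)
}

# 2-D Gaussian smoothing with NA-aware renormalisation: NA cells carry no
# weight and stay NA where the local weight is zero.
gauss_smooth2d <- function(m, sigma) {
  stopifnot(is.matrix(m), sigma >= 0)
  if (sigma == 0) return(m)
  half <- max(1L, ceiling(4 * sigma))
  k1 <- exp(-0.5 * ((-half:half) / sigma)^2)
  w <- !is.na(m)
  m0 <- ifelse(w, m, 0)
  conv1 <- function(a) {
    # separable convolution, zero padding
    a2 <- apply(a, 2, function(col) {
      as.numeric(stats::filter(c(rep(0, half), col, rep(0, half)), k1,
                               sides = 2))[(half + 1):(half + length(col))]
    })
    t(apply(a2, 1, function(row) {
      as.numeric(stats::filter(c(rep(0, half), row, rep(0, half)), k1,
                               sides = 2))[(half + 1):(half + length(row))]
    }))
  }
  num <- conv1(m0)
  den <- conv1(w * 1.0)
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Wrap angles into (-pi, pi]
#'
#' @param theta Angles in radians.
#' @return Angles wrapped to the principal interval.
#' @export
wrap_angle <- function(theta) {
  out <- (theta + pi) %% (2 * pi) - pi
  # map -pi to +pi so the interval is (-pi, pi]
  out[out == -pi] <- pi
  out
}

# Smallest absolute angular difference, in [0, pi].
angle_diff_abs <- function(a, b) {
  d <- abs(wrap_angle(a - b))
  pmin(d, 2 * pi - d)
}

# Deterministic child seed derived from a base seed and a stream label,
# kept below 2^31.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Interval helper: rows (start, end) in seconds.
interval_tbl <- function(start = numeric(), end = numeric()) {
  tibble(start = as.numeric(start), end = as.numeric(end))
}
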