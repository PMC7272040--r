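#' Rule-of-Twelfths tidal interpolation between two extremes
#'
#' The interval between consecutive opposite tide extremes is split into six
#' equal sub-intervals; the cumulative fraction of the tidal range completed
#' after sub-interval k is (1, 3, 6, 9, 11, 12)/12, with linear interpolation
#' inside each sub-interval. This is the mariner's piecewise-linear
#' approximation to the sinusoidal tide curve.
#'
#' @param prev,next_ Lists with elements `time` and `height` describing the
#'   bracketing extremes; `prev` must precede `next_` and the two must be of
#'   opposite kind (heights differ monotonically between them).
#' @param t Time(s) at which to evaluate, within `[prev$time, next_$time]`.
#' @return Interpolated height(s) in metres.
#' @export
#' @examples
#' lo <- list(time = 0, height = 0)
#' hi <- list(time = 6 * 3600, height = 2.4)
#' rule_of_twelfths(lo, hi, 3 * 3600)  # half the range: 1.2
rule_of_twelfths <- function(prev, next_, t) {
  t0 <- as.numeric(prev$time)
  t1 <- as.numeric(next_$time)
  tt <- as.numeric(t)
  if (t1 <= t0) stop_invalid("`prev` must precede `next_`.")
  if (any(tt < t0 - 1e-9) || any(tt > t1 + 1e-9)) {
    stop_invalid("`t` must lie within [prev$time, next_$time].")
  }
  frac <- (tt - t0) / (t1 - t0)
  cum <- c(0, 1, 3, 6, 9, 11, 12) / 12
  done <- stats::approx(seq(0, 1, by = 1 / 6), cum, xout = pmin(pmax(frac, 0), 1))$y
  prev$height + done * (next_$height - prev$height)
}

check_tides <- function(tides) {
  if (!all(c("time", "height", "kind") %in% names(tides))) {
    stop_invalid("tide extremes need columns `time`, `height`, `kind`.")
  }
  tt <- as.numeric(tides$time)
  if (any(diff(tt) <= 0)) stop_invalid("tide extreme times must be strictly increasing.")
  k <- tides$kind
  if (any(k[-1] == k[-length(k)])) {
    stop_invalid("tide extremes must alternate high/low.")
  }
  invisible(tides)
}

#' Tide height at arbitrary times
#'
#' Locates the bracketing pair of extremes for each query time and applies
#' [rule_of_twelfths()].
#'
#' @param tides Tibble of tide extremes (`time`, `height`,
#'   `kind` in `"H"`/`"L"`), strictly alternating.
#' @param t Time(s) within the span of the extremes.
#' @return Height(s) in metres.
#' @export
tide_height <- function(tides, t) {
  check_tides(tides)
  tt <- as.numeric(t)
  ev <- as.numeric(tides$time)
  if (any(tt < ev[1] - 1e-9) || any(tt > ev[length(ev)] + 1e-9)) {
    stop("query time outside the span of the tide extremes.", call. = FALSE)
  }
  i <- pmin(pmax(findInterval(tt, ev), 1L), length(ev) - 1L)
  frac <- (tt - ev[i]) / (ev[i + 1L] - ev[i])
  cum <- c(0, 1, 3, 6, 9, 11, 12) / 12
  done <- stats::approx(seq(0, 1, by = 1 / 6), cum,
                        xout = pmin(pmax(frac, 0), 1))$y
  tides$height[i] + done * (tides$height[i + 1L] - tides$height[i])
}

#' Benthos level from a tide-corrected depth measurement
#'
#' A depth sounding taken at time `t` is converted to the elevation of the
#' benthos relative to the tide datum: `benthos = tide_height(t) - depth`.
#' The result is independent of when the measurement was taken.
#'
#' @param measured_depth Water depth reading(s) in metres.
#' @param t Measurement time(s).
#' @param tides Tide extremes tibble.
#' @param datum Reference level offset (m); heights in `tides` are assumed
#'   relative to this datum and the returned level is expressed on the same
#'   datum.
#' @return Benthos elevation(s) in metres relative to the datum.
#' @export
tide_correct_depth <- function(measured_depth, t, tides, datum = 0) {
  tide_height(tides, t) - measured_depth - datum
}

#' Tidal accessibility of a habitat
#'
#' Evaluates the water depth over the benthos on a regular time grid across
#' the span of the tide series and returns the percentage of time the depth
#' is at least `threshold` (30 cm by default, the depth below which roving
#' herbivorous fishes are excluded from grazing). The complement is the
#' percentage of time the habitat is covered by less than the threshold.
#'
#' @param tides Tide extremes tibble.
#' @param benthos_level Benthos elevation (m) relative to the tide datum.
#' @param threshold Minimum accessible depth (m); depth exactly at the
#'   threshold counts as accessible.
#' @param step Evaluation step in seconds (default 600, i.e. 10 minutes).
#' @return Percentage in \[0, 100\].
#' @export
tidal_accessibility <- function(tides, benthos_level, threshold = 0.30, step = 600) {
  check_tides(tides)
  check_scalar_pos(step, "step")
  ev <- as.numeric(tides$time)
  grid <- seq(ev[1], ev[length(ev)], by = step)
  depth <- tide_height(tides, grid) - benthos_level
  100 * mean(depth >= threshold)
}

#' Per-habitat accessibility table
#'
#' @param depths Tibble with columns `site`, `habitat` and `benthos_level`
#'   (m relative to the tide datum).
#' @param tides Tide extremes tibble.
#' @inheritParams tidal_accessibility
#' @return `depths` with `pct_accessible` and `pct_excluded` columns added.
#' @export
accessibility_table <- function(depths, tides, threshold = 0.30, step = 600) {
  depths$pct_accessible <- vapply(depths$benthos_level, function(b) {
    tidal_accessibility(tides, b, threshold, step)
  }, numeric(1))
  depths$pct_excluded <- 100 - depths$pct_accessible
  depths
}

#' Generate a synthetic semidiurnal tide-extreme series
#'
#' Simulates the water level as the sum of two semidiurnal harmonics - a
#' principal lunar constituent (period 12.4206 h) and a solar constituent
#' (12 h) whose interference produces the spring-neap cycle - plus a mean
#' level, then extracts the alternating high/low extremes. With the
#' secondary amplitude at zero all highs (and all lows) are equal.
#'
#' @param n_days Number of days (>= 1).
#' @param principal_amplitude,secondary_amplitude Constituent amplitudes (m).
#' @param mean_level Mean water level above the datum (m).
#' @param seed Integer seed (randomises the constituent phases).
#' @param start Series start time (POSIXct or ISO string, UTC).
#' @return A tibble of extremes: `time` (POSIXct), `height` (m), `kind`
#'   (`"H"`/`"L"`), strictly increasing and alternating.
#' @export
generate_tides <- function(n_days = 365, principal_amplitude = 1.2,
                           secondary_amplitude = 0.4, mean_level = 1.8,
                           seed = 1L, start = "2017-04-01") {
  if (n_days < 1) stop_invalid("`n_days` must be >= 1.")
  if (principal_amplitude < 0 || secondary_amplitude < 0) {
    stop_invalid("amplitudes must be >= 0.")
  }
  t0 <- as.POSIXct(start, tz = "UTC")
  T1 <- 12.4206 * 3600
  T2 <- 12 * 3600
  phases <- with_seed(seed, stats::runif(2, 0, 2 * pi))
  height_fun <- function(s) {
    mean_level + principal_amplitude * cos(2 * pi * s / T1 + phases[1]) +
      secondary_amplitude * cos(2 * pi * s / T2 + phases[2])
  }
  s <- seq(0, n_days * 86400, by = 60)
  h <- height_fun(s)
  dh <- diff(h)
  # local extrema: sign change of the first difference
  turn <- which(dh[-1] * dh[-length(dh)] < 0) + 1L
  if (length(turn) < 2L) stop_invalid("tide series too short to contain extremes.")
  # refine each extremum on a 1-second grid around the coarse location
  ref <- vapply(turn, function(i) {
    win <- seq(max(0, s[i] - 120), min(n_days * 86400, s[i] + 120), by = 1)
    hw <- height_fun(win)
    if (h[i + 1L] < h[i]) win[which.max(hw)] else win[which.min(hw)]
  }, numeric(1))
  heights <- height_fun(ref)
  kind <- ifelse(c(diff(heights) < 0, NA), "H", "L")
  kind[length(kind)] <- if (kind[length(kind) - 1L] == "H") "L" else "H"
  tibble::tibble(time = t0 + ref, height = heights, kind = kind)
}
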