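# Shared fixtures, all generated in code.

flat_profile <- function(length = 5, res = 0.005) {
  x <- seq(0, length, by = res)
  reef_profile(x, rep(0, length(x)), resolution = res)
}

ramp_profile <- function(gradient = 1, length = 5, res = 0.005) {
  x <- seq(0, length, by = res)
  reef_profile(x, gradient * x, resolution = res)
}

# 45-degree sawtooth with 0.2 m period
sawtooth_profile <- function(length = 5, res = 0.005) {
  x <- seq(0, length, by = res)
  reef_profile(x, abs((x %% 0.2) - 0.1), resolution = res)
}

# Alternating extremes of a pure sinusoid A*cos(2*pi*t/period) + mean_level,
# starting at a high at t = 0.
sinusoid_extremes <- function(A = 1.2, mean_level = 0, period = 12 * 3600,
                              n_half = 60) {
  ts <- seq(0, n_half * period / 2, by = period / 2)
  tibble::tibble(time = ts,
                 height = mean_level + A * cos(2 * pi * ts / period),
                 kind = rep(c("H", "L"), length.out = length(ts)))
}

# Small unit table for the fish-count generator.
toy_units <- function(n = 15, grazing = NULL, seed = 1) {
  g <- grazing %||% withr::with_seed(seed, stats::runif(n, 0.2, 0.7))
  tibble::tibble(site = paste0("site", rep(1:3, length.out = n)),
                 habitat = paste0("h", seq_len(n)),
                 grazing = g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

expect_tbl_cols <- function(x, cols) {
  expect_true(all(cols %in% names(x)))
}
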