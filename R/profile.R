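#' Construct an elevation profile
#'
#' An elevation profile is an ordered cross-section of the benthos: planar
#' distance `x` (m, strictly increasing) against elevation `z` (m). It is the
#' fundamental input to every structural metric.
#'
#' @param x,z Numeric vectors of equal length (>= 2), metres.
#' @param resolution Nominal sample spacing in metres; defaults to the median
#'   spacing of `x`.
#' @return A tibble of class `reef_profile` with columns `x` and `z`.
#' @export
#' @examples
#' reef_profile(c(0, 3), c(0, 4))
reef_profile <- function(x, z, resolution = NULL) {
  if (length(x) != length(z) || length(x) < 2L) {
    stop_invalid("a profile needs >= 2 (x, z) samples of equal length.")
  }
  if (!all(is.finite(x)) || !all(is.finite(z))) {
    stop_invalid("profile coordinates must all be finite.")
  }
  if (any(diff(x) <= 0)) stop_invalid("`x` must be strictly increasing.")
  out <- tibble::tibble(x = as.numeric(x), z = as.numeric(z))
  attr(out, "resolution") <- resolution %||% stats::median(diff(x))
  attr(out, "planted") <- list(
    crevices = tibble::tibble(x = numeric(), width = numeric(), depth = numeric()),
    overhangs = tibble::tibble(x = numeric(), height = numeric())
  )
  class(out) <- c("reef_profile", class(out))
  out
}

profile_extent <- function(profile) range(profile$x)

#' Planted-refuge ground truth of a synthetic profile
#'
#' @param profile A `reef_profile`.
#' @return A list with tibbles `crevices` (`x`, `width`, `depth`) and
#'   `overhangs` (`x`, `height`) recording features planted by
#'   [insert_crevice()] / [insert_overhang()] or by [generate_study()].
#' @export
planted_refuges <- function(profile) {
  attr(profile, "planted") %||% list(
    crevices = tibble::tibble(x = numeric(), width = numeric(), depth = numeric()),
    overhangs = tibble::tibble(x = numeric(), height = numeric())
  )
}

# One level-by-level midpoint displacement pass on a dyadic grid.
# Returns displacements with standard deviation scaled to `amplitude`.
# The per-level amplitude decays as 2^-hurst, giving terrain whose local
# slopes soften at fine scales (hurst > 1): rough at the decimetre-to-metre
# scales that drive rugosity, without near-vertical sampling artefacts at
# the millimetre grid.
midpoint_displacement <- function(n_segments, amplitude, hurst = 1.3) {
  k <- max(1L, ceiling(log2(n_segments)))
  n <- 2L^k + 1L
  z <- numeric(n)
  step <- 2L^k
  amp <- 1
  decay <- 2^(-hurst)
  while (step > 1L) {
    half <- step %/% 2L
    idx <- seq(half + 1L, n, by = step)
    left <- z[idx - half]
    right <- z[pmin(idx + half, n)]
    z[idx] <- (left + right) / 2 + stats::rnorm(length(idx), 0, amp)
    amp <- amp * decay
    step <- half
  }
  s <- stats::sd(z)
  if (s > 0) z <- z * (amplitude / s)
  z
}

#' Generate a synthetic elevation profile
#'
#' Builds one reef cross-section as a base ramp (`base_gradient * x`) plus
#' midpoint-displacement roughness whose standard deviation equals the
#' archetype's `roughness_amplitude`. Deterministic for a fixed seed.
#'
#' @param archetype A [habitat_archetype()].
#' @param length Transect length in metres (> 0).
#' @param resolution Sample spacing in metres (0 < resolution <= 0.01).
#' @param seed Integer seed.
#' @return A [reef_profile()] sampled on `seq(0, length, by = resolution)`.
#' @export
#' @examples
#' p <- generate_profile(default_archetypes()$crest, seed = 1)
#' rugosity_index(p)
generate_profile <- function(archetype, length = 5, resolution = 0.005, seed = 1L) {
  stopifnot(inherits(archetype, "habitat_archetype"))
  check_scalar_pos(length, "length")
  check_scalar_pos(resolution, "resolution")
  if (resolution > 0.01) stop_invalid("`resolution` must be <= 0.01 m.")
  x <- seq(0, length, by = resolution)
  n_seg <- length(x) - 1L
  disp <- if (archetype$roughness_amplitude > 0) {
    d <- with_seed(seed, midpoint_displacement(n_seg, archetype$roughness_amplitude))
    grid <- seq(0, length, length.out = length(d))
    stats::approx(grid, d, xout = x)$y
  } else {
    numeric(length(x))
  }
  reef_profile(x, archetype$base_gradient * x + disp, resolution = resolution)
}

#' Carve a crevice into a profile
#'
#' Cuts a notch of the stated rim width and depth, with short tapered rims so
#' the opening width is well defined, and records the feature in the
#' profile's ground-truth registry. A rule-conforming notch (width 10-20 cm,
#' depth >= 10 cm) is recovered by [detect_refuges()].
#'
#' @param profile A `reef_profile`.
#' @param x Planar position of the crevice's left rim (m).
#' @param width Rim opening width (m); `[x, x + width]` must lie inside the
#'   profile extent.
#' @param depth Vertical depth of the notch (m, > 0).
#' @return The modified profile, ground-truth registry updated.
#' @export
insert_crevice <- function(profile, x, width, depth) {
  check_scalar_pos(width, "width")
  check_scalar_pos(depth, "depth")
  ext <- profile_extent(profile)
  if (x < ext[1] || x + width > ext[2]) {
    stop_invalid("crevice [x, x + width] must lie inside the profile extent.")
  }
  taper <- min(0.01, width / 6)
  u <- profile$x - x
  inside <- u > 0 & u < width
  z <- profile$z
  rims <- stats::approx(profile$x, profile$z, xout = c(x, x + width))$y
  # flat floor a fixed depth below the lower rim shoulder, short tapered
  # walls up to each rim: the notch keeps its nominal depth and admits a
  # disc as wide as its floor regardless of the terrain gradient
  floor_level <- min(rims) - depth
  rim_line <- stats::approx(c(x, x + width), rims, xout = profile$x[inside])$y
  wall <- pmin(1, u[inside] / taper, (width - u[inside]) / taper)
  target <- rim_line + (floor_level - rim_line) * wall
  z[inside] <- pmin(z[inside], target)
  out <- reef_profile(profile$x, z, attr(profile, "resolution"))
  planted <- planted_refuges(profile)
  planted$crevices <- dplyr::bind_rows(
    planted$crevices, tibble::tibble(x = x + width / 2, width = width, depth = depth)
  )
  attr(out, "planted") <- planted
  out
}

#' Add a near-vertical step (overhang proxy) to a profile
#'
#' Single-valued cross-sections cannot represent true undercuts, so an
#' overhang is modelled as a near-vertical surface of the stated height: the
#' terrain beyond `x` is raised by `height` over a two-sample ramp.
#'
#' @param profile A `reef_profile`.
#' @param x Planar position of the step (m), inside the extent.
#' @param height Vertical extent of the step (m, > 0).
#' @return The modified profile, ground-truth registry updated.
#' @export
insert_overhang <- function(profile, x, height) {
  check_scalar_pos(height, "height")
  ext <- profile_extent(profile)
  if (x <= ext[1] || x >= ext[2]) stop_invalid("`x` must lie inside the profile extent.")
  res <- attr(profile, "resolution")
  ramp <- 2 * res
  u <- profile$x - x
  z <- profile$z + height * pmin(1, pmax(0, u / ramp))
  out <- reef_profile(profile$x, z, res)
  planted <- planted_refuges(profile)
  planted$overhangs <- dplyr::bind_rows(
    planted$overhangs, tibble::tibble(x = x, height = height)
  )
  attr(out, "planted") <- planted
  out
}

#' Generate a benthic segmentation for a profile
#'
#' Tiles the planar extent `[0, length)` with contiguous half-open patches;
#' patch lengths are exponential with the stated mean and each patch's label
#' is drawn independently from the archetype's `cover_probs`, so the expected
#' planar fraction of each label equals its probability.
#'
#' @param profile A `reef_profile`.
#' @param archetype A [habitat_archetype()] supplying `cover_probs`.
#' @param mean_patch_length Mean patch length in metres (> 0).
#' @param seed Integer seed.
#' @return A tibble with columns `start`, `end` (m) and `label`.
#' @export
generate_segmentation <- function(profile, archetype, mean_patch_length = 0.4, seed = 1L) {
  stopifnot(inherits(archetype, "habitat_archetype"))
  check_scalar_pos(mean_patch_length, "mean_patch_length")
  ext <- profile_extent(profile)
  len <- ext[2] - ext[1]
  with_seed(seed, {
    # Draw more patches than could be needed, then truncate the tiling.
    n_guess <- max(10L, ceiling(4 * len / mean_patch_length))
    lengths <- stats::rexp(n_guess, rate = 1 / mean_patch_length)
    while (sum(lengths) < len) {
      lengths <- c(lengths, stats::rexp(n_guess, rate = 1 / mean_patch_length))
    }
    ends <- ext[1] + cumsum(lengths)
    keep <- seq_len(which(ends >= ext[2])[1])
    ends <- pmin(ends[keep], ext[2])
    starts <- c(ext[1], utils::head(ends, -1))
    probs <- archetype$cover_probs
    labels <- sample(names(probs), length(starts), replace = TRUE, prob = probs)
    tibble::tibble(start = starts, end = ends, label = labels)
  })
}
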