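#' Contoured (chain) length of a profile
#'
#' The virtual chain-and-tape measure: the sum of Euclidean segment lengths
#' `sqrt(dx^2 + dz^2)` over consecutive samples, optionally restricted to a
#' planar sub-range. Range endpoints falling between samples are honoured by
#' linear interpolation, which makes the measure additive over any partition
#' of the transect.
#'
#' @param profile A [reef_profile()].
#' @param range Optional `c(x_start, x_end)` within the profile extent.
#' @return Length in metres.
#' @export
#' @examples
#' contour_length(reef_profile(c(0, 3), c(0, 4)))  # 5
contour_length <- function(profile, range = NULL) {
  x <- profile$x
  z <- profile$z
  if (!is.null(range)) {
    if (length(range) != 2L || range[1] >= range[2]) {
      stop_invalid("`range` must be c(x_start, x_end) with x_start < x_end.")
    }
    ext <- profile_extent(profile)
    if (range[1] < ext[1] - 1e-12 || range[2] > ext[2] + 1e-12) {
      stop_invalid("`range` must lie within the profile extent.")
    }
    zr <- stats::approx(x, z, xout = range, rule = 2)$y
    keep <- x > range[1] & x < range[2]
    x <- c(range[1], x[keep], range[2])
    z <- c(zr[1], z[keep], zr[2])
  }
  sum(sqrt(diff(x)^2 + diff(z)^2))
}

#' Rugosity index
#'
#' The classic chain-and-tape roughness measure: the ratio of the contoured
#' surface length to its planar distance, `RI = L_chain / D_chain`. Equals 1
#' for flat terrain and exceeds 1 otherwise.
#'
#' @param profile A [reef_profile()].
#' @return Dimensionless index >= 1.
#' @export
rugosity_index <- function(profile) {
  ext <- profile_extent(profile)
  planar <- ext[2] - ext[1]
  if (planar <= 0) stop_invalid("profile has zero planar span.")
  contour_length(profile) / planar
}

#' Verticality: mean absolute rate of elevation change
#'
#' The profile is linearly resampled on a grid of fixed planar intervals
#' anchored at the transect start; for each interval the absolute elevation
#' change divided by the interval length, `A(x) = |f(b) - f(a)| / interval`,
#' is computed and the mean over intervals returned. A trailing partial
#' interval is dropped. The 10 cm default matches the body scale at which
#' reef fishes engage with structure.
#'
#' @param profile A [reef_profile()].
#' @param interval Planar interval in metres (default 0.10).
#' @return Dimensionless mean rate of change >= 0.
#' @export
verticality <- function(profile, interval = 0.10) {
  check_scalar_pos(interval, "interval")
  ext <- profile_extent(profile)
  if (ext[2] - ext[1] < interval) stop_invalid("profile span is shorter than `interval`.")
  n <- floor((ext[2] - ext[1]) / interval + 1e-9)
  grid <- ext[1] + interval * (0:n)
  # rule = 2 guards the last grid point against floating-point overshoot of
  # the profile end (the grid never genuinely exceeds the span)
  zg <- stats::approx(profile$x, profile$z, xout = grid, rule = 2)$y
  mean(abs(diff(zg)) / interval)
}

check_segmentation <- function(profile, seg) {
  if (!all(c("start", "end", "label") %in% names(seg))) {
    stop_invalid("segmentation needs columns `start`, `end`, `label`.")
  }
  if (any(seg$start >= seg$end)) stop_invalid("segmentation intervals need start < end.")
  ext <- profile_extent(profile)
  if (any(seg$start < ext[1] - 1e-9) || any(seg$end > ext[2] + 1e-9)) {
    stop_invalid("segmentation exceeds the profile extent.")
  }
  o <- order(seg$start)
  if (any(seg$end[o][-nrow(seg)] > seg$start[o][-1] + 1e-9)) {
    stop_invalid("segmentation intervals overlap.")
  }
  invisible(seg)
}

#' Contour-length cover fraction of benthic categories
#'
#' The fraction of the contoured (not planar) profile length lying over
#' intervals whose label is in `labels`; on rugose terrain a category draped
#' over steep structure contributes more than its planar footprint.
#'
#' @param profile A [reef_profile()].
#' @param seg Benthic segmentation tibble (`start`, `end`, `label`,
#'   half-open intervals `[start, end)`).
#' @param labels Character vector of benthic category labels to count.
#' @return Proportion in \[0, 1\] of the total contour length.
#' @export
cover_fraction <- function(profile, seg, labels) {
  check_segmentation(profile, seg)
  total <- contour_length(profile)
  hit <- seg[seg$label %in% labels, , drop = FALSE]
  if (nrow(hit) == 0L) return(0)
  sum(vapply(seq_len(nrow(hit)), function(i) {
    contour_length(profile, c(hit$start[i], hit$end[i]))
  }, numeric(1))) / total
}

#' Grazing surface area fraction
#'
#' The fraction of the contoured profile covered in short algal turfs on
#' consolidated substratum (the epilithic algal matrix) - the nutritional
#' resource grazed by roving herbivores. Macroalgae, sand and live coral are
#' excluded.
#'
#' @inheritParams cover_fraction
#' @return Proportion in \[0, 1\].
#' @export
grazing_area_fraction <- function(profile, seg) {
  cover_fraction(profile, seg, "turf_EAM")
}

#' Compute the six structural/nutritional metrics for one transect
#'
#' Combines [rugosity_index()], [verticality()], hard-coral
#' [cover_fraction()], [detect_refuges()] (crevices + overhangs pooled),
#' [field_of_view()] and [grazing_area_fraction()] into a one-row record.
#'
#' @param profile A [reef_profile()].
#' @param seg Benthic segmentation for the profile.
#' @param config An [observer_config()] for the field-of-view metric.
#' @param interval Verticality interval (m).
#' @param ... Passed to [detect_refuges()].
#' @return A one-row tibble with columns `rugosity`, `verticality`,
#'   `coral_cover`, `refuge_count`, `fov_visible`, `grazing_area`.
#' @export
compute_metrics <- function(profile, seg, config = observer_config(),
                            interval = 0.10, ...) {
  refuges <- detect_refuges(profile, ...)
  fov <- field_of_view(profile, config)
  tibble::tibble(
    rugosity = rugosity_index(profile),
    verticality = verticality(profile, interval),
    coral_cover = cover_fraction(profile, seg, "hard_coral"),
    refuge_count = nrow(refuges$crevices) + nrow(refuges$overhangs),
    fov_visible = fov$transect_visible,
    grazing_area = grazing_area_fraction(profile, seg)
  )
}
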