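#' Observer configuration for the feeding field-of-view metric
#'
#' Observers stand in for herbivorous fish feeding on the benthos: the eye
#' sits 2.5 cm above the substratum, observers are placed every metre from
#' 0.5 m along the transect, and only terrain within the sight length (2.5 m,
#' the scale of flight-initiation distance and local water visibility) can
#' obstruct the view.
#'
#' @param eye_height Eye height above the benthos (m).
#' @param spacing Distance between observers (m).
#' @param first_offset Position of the first observer (m).
#' @param sight_length Horizontal extent considered (m).
#' @return An object of class `observer_config`.
#' @export
observer_config <- function(eye_height = 0.025, spacing = 1.0,
                            first_offset = 0.5, sight_length = 2.5) {
  for (nm in c("eye_height", "spacing", "first_offset", "sight_length")) {
    check_scalar_pos(get(nm), nm)
  }
  structure(list(eye_height = eye_height, spacing = spacing,
                 first_offset = first_offset, sight_length = sight_length),
            class = "observer_config")
}

#' Observer positions and viewing directions along a transect
#'
#' Observers are placed at `first_offset`, `first_offset + spacing`, ... and
#' each looks horizontally inwards, towards the transect midpoint. An
#' observer at the exact midpoint looks in both directions.
#'
#' @param transect_length Transect length (m), must exceed `first_offset`.
#' @param config An [observer_config()].
#' @return A tibble with columns `x` and `direction`
#'   (`"left"` / `"right"`); midpoint observers contribute two rows.
#' @export
#' @examples
#' observer_positions(5)  # 0.5 ... 4.5, both directions at 2.5
observer_positions <- function(transect_length, config = observer_config()) {
  if (transect_length <= config$first_offset) {
    stop_invalid("`transect_length` must exceed the first observer offset.")
  }
  xs <- seq(config$first_offset, transect_length - 1e-9, by = config$spacing)
  mid <- transect_length / 2
  purrr::map_dfr(xs, function(x) {
    if (abs(x - mid) < 1e-9) {
      tibble::tibble(x = x, direction = c("left", "right"))
    } else {
      tibble::tibble(x = x, direction = if (x < mid) "right" else "left")
    }
  })
}

#' Maximum obstruction angle seen by one observer
#'
#' The eye sits at `z(x_obs) + eye_height`. The obstruction angle is the
#' largest angle above the horizontal subtended by any terrain sample within
#' `sight_length` horizontal distance in the viewing direction - the sample
#' that would physically block the secant to the sky. Downward angles clamp
#' to zero (a fish looking over a drop-off keeps its full upward view), and
#' the result is capped at 90 degrees.
#'
#' @param profile A [reef_profile()].
#' @param x_obs Observer position (m), inside the profile extent.
#' @param direction `"left"` or `"right"`.
#' @param config An [observer_config()].
#' @return Angle in degrees, in \[0, 90\].
#' @export
obstruction_angle <- function(profile, x_obs, direction = c("right", "left"),
                              config = observer_config()) {
  direction <- match.arg(direction)
  ext <- profile_extent(profile)
  if (x_obs < ext[1] || x_obs > ext[2]) stop_invalid("`x_obs` outside the profile extent.")
  z_eye <- stats::approx(profile$x, profile$z, xout = x_obs)$y + config$eye_height
  dx <- profile$x - x_obs
  if (direction == "right") {
    keep <- dx > 1e-12 & dx <= config$sight_length
  } else {
    keep <- dx < -1e-12 & dx >= -config$sight_length
  }
  if (!any(keep)) return(0)
  theta <- atan2(profile$z[keep] - z_eye, abs(dx[keep])) * 180 / pi
  min(90, max(0, theta))
}

#' Feeding field of view along a transect
#'
#' For each observer the visible fraction of the upward 90-degree quadrant is
#' `(90 - theta) / 90`, where `theta` is the [obstruction_angle()]; a
#' midpoint observer contributes the mean of its two directions so every
#' observer location carries equal weight. The transect-level score is the
#' mean over observer locations.
#'
#' @param profile A [reef_profile()].
#' @param config An [observer_config()].
#' @return A list of class `viewshed` with `per_observer` (tibble: `x`,
#'   `direction`, `theta`, `visible_fraction`), `transect_visible` and
#'   `transect_blocked`.
#' @export
#' @examples
#' field_of_view(generate_profile(default_archetypes()$crest, seed = 1))$transect_visible
field_of_view <- function(profile, config = observer_config()) {
  ext <- profile_extent(profile)
  obs <- observer_positions(ext[2] - ext[1], config)
  obs$x <- obs$x + ext[1]
  obs$theta <- purrr::map2_dbl(obs$x, obs$direction, function(x, d) {
    obstruction_angle(profile, x, d, config)
  })
  obs$visible_fraction <- (90 - obs$theta) / 90
  per_location <- dplyr::summarise(
    dplyr::group_by(obs, .data$x),
    visible = mean(.data$visible_fraction), .groups = "drop"
  )
  visible <- mean(per_location$visible)
  structure(list(per_observer = obs,
                 transect_visible = visible,
                 transect_blocked = 1 - visible),
            class = "viewshed")
}

#' @export
print.viewshed <- function(x, ...) {
  cat("<viewshed> visible fraction ", round(x$transect_visible, 3),
      " over ", length(unique(x$per_observer$x)), " observers\n", sep = "")
  invisible(x)
}
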