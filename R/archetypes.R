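#' Define a reef habitat archetype
#'
#' An archetype parameterises the synthetic generator for one habitat zone of
#' a fringing-reef gradient: the underlying slope of the benthos, the
#' amplitude of its topographic roughness, the benthic community composition,
#' and the expected density of physical refuges.
#'
#' @param name Habitat name, one of `"slope"`, `"crest"`, `"outer_flat"`,
#'   `"mid_flat"`, `"inner_flat"`.
#' @param base_gradient Dimensionless slope of the underlying ramp (dz/dx).
#' @param roughness_amplitude Standard deviation (m) of the midpoint
#'   displacement noise added to the ramp. Zero gives a perfectly smooth ramp.
#' @param cover_probs Named numeric vector of per-label probabilities over the
#'   benthic categories `hard_coral`, `turf_EAM`, `macroalgae`, `sand`,
#'   `other`; must sum to 1.
#' @param crevice_rate Expected number of crevices per 5 m transect.
#' @param overhang_rate Expected number of overhangs per 5 m transect.
#' @param benthos_level Benthos elevation (m) relative to the tide datum, used
#'   when deriving depths and tidal accessibility for the habitat.
#'
#' @return An object of class `habitat_archetype` (a named list).
#' @export
#' @examples
#' habitat_archetype("crest", base_gradient = 0.15, roughness_amplitude = 0.4,
#'   cover_probs = c(hard_coral = 0.36, turf_EAM = 0.52, macroalgae = 0.02,
#'                   sand = 0.06, other = 0.04),
#'   crevice_rate = 3, overhang_rate = 1.5)
habitat_archetype <- function(name,
                              base_gradient = 0,
                              roughness_amplitude = 0.1,
                              cover_probs = NULL,
                              crevice_rate = 0,
                              overhang_rate = 0,
                              benthos_level = 0) {
  name <- match.arg(name, c("slope", "crest", "outer_flat", "mid_flat", "inner_flat"))
  if (roughness_amplitude < 0) stop_invalid("`roughness_amplitude` must be >= 0.")
  if (crevice_rate < 0 || overhang_rate < 0) stop_invalid("refuge rates must be >= 0.")
  if (is.null(cover_probs)) {
    cover_probs <- c(hard_coral = 0.2, turf_EAM = 0.5, macroalgae = 0.1,
                     sand = 0.15, other = 0.05)
  }
  full <- stats::setNames(numeric(length(benthic_labels())), benthic_labels())
  if (is.null(names(cover_probs)) || !all(names(cover_probs) %in% benthic_labels())) {
    stop_invalid("`cover_probs` must be named with benthic category labels.")
  }
  full[names(cover_probs)] <- cover_probs
  if (any(full < 0) || any(full > 1) || abs(sum(full) - 1) > 1e-9) {
    stop_invalid("`cover_probs` entries must lie in [0, 1] and sum to 1.")
  }
  structure(
    list(name = name, base_gradient = base_gradient,
         roughness_amplitude = roughness_amplitude, cover_probs = full,
         crevice_rate = crevice_rate, overhang_rate = overhang_rate,
         benthos_level = benthos_level),
    class = "habitat_archetype"
  )
}

#' Default archetypes for the five-habitat reef gradient
#'
#' Parameter choices encode the qualitative gradient of an inner-shelf
#' fringing reef: topographic complexity and coral cover peak on the slope and
#' crest and decline shoreward across the flat; the grazing surface (short
#' algal turfs on consolidated substratum) is maximal on the outer-flat; the
#' mid-flat is macroalgae-dominated and the inner-flat sandy. Benthos levels
#' are relative to the tide-table datum, with the slope well below the lowest
#' low water and the inner-flat shallowest.
#'
#' @return A named list of five [habitat_archetype()] objects, in gradient
#'   order `slope`, `crest`, `outer_flat`, `mid_flat`, `inner_flat`.
#' @export
default_archetypes <- function() {
  list(
    slope = habitat_archetype(
      "slope", base_gradient = 0.5, roughness_amplitude = 0.35,
      cover_probs = c(hard_coral = 0.35, turf_EAM = 0.545, macroalgae = 0.02,
                      sand = 0.05, other = 0.035),
      crevice_rate = 3, overhang_rate = 2, benthos_level = -2.5
    ),
    crest = habitat_archetype(
      "crest", base_gradient = 0.15, roughness_amplitude = 0.4,
      cover_probs = c(hard_coral = 0.361, turf_EAM = 0.515, macroalgae = 0.02,
                      sand = 0.06, other = 0.044),
      crevice_rate = 3.5, overhang_rate = 2, benthos_level = -0.6
    ),
    outer_flat = habitat_archetype(
      "outer_flat", base_gradient = 0.03, roughness_amplitude = 0.12,
      cover_probs = c(hard_coral = 0.12, turf_EAM = 0.573, macroalgae = 0.06,
                      sand = 0.2, other = 0.047),
      crevice_rate = 1, overhang_rate = 0.5, benthos_level = -0.3
    ),
    mid_flat = habitat_archetype(
      "mid_flat", base_gradient = 0.02, roughness_amplitude = 0.08,
      cover_probs = c(hard_coral = 0.05, turf_EAM = 0.30, macroalgae = 0.45,
                      sand = 0.15, other = 0.05),
      crevice_rate = 0.5, overhang_rate = 0.3, benthos_level = -0.1
    ),
    inner_flat = habitat_archetype(
      "inner_flat", base_gradient = 0.02, roughness_amplitude = 0.06,
      cover_probs = c(hard_coral = 0.04, turf_EAM = 0.385, macroalgae = 0.10,
                      sand = 0.43, other = 0.045),
      crevice_rate = 0.3, overhang_rate = 0.2, benthos_level = 0.1
    )
  )
}
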