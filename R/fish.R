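#' Allometric weight from total length
#'
#' Standard length-weight allometry `W = a * L^b`, with `a` in g cm^-b and
#' `L` in cm, as parameterised by length-weight regressions for each species.
#'
#' @param length Total length(s) in cm (> 0).
#' @param a Coefficient (> 0).
#' @param b Allometric exponent (typically near 3).
#' @return Weight(s) in grams.
#' @export
#' @examples
#' weight_from_length(10, a = 0.01, b = 3)  # 10 g
weight_from_length <- function(length, a, b) {
  if (any(length <= 0)) stop_invalid("`length` must be positive.")
  if (any(a <= 0)) stop_invalid("`a` must be positive.")
  a * length^b
}

#' Midpoint of a size class
#'
#' Census fishes are binned into total-length classes (5 cm bins above 10 cm
#' TL, 2.5 cm bins below); the class midpoint is the representative length
#' used for biomass.
#'
#' @param lower,upper Class bounds in cm (`lower < upper`).
#' @return Midpoint length(s) in cm.
#' @export
class_midpoint <- function(lower, upper) {
  if (any(lower >= upper)) stop_invalid("size class needs lower < upper.")
  (lower + upper) / 2
}

check_records <- function(records) {
  need <- c("site", "habitat", "replicate", "species", "tl_lower_cm",
            "tl_upper_cm", "count", "transect_length_m", "transect_width_m")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop_invalid("survey records missing column(s): ",
                                 paste(miss, collapse = ", "))
  if (any(records$count < 0)) stop_invalid("counts must be >= 0.")
  if (any(records$transect_length_m <= 0)) stop_invalid("zero transect area.")
  if (any(records$transect_width_m <= 0)) stop_invalid("zero transect area.")
  invisible(records)
}

#' Standardise census records to density and biomass per unit area
#'
#' Each record's count is converted to a density on its own belt transect
#' (`count / (length x width)`) and scaled to the target area, so the narrow
#' small-fish belt (1 m, fishes < 10 cm TL) and the wide large-fish belt
#' (5 m, fishes > 10 cm TL) are standardised separately before being summed.
#' Replicate census days are averaged per site x habitat unit. Biomass uses
#' the size-class midpoint and [weight_from_length()], reported in kg.
#'
#' @param records Survey tibble with columns `site`, `habitat`, `replicate`,
#'   `species`, `tl_lower_cm`, `tl_upper_cm`, `count`, `transect_length_m`,
#'   `transect_width_m`.
#' @param lw_params Tibble `species`, `a`, `b` of length-weight parameters.
#' @param target_area Reporting area in m^2 (default 250).
#' @return A tibble with one row per site x habitat x species x size group
#'   (`size_group` in `"small"`/`"large"`, split at 10 cm TL), holding
#'   `abundance` (ind. per `target_area`) and `biomass_kg` (kg per
#'   `target_area`), averaged over replicates.
#' @export
standardize_density <- function(records, lw_params, target_area = 250) {
  check_records(records)
  check_scalar_pos(target_area, "target_area")
  recs <- dplyr::left_join(records, lw_params, by = "species")
  if (anyNA(recs$a)) {
    bad <- unique(recs$species[is.na(recs$a)])
    stop_invalid("no length-weight parameters for: ", paste(bad, collapse = ", "))
  }
  recs <- dplyr::mutate(
    recs,
    size_group = ifelse(.data$tl_upper_cm <= 10, "small", "large"),
    midpoint = class_midpoint(.data$tl_lower_cm, .data$tl_upper_cm),
    dens = .data$count / (.data$transect_length_m * .data$transect_width_m) * target_area,
    biom = .data$dens * weight_from_length(.data$midpoint, .data$a, .data$b) / 1000
  )
  n_rep <- dplyr::summarise(
    dplyr::group_by(recs, .data$site, .data$habitat),
    n_rep = dplyr::n_distinct(.data$replicate), .groups = "drop"
  )
  per_rep <- dplyr::summarise(
    dplyr::group_by(recs, .data$site, .data$habitat, .data$replicate,
                    .data$species, .data$size_group),
    abundance = sum(.data$dens), biomass_kg = sum(.data$biom), .groups = "drop"
  )
  # average over replicate days; a species absent on a day contributes zero
  out <- dplyr::summarise(
    dplyr::group_by(per_rep, .data$site, .data$habitat, .data$species, .data$size_group),
    abundance = sum(.data$abundance), biomass_kg = sum(.data$biomass_kg),
    .groups = "drop"
  )
  out <- dplyr::left_join(out, n_rep, by = c("site", "habitat"))
  dplyr::select(
    dplyr::mutate(out,
                  abundance = .data$abundance / .data$n_rep,
                  biomass_kg = .data$biomass_kg / .data$n_rep),
    -"n_rep"
  )
}

#' Build the site x habitat assemblage table
#'
#' Assembles the species-by-unit matrices used by the multivariate and
#' fish-distribution models: abundance split into small (< 10 cm TL) and
#' large (> 10 cm TL) individuals, biomass pooled across sizes, plus a
#' covariate block (per-unit metric means and depth).
#'
#' @param records Survey records (see [standardize_density()]).
#' @param lw_params Length-weight parameter tibble.
#' @param covariates Optional tibble keyed by `site` and `habitat` with
#'   per-unit covariate columns (e.g. metric means, `depth`).
#' @param target_area Reporting area in m^2.
#' @return An object of class `assemblage`: a list with tibbles `abundance`
#'   (unit rows, species-size columns), `biomass` (unit rows, species
#'   columns), `units` (site, habitat, totals) and `covariates`.
#' @export
build_assemblage <- function(records, lw_params, covariates = NULL,
                             target_area = 250) {
  dens <- standardize_density(records, lw_params, target_area)
  units <- dplyr::distinct(dens, .data$site, .data$habitat)
  units <- dplyr::arrange(units, .data$site, .data$habitat)
  if (!is.null(covariates)) {
    miss <- dplyr::anti_join(units, covariates, by = c("site", "habitat"))
    if (nrow(miss)) {
      stop_invalid("covariates missing for unit(s): ",
                   paste(paste(miss$site, miss$habitat, sep = "/"), collapse = ", "))
    }
    covariates <- dplyr::left_join(units, covariates, by = c("site", "habitat"))
  }
  ab <- tidyr::pivot_wider(
    dplyr::mutate(dens, col = paste(.data$species, .data$size_group, sep = "|")),
    id_cols = c("site", "habitat"), names_from = "col",
    values_from = "abundance", values_fill = 0
  )
  ab <- dplyr::arrange(ab, .data$site, .data$habitat)
  bio <- dplyr::summarise(
    dplyr::group_by(dens, .data$site, .data$habitat, .data$species),
    biomass_kg = sum(.data$biomass_kg), .groups = "drop"
  )
  bio <- tidyr::pivot_wider(bio, id_cols = c("site", "habitat"),
                            names_from = "species", values_from = "biomass_kg",
                            values_fill = 0)
  bio <- dplyr::arrange(bio, .data$site, .data$habitat)
  totals <- dplyr::summarise(
    dplyr::group_by(dens, .data$site, .data$habitat),
    abundance = sum(.data$abundance), biomass_kg = sum(.data$biomass_kg),
    .groups = "drop"
  )
  totals <- dplyr::arrange(totals, .data$site, .data$habitat)
  structure(list(abundance = ab, biomass = bio, units = totals,
                 covariates = covariates),
            class = "assemblage")
}

#' @export
print.assemblage <- function(x, ...) {
  cat("<assemblage> ", nrow(x$units), " site x habitat units, ",
      ncol(x$biomass) - 2L, " species\n", sep = "")
  invisible(x)
}

#' Generate synthetic timed-swim census records
#'
#' Per survey unit the expected total abundance (individuals per 250 m^2)
#' follows a log-linear dependence on the unit's grazing surface fraction,
#' `mu = exp(beta0 + beta1 * grazing)`, with negative-binomial dispersion
#' `k`. Individuals are allocated to species and total-length size classes
#' according to `species_profile`, and observed counts are generated per belt
#' transect: large fishes (> 10 cm TL) on a 5 m belt, small fishes on a 1 m
#' belt, each over `n_replicates` census days with transect lengths drawn
#' around 47.25 m.
#'
#' @param units Tibble with columns `site`, `habitat` and `grazing`
#'   (grazing surface fraction in \[0, 1\]).
#' @param beta0,beta1 Log-linear intercept and grazing slope.
#' @param dispersion_k Negative-binomial size parameter (> 0).
#' @param species_profile Tibble `species`, `prop` (relative mix, sums to 1),
#'   `p_small` (probability an individual is < 10 cm TL); see
#'   [default_species_profile()].
#' @param n_replicates Census days per unit.
#' @param seed Integer seed.
#' @return A survey-record tibble accepted by [standardize_density()].
#' @export
generate_fish_counts <- function(units, beta0 = 3.25, beta1 = 3,
                                 dispersion_k = 5,
                                 species_profile = default_species_profile(),
                                 n_replicates = 3, seed = 1L) {
  if (any(units$grazing < 0 | units$grazing > 1)) {
    stop_invalid("grazing fractions must lie in [0, 1].")
  }
  check_scalar_pos(dispersion_k, "dispersion_k")
  if (abs(sum(species_profile$prop) - 1) > 1e-9) {
    stop_invalid("species_profile proportions must sum to 1.")
  }
  small_classes <- cbind(lower = seq(2.5, 7.5, by = 2.5),
                         upper = seq(5, 10, by = 2.5))
  large_classes <- cbind(lower = seq(10, 35, by = 5),
                         upper = seq(15, 40, by = 5))
  with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(units))) {
      mu250 <- exp(beta0 + beta1 * units$grazing[i])
      for (rep_day in seq_len(n_replicates)) {
        len <- max(20, stats::rnorm(1, 47.25, 5))
        for (grp in c("large", "small")) {
          width <- if (grp == "large") 5 else 1
          p_grp <- if (grp == "large") {
            sum(species_profile$prop * (1 - species_profile$p_small))
          } else {
            sum(species_profile$prop * species_profile$p_small)
          }
          mu_obs <- mu250 * p_grp * (len * width) / 250
          n_obs <- stats::rnbinom(1, size = dispersion_k, mu = mu_obs)
          if (n_obs == 0) next
          w <- species_profile$prop *
            (if (grp == "large") 1 - species_profile$p_small else species_profile$p_small)
          sp <- sample(species_profile$species, n_obs, replace = TRUE, prob = w)
          classes <- if (grp == "large") large_classes else small_classes
          cls <- sample(nrow(classes), n_obs, replace = TRUE,
                        prob = stats::dlnorm(rowMeans(classes),
                                             log(if (grp == "large") 18 else 6), 0.4))
          tab <- table(sp, cls)
          idx <- which(tab > 0, arr.ind = TRUE)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            site = units$site[i], habitat = units$habitat[i],
            replicate = rep_day,
            species = rownames(tab)[idx[, 1]],
            tl_lower_cm = classes[as.integer(colnames(tab)[idx[, 2]]), "lower"],
            tl_upper_cm = classes[as.integer(colnames(tab)[idx[, 2]]), "upper"],
            count = as.integer(tab[idx]),
            transect_length_m = len, transect_width_m = width
          )
        }
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Default synthetic species pool
#'
#' A pool mirroring an inner-shelf roving-herbivore assemblage dominated by a
#' parrotfish, a rabbitfish and a second parrotfish, with length-weight
#' parameters of cube-law magnitude.
#'
#' @return A list with `profile` (tibble `species`, `prop`, `p_small`) and
#'   `lw_params` (tibble `species`, `a`, `b`).
#' @export
default_species_pool <- function() {
  profile <- tibble::tibble(
    species = c("Scarus rivulatus", "Siganus doliatus", "Chlorurus microrhinos",
                "Acanthurus grammoptilus", "Siganus lineatus", "Scarus ghobban"),
    prop = c(0.45, 0.16, 0.14, 0.10, 0.08, 0.07),
    p_small = c(0.30, 0.25, 0.20, 0.35, 0.20, 0.30)
  )
  lw <- tibble::tibble(
    species = profile$species,
    a = c(0.0136, 0.0190, 0.0146, 0.0245, 0.0226, 0.0129),
    b = c(3.02, 2.96, 3.06, 2.95, 2.94, 3.05)
  )
  list(profile = profile, lw_params = lw)
}

#' @rdname default_species_pool
#' @export
default_species_profile <- function() default_species_pool()$profile
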