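#' Generate a complete synthetic reef study
#'
#' Emulates the full survey design: `n_sites` sites x 5 habitats x
#' `n_reconstructions` reconstruction locations, each sampled by
#' `n_transects` transect cross-sections of `length` metres, with benthic
#' segmentations, planted refuges (ground truth), per-habitat depth
#' soundings, a year of synthetic tides, and timed-swim fish censuses whose
#' expected abundance depends log-linearly on each unit's grazing surface
#' fraction. Fully deterministic for a fixed seed.
#'
#' @param n_sites,n_reconstructions,n_transects Design counts (>= 1).
#' @param seed Integer seed.
#' @param length,resolution Transect geometry (m).
#' @param archetypes Named list of five [habitat_archetype()]s.
#' @param beta0,beta1,dispersion_k Fish-count generator parameters
#'   (log-linear intercept, grazing slope, negative-binomial size).
#' @param n_days Length of the tide series in days.
#' @return An object of class `reef_study`: a list with `transects` (nested
#'   tibble with list-columns `profile` and `segmentation`), `fish_surveys`,
#'   `tides`, `depths` (replicate soundings), `lw_params`,
#'   `ground_truth` (unit grazing fractions, true benthos levels, planted
#'   refuge tallies, fish parameters) and `params`.
#' @export
#' @examples
#' \donttest{
#' study <- generate_study(seed = 1)
#' nrow(study$transects)  # 150 at the default design
#' }
generate_study <- function(n_sites = 3, n_reconstructions = 2, n_transects = 5,
                           seed = 1L, length = 5, resolution = 0.005,
                           archetypes = default_archetypes(),
                           beta0 = 3.25, beta1 = 3, dispersion_k = 5,
                           n_days = 365) {
  if (n_sites < 1 || n_reconstructions < 1 || n_transects < 1) {
    stop_invalid("design counts must all be >= 1.")
  }
  habitats <- names(archetypes)
  design <- tidyr::expand_grid(
    site = paste0("site", seq_len(n_sites)),
    habitat = habitats,
    reconstruction = seq_len(n_reconstructions),
    transect = seq_len(n_transects)
  )
  n_tr <- nrow(design)
  sub <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                    n_tr * 2L + n_sites * 5L + 2L))
  tide_seed <- sub[1]
  fish_seed <- sub[2]
  tides <- generate_tides(n_days = n_days, seed = tide_seed)

  transects <- design
  transects$profile <- vector("list", n_tr)
  transects$segmentation <- vector("list", n_tr)
  planted_crevices <- integer(n_tr)
  planted_overhangs <- integer(n_tr)
  for (i in seq_len(n_tr)) {
    arch <- archetypes[[design$habitat[i]]]
    p <- generate_profile(arch, length, resolution, seed = sub[2L + i])
    feats <- with_seed(sub[2L + n_tr + i], {
      nc <- stats::rpois(1, arch$crevice_rate)
      no <- stats::rpois(1, arch$overhang_rate)
      # feature anchor points kept >= 0.5 m apart and off the transect ends
      slots <- seq(0.3, length - 0.5, by = 0.5)
      k <- min(nc + no, base::length(slots))
      xs <- if (k > 0) sort(sample(slots, k)) else numeric()
      nc <- min(nc, k)
      list(
        crevices = tibble::tibble(
          x = utils::head(xs, nc),
          width = stats::runif(nc, 0.12, 0.19),
          depth = stats::runif(nc, 0.12, 0.20)
        ),
        overhangs = tibble::tibble(
          x = utils::tail(xs, max(0, k - nc)),
          height = stats::runif(max(0, k - nc), 0.12, 0.30)
        )
      )
    })
    if (nrow(feats$crevices)) {
      for (j in seq_len(nrow(feats$crevices))) {
        p <- insert_crevice(p, feats$crevices$x[j], feats$crevices$width[j],
                            feats$crevices$depth[j])
      }
    }
    if (nrow(feats$overhangs)) {
      for (j in seq_len(nrow(feats$overhangs))) {
        p <- insert_overhang(p, feats$overhangs$x[j], feats$overhangs$height[j])
      }
    }
    seg <- generate_segmentation(p, arch, seed = sub[2L + i] %% 1000000L + 7L)
    transects$profile[[i]] <- p
    transects$segmentation[[i]] <- seg
    planted_crevices[i] <- nrow(feats$crevices)
    planted_overhangs[i] <- nrow(feats$overhangs)
  }
  transects$planted_crevices <- planted_crevices
  transects$planted_overhangs <- planted_overhangs

  # unit-level grazing fractions drive the fish generator
  transects$grazing <- purrr::map2_dbl(transects$profile, transects$segmentation,
                                       grazing_area_fraction)
  units <- dplyr::summarise(
    dplyr::group_by(transects, .data$site, .data$habitat),
    grazing = mean(.data$grazing), .groups = "drop"
  )

  # per-unit true benthos level and replicate depth soundings near high tide
  site_idx <- as.integer(factor(units$site))
  hab_levels <- vapply(units$habitat, function(h) archetypes[[h]]$benthos_level,
                       numeric(1))
  units$benthos_true <- with_seed(sub[2L + 2L * n_tr + 1L], {
    unname(hab_levels) + stats::rnorm(nrow(units), 0, 0.05)[site_idx]
  })
  # skip the first/last extremes so soundings within +-1 h of a high always
  # fall inside the interpolable span
  highs <- tides[tides$kind == "H", ]
  highs <- highs[-c(1, nrow(highs)), ]
  depths <- with_seed(sub[2L + 2L * n_tr + 2L], {
    purrr::map_dfr(seq_len(nrow(units)), function(i) {
      hi <- highs[sample.int(nrow(highs), 9), ]
      t_meas <- hi$time + stats::runif(9, -3600, 3600)
      tibble::tibble(
        site = units$site[i], habitat = units$habitat[i], time = t_meas,
        measured_depth = round(
          tide_height(tides, t_meas) - units$benthos_true[i] +
            stats::rnorm(9, 0, 0.03), 1)
      )
    })
  })

  pool <- default_species_pool()
  surveys <- generate_fish_counts(units, beta0 = beta0, beta1 = beta1,
                                  dispersion_k = dispersion_k,
                                  species_profile = pool$profile,
                                  seed = fish_seed)
  structure(
    list(
      transects = transects[setdiff(names(transects), "grazing")],
      fish_surveys = surveys, tides = tides, depths = depths,
      lw_params = pool$lw_params,
      ground_truth = list(
        units = units,
        fish_model = list(beta0 = beta0, beta1 = beta1,
                          dispersion_k = dispersion_k)
      ),
      params = list(n_sites = n_sites, n_reconstructions = n_reconstructions,
                    n_transects = n_transects, seed = seed, length = length,
                    resolution = resolution, n_days = n_days)
    ),
    class = "reef_study"
  )
}

#' @export
print.reef_study <- function(x, ...) {
  cat("<reef_study> ", nrow(x$transects), " transects over ",
      nrow(x$ground_truth$units), " site x habitat units (seed ",
      x$params$seed, ")\n", sep = "")
  invisible(x)
}

#' Compute the metric table for every transect of a study
#'
#' @param study A [generate_study()] object.
#' @param config An [observer_config()].
#' @param ... Passed to [compute_metrics()].
#' @return A tibble with one row per transect: design identifiers plus the
#'   six metric columns.
#' @export
study_metrics <- function(study, config = observer_config(), ...) {
  stopifnot(inherits(study, "reef_study"))
  tr <- study$transects
  met <- purrr::map2_dfr(tr$profile, tr$segmentation, compute_metrics,
                         config = config, ...)
  dplyr::bind_cols(
    tr[c("site", "habitat", "reconstruction", "transect")], met
  )
}

#' Aggregate transect metrics and depths to site x habitat units
#'
#' Produces the unit-level covariate table used by the fish-distribution and
#' multivariate models: per-unit means of the six metrics, plus the average
#' water depth obtained by tide-correcting the replicate soundings
#' (depth is reported positive-down relative to the tide datum).
#'
#' @param metrics A [study_metrics()] table.
#' @param depths Replicate soundings (`site`, `habitat`, `time`,
#'   `measured_depth`); optional.
#' @param tides Tide extremes used to correct the soundings.
#' @return A tibble with one row per site x habitat unit.
#' @export
aggregate_units <- function(metrics, depths = NULL, tides = NULL) {
  out <- dplyr::summarise(
    dplyr::group_by(metrics, .data$site, .data$habitat),
    dplyr::across(c("rugosity", "verticality", "coral_cover", "refuge_count",
                    "fov_visible", "grazing_area"), mean),
    .groups = "drop"
  )
  if (!is.null(depths)) {
    if (is.null(tides)) stop_invalid("`tides` needed to tide-correct depths.")
    benthos <- dplyr::summarise(
      dplyr::group_by(depths, .data$site, .data$habitat),
      benthos_level = mean(tide_correct_depth(.data$measured_depth, .data$time,
                                              tides)),
      .groups = "drop"
    )
    benthos$depth <- -benthos$benthos_level
    out <- dplyr::left_join(out, benthos, by = c("site", "habitat"))
  }
  dplyr::arrange(out, .data$site, .data$habitat)
}

#' Write a study bundle of plain-text files
#'
#' Writes `profiles/<site>_<habitat>_<rec>_<transect>.csv` (`x_m,z_m`),
#' `segments/` CSVs (`start_m,end_m,label`), `fish_surveys.csv`, `tides.csv`
#' (ISO-8601 timestamps), `depths.csv`, `lw_params.csv` and `config.csv`
#' capturing the design parameters and seed. Byte-identical on re-run for a
#' fixed seed.
#'
#' @param study A [generate_study()] object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_bundle <- function(study, dir) {
  stopifnot(inherits(study, "reef_study"))
  dir.create(file.path(dir, "profiles"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "segments"), showWarnings = FALSE)
  tr <- study$transects
  for (i in seq_len(nrow(tr))) {
    stem <- paste(tr$site[i], tr$habitat[i], tr$reconstruction[i],
                  tr$transect[i], sep = "_")
    p <- tr$profile[[i]]
    utils::write.csv(data.frame(x_m = p$x, z_m = p$z),
                     file.path(dir, "profiles", paste0(stem, ".csv")),
                     row.names = FALSE)
    s <- tr$segmentation[[i]]
    utils::write.csv(data.frame(start_m = s$start, end_m = s$end, label = s$label),
                     file.path(dir, "segments", paste0(stem, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(study$fish_surveys, file.path(dir, "fish_surveys.csv"),
                   row.names = FALSE)
  tides <- data.frame(
    timestamp = format(study$tides$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    height_m = study$tides$height, kind = study$tides$kind
  )
  utils::write.csv(tides, file.path(dir, "tides.csv"), row.names = FALSE)
  depths <- data.frame(
    site = study$depths$site, habitat = study$depths$habitat,
    timestamp = format(study$depths$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    measured_depth_m = study$depths$measured_depth
  )
  utils::write.csv(depths, file.path(dir, "depths.csv"), row.names = FALSE)
  utils::write.csv(study$lw_params, file.path(dir, "lw_params.csv"),
                   row.names = FALSE)
  cfg <- data.frame(parameter = names(study$params),
                    value = vapply(study$params, as.character, character(1)))
  utils::write.csv(cfg, file.path(dir, "config.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a profile / segmentation / tide CSV written by [write_study_bundle()]
#'
#' @param path File path.
#' @return A [reef_profile()], segmentation tibble, or tide tibble.
#' @export
read_profile_csv <- function(path) {
  d <- utils::read.csv(path)
  reef_profile(d$x_m, d$z_m)
}

#' @rdname read_profile_csv
#' @export
read_segmentation_csv <- function(path) {
  d <- utils::read.csv(path)
  tibble::tibble(start = d$start_m, end = d$end_m, label = d$label)
}

#' @rdname read_profile_csv
#' @export
read_tides_csv <- function(path) {
  d <- utils::read.csv(path)
  tibble::tibble(time = as.POSIXct(d$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                                   tz = "UTC"),
                 height = d$height_m, kind = d$kind)
}
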