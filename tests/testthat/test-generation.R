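test_that("archetype construction enforces its invariants", {
  expect_error(habitat_archetype("crest", cover_probs = c(hard_coral = 0.6, sand = 0.6)),
               "sum to 1")
  expect_error(habitat_archetype("crest", roughness_amplitude = -1), ">= 0")
  a <- default_archetypes()
  expect_named(a, c("slope", "crest", "outer_flat", "mid_flat", "inner_flat"))
  for (arch in a) expect_equal(sum(arch$cover_probs), 1, tolerance = 1e-12)
})

test_that("profile generation honours the flat and ramp identities", {
  smooth <- habitat_archetype("inner_flat", base_gradient = 0,
                              roughness_amplitude = 0)
  p <- generate_profile(smooth, length = 5, resolution = 0.005, seed = 1)
  expect_equal(unique(p$z), 0)
  expect_equal(rugosity_index(p), 1.0)
  ramp <- habitat_archetype("slope", base_gradient = 1, roughness_amplitude = 0)
  pr <- generate_profile(ramp, seed = 1)
  expect_equal(verticality(pr), 1.0, tolerance = 1e-9)
  expect_error(generate_profile(smooth, length = -1), "positive")
  expect_error(generate_profile(smooth, resolution = 0.05), "0.01")
})

test_that("profile generation is deterministic per seed and leaves the RNG alone", {
  a <- default_archetypes()$crest
  set.seed(123)
  before <- runif(1)
  p1 <- generate_profile(a, seed = 42)
  p2 <- generate_profile(a, seed = 42)
  p3 <- generate_profile(a, seed = 43)
  expect_identical(p1$z, p2$z)
  expect_false(identical(p1$z, p3$z))
  set.seed(123)
  expect_identical(runif(1), before)
})

test_that("planted crevices follow the detection rules by construction", {
  flat <- flat_profile()
  p <- insert_crevice(flat, 2, width = 0.15, depth = 0.12)
  r <- detect_refuges(p)
  expect_equal(nrow(r$crevices), 1L)
  expect_equal(r$crevices$x, 2.075, tolerance = 0.02)
  expect_equal(r$crevices$depth, 0.12, tolerance = 0.01)
  # too wide and too shallow notches are rejected
  expect_equal(nrow(detect_refuges(insert_crevice(flat, 2, 0.25, 0.12))$crevices), 0L)
  expect_equal(nrow(detect_refuges(insert_crevice(flat, 2, 0.15, 0.05))$crevices), 0L)
  expect_error(insert_crevice(flat, 4.95, 0.15, 0.12), "extent")
})

test_that("planted overhangs follow the detection rules by construction", {
  flat <- flat_profile()
  expect_equal(nrow(detect_refuges(insert_overhang(flat, 2, 0.12))$overhangs), 1L)
  expect_equal(nrow(detect_refuges(insert_overhang(flat, 2, 0.08))$overhangs), 0L)
  two <- insert_overhang(insert_overhang(flat, 1.5, 0.15), 3.2, 0.2)
  expect_equal(nrow(detect_refuges(two)$overhangs), 2L)
  expect_error(insert_overhang(flat, 5.5, 0.12), "inside")
})

test_that("segmentation tiles the profile and realises cover probabilities", {
  flat <- flat_profile()
  turf_only <- habitat_archetype("outer_flat",
                                 cover_probs = c(turf_EAM = 1))
  seg <- generate_segmentation(flat, turf_only, seed = 1)
  expect_equal(min(seg$start), 0)
  expect_equal(max(seg$end), 5)
  expect_true(all(abs(seg$start[-1] - seg$end[-nrow(seg)]) < 1e-12))
  expect_equal(grazing_area_fraction(flat, seg), 1.0)
  sand_only <- habitat_archetype("inner_flat", cover_probs = c(sand = 1))
  seg2 <- generate_segmentation(flat, sand_only, seed = 1)
  expect_equal(grazing_area_fraction(flat, seg2), 0.0)
  expect_equal(cover_fraction(flat, seg2, "hard_coral"), 0.0)
})

test_that("realised planar turf fraction tracks its cover probability", {
  flat <- flat_profile(res = 0.01)
  arch <- default_archetypes()$outer_flat
  fr <- vapply(1:400, function(s) {
    seg <- generate_segmentation(flat, arch, seed = s)
    turf <- seg[seg$label == "turf_EAM", ]
    sum(turf$end - turf$start) / 5
  }, numeric(1))
  expect_equal(mean(fr), arch$cover_probs[["turf_EAM"]], tolerance = 0.03)
})

test_that("synthetic tides alternate, are evenly spaced and collapse correctly", {
  td <- generate_tides(n_days = 20, seed = 3)
  expect_true(all(diff(as.numeric(td$time)) > 0))
  expect_true(all(td$kind[-1] != td$kind[-nrow(td)]))
  gaps <- diff(as.numeric(td$time)) / 3600
  expect_lt(abs(mean(gaps) - 6.2103), 0.1)
  single <- generate_tides(n_days = 10, secondary_amplitude = 0, seed = 5)
  g0 <- diff(as.numeric(single$time)) / 3600
  expect_true(all(abs(g0 - 6.2103) < 0.1))
  expect_lt(stats::sd(single$height[single$kind == "H"]), 1e-6)
  expect_lt(stats::sd(single$height[single$kind == "L"]), 1e-6)
  expect_error(generate_tides(n_days = 0), ">= 1")
})

test_that("fish-count generator is null-calibrated and approaches the Poisson limit", {
  units <- toy_units(n = 200, seed = 9)
  recs <- generate_fish_counts(units, beta0 = 3, beta1 = 0, dispersion_k = 5,
                               n_replicates = 1, seed = 11)
  pool <- default_species_pool()
  dens <- standardize_density(recs, pool$lw_params)
  tot <- dplyr::summarise(dplyr::group_by(dens, habitat),
                          ab = sum(abundance), .groups = "drop")
  tot <- dplyr::left_join(units, tot, by = "habitat")
  tot$ab[is.na(tot$ab)] <- 0
  expect_lt(abs(stats::cor(tot$grazing, tot$ab)), 0.2)
  # dispersion -> infinity: counts approach Poisson (variance ~ mean)
  units1 <- tibble::tibble(site = "site1", habitat = paste0("u", 1:300),
                           grazing = 0.5)
  recs2 <- generate_fish_counts(units1, beta0 = 3, beta1 = 0,
                                dispersion_k = 1e6, n_replicates = 1, seed = 2)
  counts <- dplyr::summarise(dplyr::group_by(recs2, habitat, transect_width_m),
                             n = sum(count), .groups = "drop")
  large <- counts$n[counts$transect_width_m == 5]
  expect_lt(stats::var(large) / mean(large), 2.5)
  expect_error(generate_fish_counts(tibble::tibble(site = "a", habitat = "b",
                                                   grazing = 1.5)),
               "\\[0, 1\\]")
})

test_that("generate_study delivers the full design with known ground truth", {
  st <- generate_study(n_sites = 2, n_reconstructions = 1, n_transects = 2,
                       seed = 5, n_days = 30)
  expect_s3_class(st, "reef_study")
  expect_equal(nrow(st$transects), 2 * 5 * 1 * 2)
  expect_equal(nrow(st$ground_truth$units), 2 * 5)
  expect_tbl_cols(st$fish_surveys, c("site", "habitat", "replicate", "species",
                                     "count", "transect_width_m"))
  expect_equal(nrow(st$depths), 2 * 5 * 9)
})

test_that("a fixed seed reproduces a byte-identical study bundle", {
  d1 <- file.path(tempdir(), "bundle1")
  d2 <- file.path(tempdir(), "bundle2")
  unlink(c(d1, d2), recursive = TRUE)
  st1 <- generate_study(n_sites = 1, n_reconstructions = 1, n_transects = 1,
                        seed = 99, n_days = 10)
  st2 <- generate_study(n_sites = 1, n_reconstructions = 1, n_transects = 1,
                        seed = 99, n_days = 10)
  write_study_bundle(st1, d1)
  write_study_bundle(st2, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     label = f)
  }
  # bundle readers round-trip
  p <- read_profile_csv(list.files(file.path(d1, "profiles"), full.names = TRUE)[1])
  expect_s3_class(p, "reef_profile")
  td <- read_tides_csv(file.path(d1, "tides.csv"))
  expect_equal(td$height, st1$tides$height, tolerance = 1e-9)
})
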