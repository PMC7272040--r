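test_that("length-weight allometry evaluates a * L^b", {
  expect_equal(weight_from_length(10, 0.01, 3), 10)
  expect_equal(weight_from_length(20, 0.01, 3), 80)
  expect_equal(weight_from_length(12.5, 0.0121, 3.05), 0.0121 * 12.5^3.05,
               tolerance = 1e-12)
  expect_equal(round(weight_from_length(12.5, 0.0121, 3.05), 3), 26.814)
  expect_error(weight_from_length(-2, 0.01, 3), "positive")
})

test_that("size-class midpoints are arithmetic means", {
  expect_equal(class_midpoint(10, 15), 12.5)
  expect_equal(class_midpoint(5, 7.5), 6.25)
  expect_equal(class_midpoint(25, 30), 27.5)
  expect_error(class_midpoint(10, 10), "lower < upper")
})

make_rec <- function(count, len, width, species = "Scarus rivulatus",
                     lower = 10, upper = 15, rep = 1, site = "site1",
                     habitat = "crest") {
  tibble::tibble(site = site, habitat = habitat, replicate = rep,
                 species = species, tl_lower_cm = lower, tl_upper_cm = upper,
                 count = count, transect_length_m = len, transect_width_m = width)
}

lw <- tibble::tibble(species = "Scarus rivulatus", a = 0.0136, b = 3.02)

test_that("density standardisation scales each belt to the target area", {
  # 20 fish on 50 x 5 m = exactly the 250 m2 reporting unit
  d <- standardize_density(make_rec(20, 50, 5), lw)
  expect_equal(sum(d$abundance), 20)
  # 4 small on the 1 m belt plus 10 large on the 5 m belt
  recs <- dplyr::bind_rows(make_rec(4, 50, 1, lower = 5, upper = 7.5),
                           make_rec(10, 50, 5))
  d2 <- standardize_density(recs, lw)
  expect_equal(sum(d2$abundance), 4 / 50 * 250 + 10 / 250 * 250)
  expect_equal(sort(unique(d2$size_group)), c("large", "small"))
  # replicate days average
  recs3 <- dplyr::bind_rows(make_rec(10, 50, 5, rep = 1),
                            make_rec(20, 50, 5, rep = 2),
                            make_rec(30, 50, 5, rep = 3))
  expect_equal(sum(standardize_density(recs3, lw)$abundance), 20)
  expect_error(standardize_density(make_rec(5, 0, 5), lw), "zero")
  expect_error(standardize_density(make_rec(5, 50, 5, species = "x"), lw),
               "length-weight")
})

test_that("standardisation is invariant to record splitting and linear in counts", {
  one <- make_rec(10, 47, 5)
  split2 <- dplyr::bind_rows(make_rec(4, 47, 5), make_rec(6, 47, 5))
  expect_equal(standardize_density(one, lw)$abundance,
               standardize_density(split2, lw)$abundance)
  doubled <- make_rec(20, 47, 5)
  expect_equal(standardize_density(doubled, lw)$abundance,
               2 * standardize_density(one, lw)$abundance)
  expect_equal(standardize_density(doubled, lw)$biomass_kg,
               2 * standardize_density(one, lw)$biomass_kg)
})

test_that("biomass uses class midpoints through the allometry", {
  d <- standardize_density(make_rec(10, 50, 5), lw)
  want_kg <- 10 / 250 * 250 * weight_from_length(12.5, 0.0136, 3.02) / 1000
  expect_equal(d$biomass_kg, want_kg, tolerance = 1e-12)
})

test_that("the assemblage table has one row per unit with additive totals", {
  st <- generate_study(n_sites = 3, n_reconstructions = 1, n_transects = 1,
                       seed = 21, n_days = 10)
  asm <- build_assemblage(st$fish_surveys, st$lw_params)
  expect_s3_class(asm, "assemblage")
  expect_equal(nrow(asm$units), 15)
  expect_equal(nrow(asm$abundance), 15)
  sp_cols <- setdiff(names(asm$abundance), c("site", "habitat"))
  expect_equal(rowSums(asm$abundance[sp_cols]), asm$units$abundance,
               tolerance = 1e-9, ignore_attr = TRUE)
  bio_cols <- setdiff(names(asm$biomass), c("site", "habitat"))
  expect_equal(rowSums(asm$biomass[bio_cols]), asm$units$biomass_kg,
               tolerance = 1e-9, ignore_attr = TRUE)
  # missing covariate unit is a named data-gap error
  covs <- tibble::tibble(site = "site1", habitat = "crest", depth = 1)
  expect_error(build_assemblage(st$fish_surveys, st$lw_params, covariates = covs),
               "site1")
})

test_that("the dominant generated species carries its configured share", {
  units <- toy_units(n = 60, seed = 4)
  recs <- generate_fish_counts(units, beta0 = 4, beta1 = 0, seed = 8)
  pool <- default_species_pool()
  dens <- standardize_density(recs, pool$lw_params)
  share <- dplyr::summarise(dplyr::group_by(dens, species),
                            ab = sum(abundance), .groups = "drop")
  share$p <- share$ab / sum(share$ab)
  top <- pool$profile$prop[pool$profile$species == "Scarus rivulatus"]
  expect_equal(share$p[share$species == "Scarus rivulatus"], top,
               tolerance = 0.08)
})
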