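test_that("contour length matches Pythagoras and is additive over partitions", {
  expect_equal(contour_length(reef_profile(c(0, 3), c(0, 4))), 5.0)
  expect_equal(contour_length(flat_profile()), 5.0)
  expect_equal(contour_length(sawtooth_profile()), 5 * sqrt(2), tolerance = 1e-9)
  p <- generate_profile(default_archetypes()$crest, seed = 4)
  cuts <- c(0, 0.7, 1.33, 2.6, 4.01, 5)
  parts <- vapply(seq_len(length(cuts) - 1), function(i) {
    contour_length(p, c(cuts[i], cuts[i + 1]))
  }, numeric(1))
  expect_equal(sum(parts), contour_length(p), tolerance = 1e-9)
  expect_error(contour_length(p, c(3, 2)), "x_start < x_end")
  expect_error(contour_length(p, c(-1, 2)), "extent")
})

test_that("rugosity index equals its geometric closed forms and is >= 1", {
  expect_equal(rugosity_index(flat_profile()), 1.0)
  expect_equal(rugosity_index(reef_profile(c(0, 3), c(0, 4))), 5 / 3,
               tolerance = 1e-9)
  expect_equal(rugosity_index(sawtooth_profile()), sqrt(2), tolerance = 1e-9)
  for (s in 1:20) {
    p <- generate_profile(default_archetypes()$crest, seed = s)
    expect_gte(rugosity_index(p), 1)
  }
})

test_that("verticality evaluates the interval rule and its invariances", {
  expect_equal(verticality(flat_profile()), 0.0)
  expect_equal(verticality(ramp_profile(1)), 1.0, tolerance = 1e-9)
  # grid z-values (0, 0.03, 0.03, 0.10) at 10 cm spacing
  p <- reef_profile(c(0, 0.1, 0.2, 0.3), c(0, 0.03, 0.03, 0.10))
  expect_equal(verticality(p), mean(c(0.3, 0, 0.7)), tolerance = 1e-12)
  rough <- generate_profile(default_archetypes()$slope, seed = 7)
  v0 <- verticality(rough)
  shifted <- reef_profile(rough$x, rough$z + 3.7)
  expect_equal(verticality(shifted), v0, tolerance = 1e-12)
  doubled <- reef_profile(rough$x, rough$z * 2)
  expect_equal(verticality(doubled), 2 * v0, tolerance = 1e-9)
  # trailing partial interval is dropped
  p2 <- reef_profile(c(0, 0.1, 0.2, 0.25), c(0, 0.05, 0.05, 5))
  expect_equal(verticality(p2), mean(c(0.5, 0)), tolerance = 1e-12)
  expect_error(verticality(reef_profile(c(0, 0.05), c(0, 0)), 0.1), "shorter")
})

test_that("cover fractions weight by contour length and partition to one", {
  flat <- flat_profile()
  seg <- tibble::tibble(start = c(0, 2.5), end = c(2.5, 5),
                        label = c("hard_coral", "sand"))
  expect_equal(cover_fraction(flat, seg, "hard_coral"), 0.5)
  expect_equal(cover_fraction(flat, seg, c("hard_coral", "sand")), 1.0)
  # coral draped over a 45-degree section outweighs its planar footprint
  x <- seq(0, 2, by = 0.001)
  z <- ifelse(x <= 1, x, 1)
  p <- reef_profile(x, z)
  seg2 <- tibble::tibble(start = c(0, 1), end = c(1, 2),
                         label = c("hard_coral", "sand"))
  expect_equal(cover_fraction(p, seg2, "hard_coral"), sqrt(2) / (sqrt(2) + 1),
               tolerance = 1e-6)
  # partition property on a generated profile
  arch <- default_archetypes()$crest
  rough <- generate_profile(arch, seed = 3)
  seg3 <- generate_segmentation(rough, arch, seed = 3)
  fracs <- vapply(unique(seg3$label), function(l) cover_fraction(rough, seg3, l),
                  numeric(1))
  expect_equal(sum(fracs), 1, tolerance = 1e-9)
  bad <- tibble::tibble(start = 0, end = 9, label = "sand")
  expect_error(cover_fraction(flat, bad, "sand"), "extent")
})

test_that("grazing area counts turf only", {
  flat <- flat_profile()
  seg <- tibble::tibble(start = c(0, 2.5), end = c(2.5, 5),
                        label = c("turf_EAM", "macroalgae"))
  expect_equal(grazing_area_fraction(flat, seg), 0.5)
  seg_m <- tibble::tibble(start = 0, end = 5, label = "macroalgae")
  expect_equal(grazing_area_fraction(flat, seg_m), 0.0)
})

test_that("compute_metrics composes the six metrics and is pure", {
  flat <- flat_profile()
  seg <- tibble::tibble(start = 0, end = 5, label = "turf_EAM")
  m <- compute_metrics(flat, seg)
  expect_equal(m$rugosity, 1.0)
  expect_equal(m$verticality, 0.0)
  expect_equal(m$coral_cover, 0.0)
  expect_equal(m$refuge_count, 0)
  expect_equal(m$fov_visible, 1.0)
  expect_equal(m$grazing_area, 1.0)
  arch <- default_archetypes()$crest
  p <- generate_profile(arch, seed = 6)
  s <- generate_segmentation(p, arch, seed = 6)
  expect_identical(compute_metrics(p, s), compute_metrics(p, s))
})

test_that("halving the sampling resolution moves rugosity by under 2%", {
  for (h in c("slope", "crest", "outer_flat")) {
    a <- default_archetypes()[[h]]
    for (s in 1:3) {
      r5 <- rugosity_index(generate_profile(a, resolution = 0.005, seed = s))
      r10 <- rugosity_index(generate_profile(a, resolution = 0.01, seed = s))
      expect_lt(abs(r10 - r5) / r5, 0.02)
    }
  }
})

test_that("DEM transect sampling is exact on planes and matches the bilinear form", {
  dem <- list(x = 0:10, y = 0:10,
              z = outer(0:10, 0:10, function(e, n) 0.25 * e + 0.1 * n))
  p <- sample_transect_from_dem(dem, c(1, 5), c(9, 5), step = 0.5)
  expect_equal(diff(p$z) / diff(p$x), rep(0.25, nrow(p) - 1), tolerance = 1e-9)
  expect_error(sample_transect_from_dem(dem, c(2, 2), c(2, 2), 0.5), "coincident")
  expect_error(sample_transect_from_dem(dem, c(-5, 5), c(9, 5), 0.5), "outside")
  # saddle surface: bilinear interpolation has the closed form e*n on cell corners
  dem2 <- list(x = 0:4, y = 0:4, z = outer(0:4, 0:4, function(e, n) e * n))
  pd <- sample_transect_from_dem(dem2, c(0.5, 0.5), c(3.5, 3.5), step = 0.25)
  along <- cbind(0.5 + (3.5 - 0.5) * pd$x / max(pd$x),
                 0.5 + (3.5 - 0.5) * pd$x / max(pd$x))
  expect_equal(pd$z, along[, 1] * along[, 2], tolerance = 1e-9)
  # no-data gap is named
  dem3 <- dem
  dem3$z[5, 6] <- NA
  expect_error(sample_transect_from_dem(dem3, c(1, 5), c(9, 5), 0.5), "no-data")
})
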