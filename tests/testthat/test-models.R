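test_that("the boundary offset keeps proportions strictly inside (0,1)", {
  expect_equal(add_offset(0), 0.001)
  expect_equal(add_offset(0.573), 0.574)
  out <- add_offset(c(0, 0.5, 1))
  expect_true(all(out > 0 & out < 1))
  expect_error(add_offset(1.2), "\\[0, 1\\]")
})

test_that("hpdi matches the exhaustive shortest-window oracle", {
  brute_hpdi <- function(x, prob = 0.95) {
    s <- sort(x)
    n <- length(s)
    k <- ceiling(prob * n)
    best <- c(-Inf, Inf)
    for (i in 1:(n - k)) {
      if (s[i + k] - s[i] < best[2] - best[1]) best <- c(s[i], s[i + k])
    }
    best
  }
  set.seed(5)
  for (rep in 1:20) {
    x <- switch(1 + rep %% 3,
                rnorm(150), rexp(120), c(rnorm(80), rnorm(60, 6)))
    expect_equal(unname(hpdi(x)), brute_hpdi(x), tolerance = 1e-12)
  }
  expect_equal(unname(hpdi(rep(3, 200))), c(3, 3))
  expect_error(hpdi(rnorm(50)), "100")
})

test_that("hpdi approximates normal quantiles on many draws", {
  set.seed(6)
  h <- hpdi(rnorm(1e5))
  expect_equal(unname(h), c(-1.96, 1.96), tolerance = 0.03)
})

test_that("gaussian habitat means are recovered within their own HPDIs", {
  set.seed(2)
  habs <- rep(c("slope", "crest", "outer", "mid", "inner"), each = 30)
  sites <- rep(rep(paste0("s", 1:3), each = 10), 5)
  truth <- c(slope = 2, crest = 5, outer = 8, mid = 3, inner = 1)
  y <- rnorm(150, truth[habs] + c(s1 = -0.1, s2 = 0, s3 = 0.1)[sites], 1)
  dat <- tibble::tibble(y = y, habitat = habs, site = sites)
  fit <- fit_habitat_model(dat, "y", "gaussian", seed = 17)
  td <- tidy(fit)
  expect_true(all(td$hpdi_lower <= truth[td$term] &
                    truth[td$term] <= td$hpdi_upper))
  expect_true(all(td$link_hpdi_lower <= td$link_mean &
                    td$link_mean <= td$link_hpdi_upper))
  g <- glance(fit)
  expect_equal(g$chains, 3)
  expect_equal(g$iter, 5000)
  expect_lte(g$max_rhat, 1.01)
  # cross-check the posterior means against an independent ML fit
  skip_if_not_installed("glmmTMB")
  ml <- glmmTMB::fixef(glmmTMB::glmmTMB(y ~ 0 + habitat + (1 | site),
                                        data = dat))$cond
  expect_equal(td$mean, unname(ml[paste0("habitat", td$term)]),
               tolerance = 0.15)
})

test_that("negative-binomial habitat ratios are recovered", {
  set.seed(8)
  habs <- rep(c("a", "b"), each = 45)
  sites <- rep(rep(paste0("s", 1:3), each = 15), 2)
  mu <- ifelse(habs == "a", 8, 40)  # 5-fold ratio
  y <- rnbinom(90, size = 4, mu = mu)
  dat <- tibble::tibble(y = y, habitat = habs, site = sites)
  fit <- fit_habitat_model(dat, "y", "negbin", seed = 23)
  ratio_draws <- exp(fit$draws[, 2] - fit$draws[, 1])
  h <- hpdi(ratio_draws)
  expect_true(h[["lower"]] <= 5 && 5 <= h[["upper"]])
  expect_true(all(tidy(fit)$mean > 0))
})

test_that("null data yield no flagged contrasts; separated levels are flagged", {
  set.seed(4)
  habs <- rep(c("a", "b", "c"), each = 24)
  sites <- rep(rep(paste0("s", 1:3), each = 8), 3)
  dat <- tibble::tibble(y = rnorm(72, 5, 1), habitat = habs, site = sites)
  fit <- fit_habitat_model(dat, "y", "gaussian", seed = 29)
  ct <- pairwise_contrasts(fit)
  expect_false(any(ct$effect))
  # A-B flag symmetry holds by construction of the difference draws
  d_ab <- fit$draws[, 1] - fit$draws[, 2]
  d_ba <- fit$draws[, 2] - fit$draws[, 1]
  expect_equal(unname(hpdi(d_ab)), -rev(unname(hpdi(d_ba))), tolerance = 1e-12)
  dat2 <- dat
  dat2$y <- dat2$y + ifelse(dat2$habitat == "c", 5, 0)  # 5 sd separation
  fit2 <- fit_habitat_model(dat2, "y", "gaussian", seed = 31)
  ct2 <- pairwise_contrasts(fit2)
  flagged <- ct2[grepl("c", ct2$contrast), ]
  expect_true(all(flagged$effect))
  expect_true(all(flagged$p_sign > 0.999))
})

test_that("beta-family fits respect the (0,1) support and reject bad inputs", {
  set.seed(8)
  habs <- rep(c("a", "b"), each = 30)
  sites <- rep(rep(paste0("s", 1:3), each = 10), 2)
  mu <- ifelse(habs == "a", 0.25, 0.6)
  y <- add_offset(pmin(pmax(rbeta(60, mu * 30, (1 - mu) * 30), 0), 1))
  dat <- tibble::tibble(y = y, habitat = habs, site = sites)
  fit <- fit_habitat_model(dat, "y", "beta", seed = 37)
  td <- tidy(fit)
  expect_true(all(td$mean > 0 & td$mean < 1))
  expect_equal(td$mean, c(0.25, 0.6), tolerance = 0.08)
  dat$y[1] <- 1.0
  expect_error(fit_habitat_model(dat, "y", "beta", seed = 1), "support")
})

test_that("HPDI widths shrink as the sample grows tenfold", {
  width_at <- function(n, seed) {
    set.seed(seed)
    habs <- rep(c("a", "b"), each = n)
    sites <- rep(rep(paste0("s", 1:3), length.out = n), 2)
    dat <- tibble::tibble(y = rnorm(2 * n, ifelse(habs == "a", 2, 4), 1),
                          habitat = habs, site = sites)
    td <- tidy(fit_habitat_model(dat, "y", "gaussian", seed = seed))
    mean(td$hpdi_upper - td$hpdi_lower)
  }
  expect_lt(width_at(150, 41), width_at(15, 43))
})

test_that("collinearity screen groups by |r| and flags degenerate columns", {
  set.seed(9)
  d <- tibble::tibble(a = rnorm(30))
  d$b <- d$a                       # duplicated column
  d$c <- rnorm(30)                 # independent
  scr <- collinearity_screen(d)
  expect_equal(scr$groups, list(c("a", "b")))
  expect_equal(scr$correlations["a", "b"], 1)
  # orthogonal designed covariates form no group
  do <- tibble::tibble(x = rep(c(-1, 1), 10), y = rep(c(-1, -1, 1, 1), 5))
  expect_equal(length(collinearity_screen(do)$groups), 0)
  # five metrics from one latent factor form a single group of five
  lat <- rnorm(40)
  dm <- tibble::as_tibble(stats::setNames(
    lapply(1:5, function(i) lat + rnorm(40, 0, 0.3)), letters[1:5]
  ))
  expect_equal(collinearity_screen(dm)$groups, list(letters[1:5]))
  dz <- tibble::tibble(a = rnorm(30), z = rep(1, 30))
  expect_warning(collinearity_screen(dz), "zero-variance")
  expect_error(collinearity_screen(tibble::tibble(a = 1:2)), ">= 3")
})

test_that("the PC1 composite is centred, sign-anchored and tracks the latent factor", {
  set.seed(10)
  d <- tibble::tibble(rugosity = rnorm(30))
  d$vert <- d$rugosity
  pc <- pc1_composite(d, c("rugosity", "vert"))
  expect_equal(pc$prop_variance, 1.0, tolerance = 1e-12)
  expect_equal(mean(pc$scores), 0, tolerance = 1e-9)
  expect_gt(pc$loadings[["rugosity"]], 0)
  lat <- rnorm(60)
  dm <- tibble::as_tibble(stats::setNames(
    lapply(1:5, function(i) lat + rnorm(60, 0, 0.4)), c("rugosity", letters[2:5])
  ))
  pc2 <- pc1_composite(dm, names(dm), anchor = "rugosity")
  expect_gt(abs(stats::cor(pc2$scores, lat)), 0.9)
  expect_gt(stats::cor(pc2$scores, dm$rugosity), 0)
  dm$flat <- 1
  expect_warning(pc1_composite(dm, names(dm)), "constant")
})

test_that("loo_select handles trivial candidate sets deterministically", {
  set.seed(12)
  dat <- tibble::tibble(
    y = rgamma(15, 4, 0.5),
    x = rnorm(15),
    site = rep(paste0("s", 1:3), each = 5)
  )
  one <- loo_select(dat, "y", list(only = "x"), seed = 2)
  expect_equal(one$best_name, "only")
  two <- loo_select(dat, "y", list(a = "x", b = "x"), seed = 2)
  expect_equal(two$ranking$elpd[1], two$ranking$elpd[2], tolerance = 0.2)
  # fewer covariates win ties: intercept-only duplicates rank by parsimony
  tie <- loo_select(dat, "y", list(m0 = character(), m0b = character()), seed = 3)
  expect_equal(tie$ranking$n_covariates[1], 0L)
})

test_that("the fish model recovers a planted grazing slope and flags its sign", {
  set.seed(13)
  g <- runif(15, 0.25, 0.65)
  site <- rep(paste0("s", 1:3), each = 5)
  mu <- exp(3 + 3 * g + rep(rnorm(3, 0, 0.1), each = 5))
  dat <- tibble::tibble(abundance = rgamma(15, 8, 8 / mu), grazing = g,
                        site = site)
  fit <- fit_fish_model(dat, "abundance", "grazing", seed = 7)
  td <- tidy(fit)
  slope <- td[td$term == "grazing", ]
  expect_gt(slope$p_positive, 0.95)
  expect_true(slope$hpdi_lower <= 3 && 3 <= slope$hpdi_upper)
  pred <- predict_fish_model(fit, tibble::tibble(grazing = seq(0.25, 0.65,
                                                               length.out = 11)))
  expect_true(all(pred$.pred > 0))
  expect_true(all(pred$.pred_lower <= pred$.pred & pred$.pred <= pred$.pred_upper))
  expect_error(fit_fish_model(dplyr::mutate(dat, abundance = -abundance),
                              "abundance", "grazing", seed = 1), "positive")
})
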