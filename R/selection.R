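#' Pairwise collinearity screen
#'
#' Pearson correlations among candidate covariates, with connected components
#' of the `|r| > threshold` graph reported as collinear groups (the screen
#' used before model fitting: distinctly collinear metrics are collapsed to a
#' single composite rather than entered together).
#'
#' @param data Data frame of covariates (numeric columns are used).
#' @param threshold Absolute correlation above which two covariates are
#'   considered distinctly collinear (default 0.7).
#' @return A list of class `collinearity_screen`: `correlations` (matrix),
#'   `groups` (list of character vectors, only groups of >= 2), and
#'   `dropped` (zero-variance columns excluded with a warning).
#' @export
collinearity_screen <- function(data, threshold = 0.7) {
  num <- data[vapply(data, is.numeric, logical(1))]
  if (nrow(num) < 3L) stop_invalid("need >= 3 rows to estimate correlations.")
  sds <- vapply(num, stats::sd, numeric(1))
  dropped <- names(num)[sds == 0]
  if (length(dropped)) {
    warning("zero-variance covariate(s) excluded: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    num <- num[sds > 0]
  }
  r <- stats::cor(as.matrix(num))
  adj <- abs(r) > threshold
  diag(adj) <- FALSE
  # connected components by breadth-first search
  nms <- colnames(r)
  seen <- logical(length(nms))
  groups <- list()
  for (i in seq_along(nms)) {
    if (seen[i]) next
    comp <- i
    frontier <- i
    seen[i] <- TRUE
    while (length(frontier)) {
      nbrs <- which(apply(adj[frontier, , drop = FALSE], 2, any) & !seen)
      seen[nbrs] <- TRUE
      comp <- c(comp, nbrs)
      frontier <- nbrs
    }
    if (length(comp) >= 2L) groups[[length(groups) + 1L]] <- nms[sort(comp)]
  }
  structure(list(correlations = r, groups = groups, dropped = dropped,
                 threshold = threshold),
            class = "collinearity_screen")
}

#' @export
print.collinearity_screen <- function(x, ...) {
  cat("<collinearity_screen> |r| > ", x$threshold, ": ",
      length(x$groups), " group(s)\n", sep = "")
  for (g in x$groups) cat("  {", paste(g, collapse = ", "), "}\n")
  invisible(x)
}

#' First-principal-component composite of collinear metrics
#'
#' Centres and scales the stated columns to unit variance, extracts the
#' scores on the first principal component, and fixes the sign so the loading
#' of `anchor` (rugosity by default) is positive - a single combined
#' complexity covariate standing in for a block of collinear metrics.
#'
#' @param data Data frame holding the metric columns.
#' @param cols Character vector (>= 2) of columns in the collinear group.
#' @param anchor Column whose loading is constrained positive (defaults to
#'   the first of `cols`).
#' @return A list of class `pc1_composite`: `scores` (per-row, zero mean),
#'   `loadings`, and `prop_variance` explained by PC1.
#' @export
pc1_composite <- function(data, cols, anchor = cols[1]) {
  if (length(cols) < 2L) stop_invalid("need >= 2 columns for a composite.")
  m <- as.matrix(data[cols])
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    warning("constant column(s) excluded from the composite: ",
            paste(cols[sds == 0], collapse = ", "), call. = FALSE)
    cols <- cols[sds > 0]
    m <- m[, sds > 0, drop = FALSE]
    if (!(anchor %in% cols)) anchor <- cols[1]
  }
  pca <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  scores <- pca$x[, 1]
  loadings <- pca$rotation[, 1]
  if (loadings[anchor] < 0) {
    scores <- -scores
    loadings <- -loadings
  }
  structure(list(scores = unname(scores), loadings = loadings,
                 prop_variance = pca$sdev[1]^2 / sum(pca$sdev^2)),
            class = "pc1_composite")
}

#' @export
print.pc1_composite <- function(x, ...) {
  cat("<pc1_composite> PC1 explains ", round(100 * x$prop_variance, 1),
      "% of the block variance\n", sep = "")
  invisible(x)
}

# Exact leave-one-out log predictive density of one candidate model.
loo_elpd <- function(data, response, covariates, site, family = "gamma",
                     prior_scale = 5, n_draws = 1000L, seed = 1L,
                     method = c("laplace", "mcmc")) {
  method <- match.arg(method)
  y <- data[[response]]
  grp <- as.integer(factor(data[[site]]))
  build_X <- function(d) {
    if (length(covariates) == 0L) {
      matrix(1, nrow(d), 1, dimnames = list(NULL, "(Intercept)"))
    } else {
      Xraw <- as.matrix(d[covariates])
      cbind("(Intercept)" = 1, Xraw)
    }
  }
  Xall <- build_X(data)
  # standardise covariates once on the full data so held-out rows are mapped
  # consistently
  if (length(covariates)) {
    ctr <- colMeans(Xall[, -1, drop = FALSE])
    scl <- apply(Xall[, -1, drop = FALSE], 2, stats::sd)
    if (any(scl == 0)) stop_invalid("constant covariate in candidate model.")
    Xall[, -1] <- sweep(sweep(Xall[, -1, drop = FALSE], 2, ctr), 2, scl, "/")
  }
  inv <- linkinv_for(family)
  n <- length(y)
  lpd <- numeric(n)
  # full-data mode warm-starts each leave-one-out refit
  md_full <- make_model_data(y, Xall, grp, family, prior_scale)
  lap_full <- laplace_fit(md_full)
  for (i in seq_len(n)) {
    md <- make_model_data(y[-i], Xall[-i, , drop = FALSE], grp[-i], family,
                          prior_scale)
    draws <- if (method == "laplace") {
      lap <- laplace_fit(md, start = lap_full$mode)
      with_seed(seed + i, draw_mvn(n_draws, lap$mode, lap$cov))
    } else {
      run_mcmc(md, seed = seed + i)$draws
    }
    beta <- draws[, seq_len(md$p), drop = FALSE]
    u <- site_effect_draws(draws, md)[, grp[i]]
    disp <- exp(draws[, md$npar])
    eta <- drop(beta %*% Xall[i, ]) + u
    mu <- inv(eta)
    dens <- switch(family,
      gaussian = stats::dnorm(y[i], mu, disp),
      beta = stats::dbeta(y[i], mu * disp, (1 - mu) * disp),
      negbin = stats::dnbinom(y[i], size = disp, mu = mu),
      gamma = stats::dgamma(y[i], shape = disp, rate = disp / mu)
    )
    lpd[i] <- log(mean(pmax(dens, 1e-300)))
  }
  sum(lpd)
}

#' Leave-one-out model selection
#'
#' Scores each candidate covariate set by its exact leave-one-out expected
#' log predictive density (every observation is held out in turn and the
#' model refitted without it) and returns the candidates ranked, with ties
#' broken towards fewer covariates. Feasible exactly because the modelling
#' unit is the site x habitat mean (n = 15 at the default design).
#'
#' @param data Unit-level data frame.
#' @param response Response column (strictly positive for the gamma family).
#' @param candidates Named list of character vectors of covariate names; an
#'   empty vector is the intercept-only model.
#' @param site Site column name.
#' @param family Model family (default `"gamma"`, log link).
#' @param method `"laplace"` (default) draws from the Laplace approximation
#'   of each refit posterior; `"mcmc"` runs the full sampler per refit.
#' @param n_draws Posterior draws per refit for the predictive density.
#' @param seed Integer seed.
#' @param prior_scale Prior scale for coefficients.
#' @return A list of class `loo_selection`: `ranking` (tibble: candidate,
#'   elpd, n_covariates, rank), `best` (character vector of covariates), and
#'   `failed` (candidates excluded after fitting errors, with a warning).
#' @export
loo_select <- function(data, response, candidates, site = "site",
                       family = "gamma", method = c("laplace", "mcmc"),
                       n_draws = 1000L, seed = 1L, prior_scale = 5) {
  method <- match.arg(method)
  if (is.null(names(candidates)) || any(names(candidates) == "")) {
    names(candidates) <- vapply(candidates, function(cv) {
      if (length(cv) == 0L) "intercept_only" else paste(cv, collapse = "+")
    }, character(1))
  }
  scores <- purrr::imap(candidates, function(cv, nm) {
    tryCatch(
      loo_elpd(data, response, cv, site, family, prior_scale, n_draws,
               seed, method),
      error = function(e) {
        warning("candidate '", nm, "' excluded: ", conditionMessage(e),
                call. = FALSE)
        NA_real_
      }
    )
  })
  ranking <- tibble::tibble(
    candidate = names(candidates),
    covariates = unname(candidates),
    n_covariates = unname(lengths(candidates)),
    elpd = unname(unlist(scores))
  )
  failed <- ranking$candidate[is.na(ranking$elpd)]
  ranking <- ranking[!is.na(ranking$elpd), ]
  if (nrow(ranking) == 0L) stop_invalid("every candidate model failed.")
  ranking <- dplyr::arrange(ranking, dplyr::desc(.data$elpd), .data$n_covariates)
  ranking$rank <- seq_len(nrow(ranking))
  structure(list(ranking = ranking, best = ranking$covariates[[1]],
                 best_name = ranking$candidate[1], failed = failed),
            class = "loo_selection")
}

#' @export
print.loo_selection <- function(x, ...) {
  cat("<loo_selection> best: ", x$best_name, "\n", sep = "")
  print(x$ranking[, c("candidate", "n_covariates", "elpd", "rank")])
  invisible(x)
}
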