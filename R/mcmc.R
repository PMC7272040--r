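# Posterior engine for the hierarchical habitat models.
#
# All among-habitat and fish-distribution models share one structure: a
# linear predictor eta = X beta + u[site] with site random intercepts
# u_j ~ N(0, sigma_site), an exponential-family likelihood (gaussian /
# beta-logit / negative binomial-log / gamma-log), weakly informative
# normal priors on the coefficients and half-normal priors on scale
# parameters. Sampling is adaptive random-walk Metropolis initialised at the
# posterior mode with a Laplace proposal covariance; a Laplace-only path is
# used for fast exact-refit cross-validation.

linkinv_for <- function(family) {
  switch(family,
    gaussian = identity,
    beta = function(eta) 1 / (1 + exp(-pmin(pmax(eta, -30), 30))),
    negbin = function(eta) exp(pmin(pmax(eta, -30), 30)),
    gamma = function(eta) exp(pmin(pmax(eta, -30), 30))
  )
}

link_for <- function(family) {
  switch(family,
    gaussian = identity,
    beta = function(mu) log(mu / (1 - mu)),
    negbin = log,
    gamma = log
  )
}

check_family_support <- function(y, family) {
  ok <- switch(family,
    gaussian = all(is.finite(y)),
    beta = all(y > 0 & y < 1),
    negbin = all(y >= 0 & abs(y - round(y)) < 1e-8),
    gamma = all(y > 0)
  )
  if (!ok) {
    stop_invalid("response values are outside the support of the '", family,
                 "' family (proportions must lie strictly in (0,1); counts must ",
                 "be non-negative integers; gamma responses strictly positive).")
  }
  invisible(y)
}

# y: response; X: fixed-effect design; group: integer site index.
make_model_data <- function(y, X, group, family, prior_scale = 5) {
  check_family_support(y, family)
  n_groups <- max(group)
  p <- ncol(X)
  has_disp <- TRUE  # every family carries one auxiliary scale parameter
  list(
    y = y, X = X, group = group, family = family,
    n = length(y), p = p, n_groups = n_groups,
    prior_scale = prior_scale,
    # columns shifted by the level-translation move: the intercept if there
    # is one, else every (one-hot level) column
    shift_idx = if ("(Intercept)" %in% colnames(X)) {
      which(colnames(X) == "(Intercept)")
    } else {
      seq_len(p)
    },
    npar = p + n_groups + 1L + has_disp,
    par_names = c(colnames(X), paste0("u[", seq_len(n_groups), "]"),
                  "log_sigma_site", switch(family,
                    gaussian = "log_sigma", beta = "log_phi",
                    negbin = "log_k", gamma = "log_shape"))
  )
}

split_par <- function(par, md) {
  list(beta = par[seq_len(md$p)],
       u = par[md$p + seq_len(md$n_groups)],
       log_sigma_site = par[md$p + md$n_groups + 1L],
       log_disp = par[md$npar])
}

loglik_family <- function(y, mu, family, disp) {
  switch(family,
    gaussian = sum(stats::dnorm(y, mu, disp, log = TRUE)),
    beta = {
      mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
      sum(stats::dbeta(y, mu * disp, (1 - mu) * disp, log = TRUE))
    },
    negbin = sum(stats::dnbinom(y, size = disp, mu = mu, log = TRUE)),
    gamma = sum(stats::dgamma(y, shape = disp, rate = disp / mu, log = TRUE))
  )
}

# Non-centred parameterisation: the stored u are standard-normal raw site
# effects; the site intercepts are sigma_site * u. This keeps the joint
# posterior bounded near sigma_site = 0 (no funnel singularity at the mode).
# Priors (up to constants): beta ~ N(0, prior_scale); u ~ N(0, 1);
# sigma_site ~ half-normal(0, 1) with the log-transform Jacobian;
# log(dispersion) ~ N(log 2, 2).
log_posterior <- function(par, md) {
  if (any(!is.finite(par))) return(-Inf)
  p <- md$p
  ng <- md$n_groups
  log_sigma_site <- par[p + ng + 1L]
  log_disp <- par[p + ng + 2L]
  if (abs(log_sigma_site) > 20 || abs(log_disp) > 20) return(-Inf)
  beta <- par[seq_len(p)]
  u <- par[p + seq_len(ng)]
  sigma_site <- exp(log_sigma_site)
  disp <- exp(log_disp)
  eta <- md$X %*% beta + sigma_site * u[md$group]
  mu <- linkinv_for(md$family)(eta)
  ll <- loglik_family(md$y, mu, md$family, disp)
  if (!is.finite(ll)) return(-Inf)
  ll -
    sum(beta * beta) / (2 * md$prior_scale^2) -
    0.5 * sum(u * u) -
    0.5 * sigma_site^2 + log_sigma_site -
    (log_disp - 0.6931472)^2 / 8
}

# Site intercepts (sigma_site * u_raw) for a draw matrix.
site_effect_draws <- function(draws, md) {
  sigma <- exp(draws[, md$p + md$n_groups + 1L])
  draws[, md$p + seq_len(md$n_groups), drop = FALSE] * sigma
}

init_par <- function(md) {
  link <- link_for(md$family)
  ybar <- switch(md$family,
    gaussian = mean(md$y),
    beta = pmin(pmax(mean(md$y), 0.01), 0.99),
    negbin = max(mean(md$y), 0.1),
    gamma = mean(md$y)
  )
  beta0 <- tryCatch({
    # crude per-column start from a least-squares fit on the link scale
    ylink <- switch(md$family,
      gaussian = md$y,
      beta = link(pmin(pmax(md$y, 0.01), 0.99)),
      negbin = log(md$y + 0.5),
      gamma = log(md$y)
    )
    stats::coef(stats::lm.fit(md$X, ylink))
  }, error = function(e) rep(link(ybar), md$p))
  beta0[!is.finite(beta0)] <- link(ybar)
  c(beta0, rep(0, md$n_groups), log(0.5),
    switch(md$family, gaussian = log(stats::sd(md$y) + 1e-6),
           beta = log(10), negbin = log(2), gamma = log(2)))
}

# Posterior mode and Laplace covariance.
laplace_fit <- function(md, start = NULL) {
  fn <- function(p) -log_posterior(p, md)
  start <- start %||% init_par(md)
  opt <- stats::optim(start, fn, method = "BFGS",
                      control = list(maxit = 500), hessian = TRUE)
  H <- opt$hessian
  eig <- eigen((H + t(H)) / 2, symmetric = TRUE)
  vals <- pmax(eig$values, 1e-6 * max(abs(eig$values), 1e-6))
  cov <- eig$vectors %*% diag(1 / vals, length(vals)) %*% t(eig$vectors)
  list(mode = opt$par, cov = cov, value = -opt$value, convergence = opt$convergence)
}

draw_mvn <- function(n, mean, cov) {
  L <- tryCatch(chol(cov), error = function(e) {
    chol(cov + diag(1e-8, nrow(cov)))
  })
  z <- matrix(stats::rnorm(n * length(mean)), n)
  sweep(z %*% L, 2, mean, `+`)
}

# Univariate slice sampler (stepping out + shrinkage, Neal 2003).
slice_1d <- function(x0, logf, w = 1, m = 20L) {
  f0 <- logf(x0)
  if (!is.finite(f0)) return(x0)
  logy <- f0 - stats::rexp(1)
  lo <- x0 - w * stats::runif(1)
  hi <- lo + w
  k <- m
  while (k > 0L && logf(lo) > logy) {
    lo <- lo - w
    k <- k - 1L
  }
  k <- m
  while (k > 0L && logf(hi) > logy) {
    hi <- hi + w
    k <- k - 1L
  }
  repeat {
    x1 <- stats::runif(1, lo, hi)
    if (logf(x1) >= logy) return(x1)
    if (x1 < x0) lo <- x1 else hi <- x1
    if (hi - lo < 1e-12) return(x0)
  }
}

# Slice update of coordinate j of the full parameter vector.
slice_update <- function(par, lp, j, md, w = 1) {
  x1 <- slice_1d(par[j], function(v) {
    p <- par
    p[j] <- v
    log_posterior(p, md)
  }, w = w)
  par[j] <- x1
  list(par = par, lp = log_posterior(par, md))
}

# Split-chain potential scale reduction factor.
split_rhat <- function(draw_list) {
  halves <- list()
  for (d in draw_list) {
    m <- nrow(d) %/% 2L
    halves <- c(halves, list(d[seq_len(m), , drop = FALSE],
                             d[m + seq_len(m), , drop = FALSE]))
  }
  vapply(seq_len(ncol(draw_list[[1]])), function(j) {
    chains <- vapply(halves, function(h) h[, j], numeric(nrow(halves[[1]])))
    n <- nrow(chains)
    W <- mean(apply(chains, 2, stats::var))
    B <- n * stats::var(colMeans(chains))
    if (W <= 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
}

# Effective sample size from pooled autocorrelations (initial positive
# sequence truncation).
ess_basic <- function(draw_list) {
  vapply(seq_len(ncol(draw_list[[1]])), function(j) {
    total <- 0
    for (d in draw_list) {
      x <- d[, j]
      n <- length(x)
      if (stats::var(x) <= 0) {
        total <- total + n
        next
      }
      rho <- stats::acf(x, lag.max = min(100, n - 1), plot = FALSE)$acf[-1]
      neg <- which(rho < 0)
      if (length(neg)) rho <- rho[seq_len(neg[1] - 1)]
      total <- total + n / (1 + 2 * sum(rho))
    }
    total
  }, numeric(1))
}

to_centred_par <- function(x, u_idx, s_idx) {
  x[u_idx] <- x[u_idx] * exp(x[s_idx])
  x
}

from_centred_par <- function(y, u_idx, s_idx) {
  y[u_idx] <- y[u_idx] * exp(-y[s_idx])
  y
}

# One chain of the composite kernel. When `adapt` is TRUE the random-walk
# covariance, its scale and the centred independence proposal are tuned on
# the fly and the visited states are returned; otherwise the kernel is
# frozen and only post-warmup thinned draws are kept.
run_chain <- function(md, start, kernel, iter, warmup, thin, adapt = FALSE) {
  d <- md$npar
  u_idx <- md$p + seq_len(md$n_groups)
  s_idx <- md$p + md$n_groups + 1L
  cur <- start
  lp_cur <- log_posterior(cur, md)
  L <- kernel$L
  log_scale <- kernel$log_scale
  ind_mean <- kernel$ind_mean
  ind_L <- kernel$ind_L
  log_q <- function(x) {
    w <- backsolve(ind_L, to_centred_par(x, u_idx, s_idx) - ind_mean,
                   transpose = TRUE)
    -0.5 * sum(w^2) + md$n_groups * x[s_idx]
  }
  hist <- if (adapt) matrix(NA_real_, iter, d) else NULL
  kept <- matrix(NA_real_, floor((iter - warmup) / thin), d)
  ki <- 0L
  for (i in seq_len(iter)) {
    # random-walk metropolis with the adapted covariance
    prop <- cur + exp(log_scale) * drop(stats::rnorm(d) %*% L)
    lp_prop <- log_posterior(prop, md)
    alpha <- exp(min(0, lp_prop - lp_cur))
    if (is.finite(lp_prop) && stats::runif(1) < alpha) {
      cur <- prop
      lp_cur <- lp_prop
    }
    # independence proposals from the centred Gaussian fit: near-iid jumps
    # wherever the centred posterior is close to Gaussian
    if (!is.null(ind_mean)) {
      for (rep_ind in 1:2) {
        prop <- from_centred_par(ind_mean + drop(stats::rnorm(d) %*% ind_L),
                                 u_idx, s_idx)
        lp_prop <- log_posterior(prop, md)
        if (is.finite(lp_prop) &&
            stats::runif(1) <
              exp(min(0, lp_prop - lp_cur + log_q(cur) - log_q(prop)))) {
          cur <- prop
          lp_cur <- lp_prop
        }
      }
    }
    # interweaving step (ancillarity-sufficiency): holding the centred site
    # effects v = sigma * u fixed, the conditional of log sigma is free of
    # the likelihood; slice-sample it there and map back. This removes the
    # funnel autocorrelation between sigma_site and u.
    v <- exp(cur[s_idx]) * cur[u_idx]
    lp_s <- function(s) {
      sum(stats::dnorm(v, 0, exp(s), log = TRUE)) +
        stats::dnorm(exp(s), 0, 1, log = TRUE) + s
    }
    s_new <- slice_1d(cur[s_idx], lp_s)
    if (abs(s_new) < 20) {
      cur[s_idx] <- s_new
      cur[u_idx] <- v * exp(-s_new)
      lp_cur <- log_posterior(cur, md)
    }
    # translation move along beta + sigma * mean(u) = const: shifts the
    # overall level between fixed and site effects (volume preserving). The
    # step scales with sigma_site - the level is only weakly identified
    # when the site spread is large.
    delta <- stats::rnorm(1, 0, 0.75 * exp(cur[s_idx]))
    prop <- cur
    prop[md$shift_idx] <- cur[md$shift_idx] + delta
    prop[u_idx] <- cur[u_idx] - delta / exp(cur[s_idx])
    lp_prop <- log_posterior(prop, md)
    if (is.finite(lp_prop) && stats::runif(1) < exp(min(0, lp_prop - lp_cur))) {
      cur <- prop
      lp_cur <- lp_prop
    }
    # 1-D slice update keeps the dispersion parameter moving
    if (i %% 2L == 0L) {
      sl <- slice_update(cur, lp_cur, md$npar, md)
      cur <- sl$par
      lp_cur <- sl$lp
    }
    if (adapt) {
      log_scale <- log_scale + (alpha - 0.234) / sqrt(i)
      hist[i, ] <- cur
      if (i >= 400L && i %% 250L == 0L) {
        recent <- hist[seq_len(i), , drop = FALSE]
        L <- tryCatch(chol(stats::cov(recent) + diag(1e-8, d)),
                      error = function(e) L)
        centred <- t(apply(recent, 1, to_centred_par, u_idx = u_idx,
                           s_idx = s_idx))
        ind_try <- tryCatch(chol(stats::cov(centred) + diag(1e-8, d)),
                            error = function(e) NULL)
        if (!is.null(ind_try)) {
          ind_mean <- colMeans(centred)
          ind_L <- ind_try
        }
      }
    } else if (i > warmup && (i - warmup) %% thin == 0L) {
      ki <- ki + 1L
      kept[ki, ] <- cur
    }
  }
  if (adapt) {
    list(hist = hist, cur = cur,
         kernel = list(L = L, log_scale = log_scale, ind_mean = ind_mean,
                       ind_L = ind_L))
  } else {
    colnames(kept) <- md$par_names
    kept[seq_len(ki), , drop = FALSE]
  }
}

#' @keywords internal
#' @noRd
run_mcmc <- function(md, chains = 3L, iter = 5000L, warmup = 2500L, thin = 3L,
                     seed = 1L) {
  lap <- laplace_fit(md)
  d <- md$npar
  u_idx <- md$p + seq_len(md$n_groups)
  s_idx <- md$p + md$n_groups + 1L
  draw_list <- with_seed(seed, {
    # shared pilot: adapt the kernel once, then freeze it for every chain so
    # all chains run the same transition kernel
    start0 <- lap$mode
    # stage 1: adapt the random-walk covariance and a first independence
    # proposal
    pilot <- run_chain(md, start0,
                       kernel = list(L = chol(lap$cov + diag(1e-10, d)),
                                     log_scale = log(2.38 / sqrt(d)),
                                     ind_mean = NULL, ind_L = NULL),
                       iter = 2500L, warmup = 2500L, thin = thin,
                       adapt = TRUE)
    kernel <- pilot$kernel
    # stage 2: run the frozen kernel to collect a cleaner stationary stretch
    # and refit the centred independence moments from it
    pilot2 <- run_chain(md, pilot$cur, kernel, iter = 2500L, warmup = 2500L,
                        thin = thin, adapt = TRUE)
    kernel <- pilot2$kernel
    refit <- pilot2$hist[seq(250L, nrow(pilot2$hist)), , drop = FALSE]
    centred <- t(apply(refit, 1, to_centred_par, u_idx = u_idx,
                       s_idx = s_idx))
    ind_try <- tryCatch(chol(stats::cov(centred) + diag(1e-8, d)),
                        error = function(e) NULL)
    if (!is.null(ind_try)) {
      kernel$ind_mean <- colMeans(centred)
      kernel$ind_L <- ind_try
    }
    lapply(seq_len(chains), function(ch) {
      start <- refit[sample.int(nrow(refit), 1), ]
      run_chain(md, start, kernel, iter = iter, warmup = warmup, thin = thin)
    })
  })
  rhat <- split_rhat(draw_list)
  ess <- ess_basic(draw_list)
  names(rhat) <- names(ess) <- md$par_names
  draws <- do.call(rbind, draw_list)
  list(draws = draws, draw_list = draw_list, rhat = rhat, ess = ess,
       laplace = lap,
       settings = list(chains = chains, iter = iter, warmup = warmup,
                       thin = thin, seed = seed))
}
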