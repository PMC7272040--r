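#' Tidy a fitted habitat or fish model
#'
#' One row per model term with the back-transformed posterior mean, 95% HPDI
#' and convergence diagnostics, in the broom convention.
#'
#' @param x A `reef_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.reef_fit <- function(x, ...) {
  x$summary
}

#' Model-level summary of a fitted habitat or fish model
#'
#' @param x A `reef_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the family, sampler settings, draw count
#'   and worst-case convergence diagnostics.
#' @export
glance.reef_fit <- function(x, ...) {
  tibble::tibble(
    response = x$response,
    family = x$family,
    n_obs = x$model_data$n,
    n_draws = nrow(x$draws),
    chains = x$settings$chains,
    iter = x$settings$iter,
    warmup = x$settings$warmup,
    thin = x$settings$thin,
    seed = x$settings$seed,
    max_rhat = max(x$diagnostics$rhat),
    min_ess = min(x$diagnostics$ess)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a refuge set
#'
#' @param x A `refuge_set` from [detect_refuges()].
#' @param ... Unused.
#' @return A tibble with columns `type` (`"crevice"`/`"overhang"`), `x`,
#'   `width`, `depth`, `height`.
#' @export
tidy.refuge_set <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$crevices, type = "crevice", height = NA_real_),
    dplyr::mutate(x$overhangs, type = "overhang",
                  width = NA_real_, depth = NA_real_)
  )
}
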