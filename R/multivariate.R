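#' Zero-adjusted Bray-Curtis dissimilarity
#'
#' Appends a constant dummy column of `dummy_value` (the smallest possible
#' abundance by convention) to the community matrix before computing
#' Bray-Curtis dissimilarities, so that pairs of depauperate or empty samples
#' have defined, bounded dissimilarity (two all-zero samples get 0 instead of
#' an undefined value). Dissimilarities never exceed their unadjusted
#' counterparts.
#'
#' @param mat Numeric matrix or data frame of non-negative abundances
#'   (rows = samples, columns = species).
#' @param dummy_value Positive dummy abundance (default 1).
#' @return A symmetric dissimilarity matrix with zero diagonal, entries in
#'   \[0, 1\].
#' @export
#' @examples
#' zero_adjusted_bray_curtis(rbind(c(1, 0), c(0, 1)))  # 0.5 off-diagonal
zero_adjusted_bray_curtis <- function(mat, dummy_value = 1) {
  m <- as.matrix(mat)
  if (any(m < 0)) stop_invalid("abundances must be non-negative.")
  check_scalar_pos(dummy_value, "dummy_value")
  adj <- cbind(m, dummy = dummy_value)
  as.matrix(vegan::vegdist(adj, method = "bray"))
}

#' Gower-centred inner-product matrix of a dissimilarity matrix
#'
#' `G = -1/2 J (D o D) J` with `J = I - 11'/n`: the classical
#' multidimensional-scaling double centring that turns squared
#' dissimilarities into an inner-product (Gram) matrix, the quantity
#' partitioned by distance-based linear models.
#'
#' @param D Symmetric dissimilarity matrix with zero diagonal.
#' @return A centred symmetric matrix whose rows and columns sum to zero.
#' @export
gower_center <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n != ncol(D) || any(abs(D - t(D)) > 1e-8) || any(abs(diag(D)) > 1e-12)) {
    stop_invalid("`D` must be a symmetric dissimilarity matrix with zero diagonal.")
  }
  J <- diag(n) - matrix(1 / n, n, n)
  -0.5 * J %*% (D * D) %*% J
}

#' Marginal distance-based linear model test for one covariate
#'
#' Partitions the total multivariate variation (the trace of the
#' Gower-centred matrix) into the part explained by the hat matrix of
#' `[1, covariate]` and its residual, forming the pseudo-F statistic
#' `[tr(HGH)/q] / [tr((I-H)G(I-H))/(n-q-1)]` with `q = 1`. Significance is
#' assessed by permuting observation labels; the observed statistic is
#' included in the reference set, so `p = (count + 1) / (n_perm + 1)`.
#'
#' @param D Dissimilarity matrix (e.g. [zero_adjusted_bray_curtis()]).
#' @param covariate Numeric vector, one value per observation, non-constant.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Integer seed for the permutation stream.
#' @param name Covariate name carried into the result.
#' @return A one-row tibble: `covariate`, `pseudo_F`, `prop_explained`,
#'   `p_perm`, `n_perm`, `seed`.
#' @export
distlm_marginal <- function(D, covariate, n_perm = 9999, seed = 1L,
                            name = deparse(substitute(covariate))) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (length(covariate) != n) stop_invalid("covariate length must match the matrix.")
  if (stats::sd(covariate) == 0) stop_invalid("covariate is constant.")
  G <- gower_center(D)
  stat <- function(perm) {
    xc <- covariate[perm]
    X <- cbind(1, xc)
    H <- X %*% solve(crossprod(X)) %*% t(X)
    R <- diag(n) - H
    ss_model <- sum(diag(H %*% G %*% H))
    ss_resid <- sum(diag(R %*% G %*% R))
    c(F = (ss_model / 1) / (ss_resid / (n - 2)), ss_model = ss_model)
  }
  obs <- stat(seq_len(n))
  total <- sum(diag(G))
  perm_F <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) stat(sample.int(n))[["F"]], numeric(1))
  })
  tibble::tibble(
    covariate = name,
    pseudo_F = obs[["F"]],
    prop_explained = obs[["ss_model"]] / total,
    p_perm = (sum(perm_F >= obs[["F"]] - 1e-12) + 1) / (n_perm + 1),
    n_perm = n_perm,
    seed = seed
  )
}

#' Marginal DistLM suite over an assemblage
#'
#' Runs [distlm_marginal()] for each covariate against each response matrix
#' of the assemblage: abundance (species split into small and large
#' individuals) and biomass, both as zero-adjusted Bray-Curtis matrices.
#'
#' @param assemblage An [build_assemblage()] object whose `covariates` block
#'   contains the covariate columns.
#' @param covariates Character vector of covariate column names (defaults to
#'   `grazing_area`, `complexity_pc1` and `depth` when present).
#' @param n_perm,seed Permutation settings.
#' @param dummy_value Dummy abundance for the zero adjustment.
#' @return A tibble of marginal test results with a `response` column.
#' @export
run_marginal_suite <- function(assemblage, covariates = NULL, n_perm = 9999,
                               seed = 1L, dummy_value = 1) {
  stopifnot(inherits(assemblage, "assemblage"))
  cov_tbl <- assemblage$covariates
  if (is.null(cov_tbl)) stop_invalid("assemblage has no covariate block.")
  if (is.null(covariates)) {
    covariates <- intersect(c("grazing_area", "complexity_pc1", "depth"),
                            names(cov_tbl))
  }
  responses <- list(
    abundance = as.matrix(assemblage$abundance[setdiff(names(assemblage$abundance),
                                                       c("site", "habitat"))]),
    biomass = as.matrix(assemblage$biomass[setdiff(names(assemblage$biomass),
                                                   c("site", "habitat"))])
  )
  purrr::imap_dfr(responses, function(mat, resp) {
    D <- zero_adjusted_bray_curtis(mat, dummy_value)
    purrr::map_dfr(covariates, function(cv) {
      distlm_marginal(D, cov_tbl[[cv]], n_perm = n_perm, seed = seed, name = cv)
    }) |>
      dplyr::mutate(response = resp, .before = 1)
  })
}
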