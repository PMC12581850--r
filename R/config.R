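#' Run configuration for the JSNMF pipeline
#'
#' Builds and validates the configuration shared by fusion, factorization
#' and co-module extraction.
#'
#' @param K Number of latent components (co-modules). Positive integer,
#'   typically an order of magnitude below the sample size.
#' @param alpha Weight of the similarity-prior penalty \eqn{\alpha\|W-R\|_F^2}.
#'   Nonnegative.
#' @param beta Weight of the orthogonality penalty on each coefficient
#'   matrix. Nonnegative.
#' @param max_iter Iteration cap for the multiplicative updates.
#' @param tol Relative objective-change tolerance for early stopping.
#' @param k_neighbors Neighborhood size of the k-nearest-neighbor affinity.
#'   Default `NULL` means ceiling(n / 10), resolved when the sample size is
#'   known.
#' @param epsilon Off-neighborhood mass of the affinity rows, in (0, 0.5).
#' @param fusion_weights Convex weights of the modality affinities; must be
#'   nonnegative and sum to 1. Default uniform over three modalities.
#' @param ortho_target Orthogonality target matrix: `"identity"` (K x K
#'   identity) or `"ones"` (K x K all-ones).
#' @param zscore_T Z-score exceedance threshold used by
#'   [select_features()].
#' @param scale_blocks Min-max scale every feature column to \[0, 1\]
#'   before factorization so no modality dominates the Frobenius terms.
#' @param mu Bandwidth factor of the scaled-exponential similarity kernel.
#' @param seed Integer seed recorded in the configuration and used by the
#'   pipeline for any stochastic step (e.g. bootstrap intervals).
#'
#' @return A validated list of class `jsnmf_config`.
#' @export
#' @examples
#' cfg <- jsnmf_config(K = 4, alpha = 0.1, beta = 0.1)
#' cfg$max_iter
jsnmf_config <- function(K = 10, alpha = 0.01, beta = 0.01,
                         max_iter = 500L, tol = 1e-6,
                         k_neighbors = NULL, epsilon = 0.01,
                         fusion_weights = rep(1 / 3, 3),
                         ortho_target = c("identity", "ones"),
                         zscore_T = 1.5, scale_blocks = TRUE,
                         mu = 0.5, seed = 1L) {
  ortho_target <- match.arg(ortho_target)
  assert_that(is_count(K), "K must be a positive integer, got %s", format(K))
  assert_that(is_scalar_num(alpha) && alpha >= 0, "alpha must be >= 0")
  assert_that(is_scalar_num(beta) && beta >= 0, "beta must be >= 0")
  assert_that(is.numeric(max_iter) && length(max_iter) == 1L &&
                max_iter >= 0 && max_iter == round(max_iter),
              "max_iter must be a nonnegative integer")
  assert_that(is_scalar_num(tol) && tol > 0, "tol must be > 0")
  if (!is.null(k_neighbors))
    assert_that(is_count(k_neighbors), "k_neighbors must be a positive integer")
  assert_that(is_scalar_num(epsilon) && epsilon > 0 && epsilon < 0.5,
              "epsilon must lie in (0, 0.5)")
  assert_that(is.numeric(fusion_weights) && all(fusion_weights >= 0),
              "fusion_weights must be nonnegative")
  assert_that(abs(sum(fusion_weights) - 1) <= 1e-9,
              "fusion_weights must sum to 1 (got %.12g)", sum(fusion_weights))
  assert_that(is_scalar_num(zscore_T) && zscore_T > 0, "zscore_T must be > 0")
  assert_that(is_scalar_num(mu) && mu > 0, "mu must be > 0")
  assert_that(isTRUE(scale_blocks) || isFALSE(scale_blocks),
              "scale_blocks must be TRUE or FALSE")
  cfg <- list(K = as.integer(K), alpha = alpha, beta = beta,
              max_iter = as.integer(max_iter), tol = tol,
              k_neighbors = if (is.null(k_neighbors)) NULL else as.integer(k_neighbors),
              epsilon = epsilon, fusion_weights = as.numeric(fusion_weights),
              ortho_target = ortho_target, zscore_T = zscore_T,
              scale_blocks = scale_blocks, mu = mu, seed = as.integer(seed))
  class(cfg) <- "jsnmf_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' The file's keys mirror the arguments of [jsnmf_config()] exactly;
#' unknown keys are an error.
#'
#' @param path Path to a YAML file.
#' @return A validated `jsnmf_config`.
#' @export
read_config <- function(path) {
  assert_that(file.exists(path), "config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(jsnmf_config))
  bad <- setdiff(names(vals), allowed)
  assert_that(length(bad) == 0L, "unknown config keys: %s",
              paste(bad, collapse = ", "))
  do.call(jsnmf_config, vals)
}

#' Write a run configuration to a YAML file
#'
#' @param config A `jsnmf_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "jsnmf_config"))
  yaml::write_yaml(unclass(config), path, precision = 17L)
  invisible(path)
}

# Resolve the default neighborhood size once n is known.
resolve_k_neighbors <- function(config, n) {
  k <- config$k_neighbors %||% as.integer(ceiling(n / 10))
  max(1L, min(k, n - 1L))
}

#' @export
print.jsnmf_config <- function(x, ...) {
  cat("jsnmf run configuration\n")
  cat(sprintf("  K = %d, alpha = %g, beta = %g, ortho_target = %s\n",
              x$K, x$alpha, x$beta, x$ortho_target))
  cat(sprintf("  max_iter = %d, tol = %g, scale_blocks = %s\n",
              x$max_iter, x$tol, x$scale_blocks))
  cat(sprintf("  k_neighbors = %s, epsilon = %g, mu = %g, weights = (%s)\n",
              if (is.null(x$k_neighbors)) "auto (n/10)" else x$k_neighbors,
              x$epsilon, x$mu, paste(signif(x$fusion_weights, 3), collapse = ", ")))
  cat(sprintf("  zscore_T = %g, seed = %d\n", x$zscore_T, x$seed))
  invisible(x)
}
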