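# Joint factorization: X_I ~ W H_I (I = 1..3) with a shared nonnegative
# basis W over samples. The constrained variant adds a similarity-prior
# penalty pulling W toward the SNF-derived prior R and an orthogonality
# penalty sparsifying each H_I, both handled by multiplicative updates
# derived from KKT stationarity.

GUARD <- 1e-10

new_jsnmf_model <- function(W, H, config, variant, trace = NULL,
                            scaling = NULL) {
  structure(list(W = W, H = H, config = config, variant = variant,
                 trace = trace, scaling = scaling),
            class = "jsnmf_model")
}

#' @export
print.jsnmf_model <- function(x, ...) {
  q <- vapply(x$H, ncol, integer(1))
  cat(sprintf("jsnmf_model (%s): W %d x %d; H blocks %s\n", x$variant,
              nrow(x$W), ncol(x$W), paste(q, collapse = " / ")))
  if (!is.null(x$trace) && nrow(x$trace) > 0)
    cat(sprintf("  %d iterations, final objective %.6g\n",
                nrow(x$trace), x$trace$objective[nrow(x$trace)]))
  invisible(x)
}

ortho_matrix <- function(K, ortho_target) {
  switch(ortho_target,
         identity = diag(K),
         ones = matrix(1, K, K),
         stop("unknown ortho_target: ", ortho_target))
}

# Per-feature min-max scaling of every block to [0, 1]; constant columns
# map to 1 (divide by their maximum) so they stay informative and nonzero.
scale_dataset <- function(blocks) {
  scaling <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    lo <- apply(b, 2L, min)
    hi <- apply(b, 2L, max)
    span <- hi - lo
    scaled <- sweep(b, 2L, lo, "-")
    scaled <- sweep(scaled, 2L, ifelse(span > 0, span, 1), "/")
    const <- span == 0
    if (any(const)) scaled[, const] <- 1
    blocks[[i]] <- scaled
    scaling[[i]] <- list(min = lo, max = hi)
  }
  list(blocks = blocks, scaling = scaling)
}

# Apply a stored scaling to fresh blocks (same features, same order).
apply_scaling <- function(blocks, scaling) {
  if (is.null(scaling)) return(blocks)
  for (i in seq_along(blocks)) {
    lo <- scaling[[i]]$min
    hi <- scaling[[i]]$max
    span <- hi - lo
    b <- sweep(blocks[[i]], 2L, lo, "-")
    b <- sweep(b, 2L, ifelse(span > 0, span, 1), "/")
    if (any(span == 0)) b[, span == 0] <- 1
    blocks[[i]] <- b
  }
  blocks
}

as_blocks <- function(dataset) {
  if (inherits(dataset, "multiomics_dataset")) dataset$blocks else dataset
}

#' Joint factorization objective
#'
#' Evaluates
#' \deqn{\sum_I \|X_I - W H_I\|_F^2 + s\,\beta \sum_I \|H_I H_I^T - M\|_F^2
#'   + \alpha \|W - R\|_F^2}
#' where M is the K x K identity or all-ones matrix. The default ortho
#' scale `s = 0.5` parameterizes the orthogonality penalty so that the
#' multiplicative update rule is its exact KKT minimizer (the penalty
#' gradient is then \eqn{2\beta(H H^T - M)H}, matching the update's
#' denominator); `ortho_scale = 1` evaluates the penalty at face value.
#'
#' @param W n x K basis matrix.
#' @param H List of three K x q_I coefficient matrices.
#' @param dataset A `multiomics_dataset` or list of three blocks
#'   (assumed on the scale used for fitting).
#' @param R Prior matrix (n x K) or `NULL` when `alpha = 0`.
#' @param alpha,beta Penalty weights.
#' @param ortho_target `"identity"` or `"ones"`.
#' @param ortho_scale Scale of the orthogonality penalty (default 0.5).
#' @return Nonnegative scalar.
#' @export
jsnmf_objective <- function(W, H, dataset, R = NULL, alpha = 0, beta = 0,
                            ortho_target = "identity", ortho_scale = 0.5) {
  blocks <- as_blocks(dataset)
  K <- ncol(W)
  M <- ortho_matrix(K, ortho_target)
  obj <- 0
  for (i in seq_along(blocks)) {
    Hi <- H[[i]]
    obj <- obj + fnorm(blocks[[i]] - W %*% Hi)^2
    if (beta > 0)
      obj <- obj + ortho_scale * beta * fnorm(Hi %*% t(Hi) - M)^2
  }
  if (alpha > 0) {
    assert_that(!is.null(R), "alpha > 0 requires a prior matrix R")
    obj <- obj + alpha * fnorm(W - R)^2
  }
  obj
}

#' Analytic gradients of the constrained objective
#'
#' Gradients of [jsnmf_objective()] (at its default ortho scale) with
#' respect to W and each H_I:
#' \eqn{\nabla_W = \sum_I(-2 X_I H_I^T + 2 W H_I H_I^T) + 2\alpha W - 2\alpha R},
#' \eqn{\nabla_{H_I} = -2 W^T X_I + 2 W^T W H_I + 2\beta (H_I H_I^T - M) H_I}.
#'
#' @inheritParams jsnmf_objective
#' @return List with `dW` and `dH` (list of three matrices).
#' @export
jsnmf_gradient <- function(W, H, dataset, R = NULL, alpha = 0, beta = 0,
                           ortho_target = "identity") {
  blocks <- as_blocks(dataset)
  K <- ncol(W)
  M <- ortho_matrix(K, ortho_target)
  dW <- matrix(0, nrow(W), K)
  dH <- vector("list", length(blocks))
  WtW <- crossprod(W)
  for (i in seq_along(blocks)) {
    Xi <- blocks[[i]]; Hi <- H[[i]]
    dW <- dW + (-2) * Xi %*% t(Hi) + 2 * W %*% (Hi %*% t(Hi))
    dH[[i]] <- -2 * crossprod(W, Xi) + 2 * WtW %*% Hi +
      2 * beta * (Hi %*% t(Hi) - M) %*% Hi
  }
  if (alpha > 0) {
    assert_that(!is.null(R), "alpha > 0 requires a prior matrix R")
    dW <- dW + 2 * alpha * W - 2 * alpha * R
  }
  list(dW = dW, dH = dH)
}

#' One multiplicative update of the unconstrained joint factorization
#'
#' Synchronous sweep: W is rescaled by the ratio of
#' \eqn{\sum_I X_I H_I^T} to \eqn{\sum_I W H_I H_I^T}, then each H_I by
#' the ratio of \eqn{W^T X_I} to \eqn{W^T W H_I} using the freshly
#' updated W. Denominators are guarded by +1e-10; nonnegativity is
#' preserved.
#'
#' @param W,H Current iterates.
#' @param dataset Blocks on the fitting scale.
#' @return List with updated `W` and `H`.
#' @export
jnmf_step <- function(W, H, dataset) {
  blocks <- as_blocks(dataset)
  num_W <- Reduce(`+`, Map(function(X, Hi) X %*% t(Hi), blocks, H))
  den_W <- Reduce(`+`, lapply(H, function(Hi) W %*% (Hi %*% t(Hi))))
  W_new <- W * num_W / (den_W + GUARD)
  check_finite(W_new, "W")
  WtW <- crossprod(W_new)
  H_new <- Map(function(X, Hi) {
    out <- Hi * crossprod(W_new, X) / (WtW %*% Hi + GUARD)
    check_finite(out, "H")
    out
  }, blocks, H)
  list(W = W_new, H = H_new)
}

check_finite <- function(M, what) {
  if (!all(is.finite(M)))
    stop(sprintf("numerical failure: non-finite values in %s update", what),
         call. = FALSE)
  invisible(TRUE)
}

#' One multiplicative update of the constrained joint factorization
#'
#' W is rescaled by \eqn{(\sum_I X_I H_I^T + \alpha R) /
#' (\sum_I W H_I H_I^T + \alpha W)}, then each H_I using the updated W.
#' The H update derives from the KKT condition
#' \eqn{W^T X_I = W^T W H_I + \beta (H_I H_I^T - M) H_I} with the
#' orthogonality term split by sign so both sides stay nonnegative:
#' \deqn{H_I \gets H_I \circ \frac{W^T X_I + \beta M H_I}
#'   {W^T W H_I + \beta H_I H_I^T H_I},}
#' which shares its fixed points with the unsplit ratio while keeping the
#' denominator strictly positive (the unsplit form can turn negative for
#' large \eqn{\beta}, where clamping it destroys the non-increasing
#' objective). Denominators carry a +1e-10 guard. With
#' `alpha = beta = 0` the update coincides exactly with [jnmf_step()].
#'
#' @inheritParams jnmf_step
#' @param R Prior matrix (n x K); required when `alpha > 0`.
#' @param alpha,beta Penalty weights.
#' @param ortho_target `"identity"` or `"ones"`.
#' @return List with updated `W` and `H`.
#' @export
jsnmf_step <- function(W, H, dataset, R = NULL, alpha = 0, beta = 0,
                       ortho_target = "identity") {
  blocks <- as_blocks(dataset)
  K <- ncol(W)
  M <- ortho_matrix(K, ortho_target)
  num_W <- Reduce(`+`, Map(function(X, Hi) X %*% t(Hi), blocks, H))
  den_W <- Reduce(`+`, lapply(H, function(Hi) W %*% (Hi %*% t(Hi))))
  if (alpha > 0) {
    assert_that(!is.null(R), "alpha > 0 requires a prior matrix R")
    num_W <- num_W + alpha * R
    den_W <- den_W + alpha * W
  }
  W_new <- W * num_W / (den_W + GUARD)
  check_finite(W_new, "W")
  WtW <- crossprod(W_new)
  H_new <- vector("list", length(H))
  for (i in seq_along(H)) {
    Hi <- H[[i]]
    num <- crossprod(W_new, blocks[[i]])
    den <- WtW %*% Hi
    if (beta > 0) {
      num <- num + beta * M %*% Hi
      den <- den + beta * (Hi %*% t(Hi)) %*% Hi
    }
    H_new[[i]] <- Hi * num / (den + GUARD)
    check_finite(H_new[[i]], "H")
  }
  list(W = W_new, H = H_new)
}

#' Relative reconstruction error
#'
#' The model-selection objective
#' \eqn{\sum_I \mathrm{mean}(|X_I - W H_I|) / \mathrm{mean}(X_I)}: per
#' block, the grand mean of the absolute residual divided by the grand
#' mean of the data, summed over the three blocks. Scale-invariant under
#' joint rescaling of a block and its reconstruction.
#'
#' @param dataset Blocks on the fitting scale (a `multiomics_dataset` or
#'   list of matrices).
#' @param W,H Factor matrices.
#' @return Nonnegative scalar.
#' @export
relative_error <- function(dataset, W, H) {
  blocks <- as_blocks(dataset)
  total <- 0
  for (i in seq_along(blocks)) {
    mX <- mean(blocks[[i]])
    assert_that(mX > 0, "block %d has zero mean; relative error undefined", i)
    total <- total + mean(abs(blocks[[i]] - W %*% H[[i]])) / mX
  }
  total
}

variant_weights <- function(variant, config) {
  switch(variant,
         jnmf = list(alpha = 0, beta = 0),
         oc_jnmf = list(alpha = 0, beta = config$beta),
         snf_jnmf = list(alpha = config$alpha, beta = 0),
         jsnmf = list(alpha = config$alpha, beta = config$beta),
         stop("unknown variant: ", variant))
}

#' Fit the joint factorization
#'
#' NNDSVD-initialized multiplicative updates for one of four variants:
#' `"jnmf"` (no constraints), `"oc_jnmf"` (orthogonality only),
#' `"snf_jnmf"` (similarity prior only), `"jsnmf"` (both). Iterates until
#' the relative change of the objective drops below `config$tol` or
#' `config$max_iter` is reached. Deterministic end-to-end.
#'
#' @param dataset A `multiomics_dataset`.
#' @param R A `prior_matrix`, its raw matrix, or `NULL`; required by the
#'   prior-regularized variants.
#' @param config A `jsnmf_config`.
#' @param variant Factorization variant.
#' @return A `jsnmf_model` whose `trace` is a data frame with columns
#'   `iter`, `objective`, `relative_error`, `dW`, `dH1`, `dH2`, `dH3`
#'   (Frobenius distances between successive iterates).
#' @export
jsnmf_fit <- function(dataset, R = NULL, config = jsnmf_config(),
                      variant = c("jsnmf", "jnmf", "oc_jnmf", "snf_jnmf")) {
  variant <- match.arg(variant)
  stopifnot(inherits(config, "jsnmf_config"))
  blocks <- as_blocks(dataset)
  scaling <- NULL
  if (config$scale_blocks) {
    sc <- scale_dataset(blocks)
    blocks <- sc$blocks
    scaling <- sc$scaling
  }
  wts <- variant_weights(variant, config)
  Rm <- if (inherits(R, "prior_matrix")) R$matrix else R
  if (wts$alpha > 0)
    assert_that(!is.null(Rm), "variant '%s' requires a prior matrix R", variant)
  init <- nndsvd_init(blocks, config$K)
  W <- init$W; H <- init$H
  obj_fun <- function(W, H) jsnmf_objective(W, H, blocks, Rm, wts$alpha,
                                            wts$beta, config$ortho_target)
  trace <- vector("list", config$max_iter)
  obj_prev <- obj_fun(W, H)
  n_iter <- 0L
  if (config$max_iter > 0) {
    for (t in seq_len(config$max_iter)) {
      upd <- if (variant == "jnmf") jnmf_step(W, H, blocks)
             else jsnmf_step(W, H, blocks, Rm, wts$alpha, wts$beta,
                             config$ortho_target)
      obj <- obj_fun(upd$W, upd$H)
      trace[[t]] <- data.frame(
        iter = t, objective = obj,
        relative_error = relative_error(blocks, upd$W, upd$H),
        dW = fnorm(upd$W - W),
        dH1 = fnorm(upd$H[[1L]] - H[[1L]]),
        dH2 = fnorm(upd$H[[2L]] - H[[2L]]),
        dH3 = fnorm(upd$H[[3L]] - H[[3L]]))
      W <- upd$W; H <- upd$H
      n_iter <- t
      delta <- abs(obj - obj_prev) / max(obj_prev, 1e-30)
      obj_prev <- obj
      if (delta < config$tol) break
    }
  }
  trace <- if (n_iter > 0) do.call(rbind, trace[seq_len(n_iter)])
           else data.frame(iter = integer(), objective = numeric(),
                           relative_error = numeric(), dW = numeric(),
                           dH1 = numeric(), dH2 = numeric(), dH3 = numeric())
  new_jsnmf_model(W, H, config, variant, trace = trace, scaling = scaling)
}

#' Reconstruction quality metrics of a fitted model
#'
#' Reports the relative error, the summed Frobenius (Euclidean) distance
#' \eqn{\sum_I \|X_I - W H_I\|_F}, and per block the mean over samples of
#' the per-sample Pearson correlation between observed and reconstructed
#' feature vectors, with a seeded percentile-bootstrap 95\% interval over
#' samples. Samples with a constant observed or reconstructed vector are
#' excluded with a warning. All quantities are computed on the scale used
#' for fitting.
#'
#' @param dataset The `multiomics_dataset` the model was fitted to.
#' @param model A `jsnmf_model`.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Seed for the bootstrap.
#' @return List with `relative_error`, `euclidean_distance`, and
#'   `sample_cor` (data frame: block, mean_cor, ci_lo, ci_hi, n_samples).
#' @export
reconstruction_metrics <- function(dataset, model, n_boot = 2000L,
                                   seed = 1L) {
  stopifnot(inherits(model, "jsnmf_model"))
  blocks <- apply_scaling(as_blocks(dataset), model$scaling)
  W <- model$W; H <- model$H
  euclid <- sum(vapply(seq_along(blocks), function(i)
    fnorm(blocks[[i]] - W %*% H[[i]]), numeric(1)))
  rows <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    X <- blocks[[i]]
    Xhat <- W %*% H[[i]]
    cors <- vapply(seq_len(nrow(X)), function(s) {
      x <- X[s, ]; y <- Xhat[s, ]
      if (sd_pop(x) == 0 || sd_pop(y) == 0) NA_real_
      else stats::cor(x, y)
    }, numeric(1))
    if (anyNA(cors))
      warning(sprintf("block %d: %d sample(s) with constant vectors excluded from correlation", i, sum(is.na(cors))), call. = FALSE)
    cors <- cors[!is.na(cors)]
    if (length(cors) == 0L) {
      rows[[i]] <- data.frame(block = i, mean_cor = NA_real_,
                              ci_lo = NA_real_, ci_hi = NA_real_,
                              n_samples = 0L)
      next
    }
    ci <- with_seed(seed + i, {
      boots <- vapply(seq_len(n_boot), function(b)
        mean(cors[sample.int(length(cors), replace = TRUE)]), numeric(1))
      stats::quantile(boots, c(0.025, 0.975), names = FALSE)
    })
    rows[[i]] <- data.frame(block = i, mean_cor = mean(cors),
                            ci_lo = ci[1L], ci_hi = ci[2L],
                            n_samples = length(cors))
  }
  list(relative_error = relative_error(blocks, W, H),
       euclidean_distance = euclid,
       sample_cor = do.call(rbind, rows))
}

#' Match fitted components to reference components
#'
#' Finds the permutation of fitted components maximizing the mean Pearson
#' correlation between matched columns of `W` and `W_ref` (exhaustive
#' search; intended for K <= 8). Used to score planted-factor recovery,
#' where component order is arbitrary.
#'
#' @param W Fitted basis (n x K).
#' @param W_ref Reference basis (n x K).
#' @return List with `perm` (column `k` of `W_ref` is matched by column
#'   `perm[k]` of `W`), `cors` (matched correlations), `mean_cor`.
#' @export
match_components <- function(W, W_ref) {
  K <- ncol(W_ref)
  assert_that(ncol(W) >= K, "W must have at least as many columns as W_ref")
  assert_that(K <= 8L, "exhaustive matching supports K <= 8")
  C <- suppressWarnings(stats::cor(W_ref, W))  # K x ncol(W)
  C[!is.finite(C)] <- 0
  perms <- permutations_of(ncol(W), K)
  best <- NULL; best_val <- -Inf
  for (p in perms) {
    val <- sum(C[cbind(seq_len(K), p)])
    if (val > best_val) { best_val <- val; best <- p }
  }
  list(perm = best, cors = C[cbind(seq_len(K), best)],
       mean_cor = best_val / K)
}

# All ordered selections of k distinct items from n (n^k growth; small use).
permutations_of <- function(n, k) {
  if (k == 0L) return(list(integer()))
  out <- list()
  recurse <- function(prefix, remaining) {
    if (length(prefix) == k) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (x in remaining) recurse(c(prefix, x), setdiff(remaining, x))
  }
  recurse(integer(), seq_len(n))
  out
}
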