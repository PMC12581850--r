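# Similarity network fusion: per-modality affinity graphs, their convex
# fusion, a spectral-clustering sanity check against the recurrence label,
# and distillation of the n x K prior matrix R by PCA.

new_affinity_graph <- function(matrix, kind, k_neighbors = NA_integer_,
                               epsilon = NA_real_) {
  structure(list(matrix = matrix, kind = kind,
                 k_neighbors = k_neighbors, epsilon = epsilon),
            class = "affinity_graph")
}

#' @export
print.affinity_graph <- function(x, ...) {
  cat(sprintf("affinity_graph (%s): %d x %d\n", x$kind,
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Pairwise Euclidean distances between samples
#'
#' @param X Numeric matrix, samples in rows.
#' @return An `affinity_graph` of kind `"distance"`: symmetric, zero
#'   diagonal, nonnegative.
#' @export
pairwise_distance <- function(X) {
  X <- as.matrix(X)
  assert_that(all(is.finite(X)), "X must be finite")
  assert_that(nrow(X) >= 3L, "need at least 3 samples (neighborhoods undefined)")
  D <- as.matrix(stats::dist(X, method = "euclidean"))
  dimnames(D) <- list(rownames(X), rownames(X))
  new_affinity_graph(D, "distance")
}

#' Scaled-exponential similarity kernel with local bandwidth
#'
#' Converts a distance graph into similarities
#' \eqn{S_{ij} = \exp(-D_{ij}^2 / (\mu \sigma_{ij}))} with the local
#' bandwidth \eqn{\sigma_{ij} = (\bar d_i + \bar d_j + D_{ij}) / 3}, where
#' \eqn{\bar d_i} is the mean distance from sample i to its k nearest
#' neighbors (self excluded). This is the standard kernel used with
#' similarity network fusion; it adapts to heterogeneous density.
#'
#' @param D An `affinity_graph` of kind `"distance"`.
#' @param k Neighborhood size, 1 <= k < n.
#' @param mu Bandwidth factor (default 0.5).
#' @return An `affinity_graph` of kind `"similarity"`, symmetric with unit
#'   diagonal and entries in (0, 1].
#' @export
similarity_kernel <- function(D, k, mu = 0.5) {
  stopifnot(inherits(D, "affinity_graph"), D$kind == "distance")
  Dm <- D$matrix
  n <- nrow(Dm)
  assert_that(k >= 1 && k < n, "k must satisfy 1 <= k < n")
  assert_that(any(Dm > 0), "degenerate input: all samples identical")
  # mean distance to the k nearest neighbors, self excluded
  dbar <- vapply(seq_len(n), function(i) {
    d <- Dm[i, -i]
    mean(sort(d, partial = k)[seq_len(k)])
  }, numeric(1))
  sigma <- (outer(dbar, dbar, "+") + Dm) / 3
  sigma[sigma <= 0] <- .Machine$double.eps
  S <- exp(-(Dm^2) / (mu * sigma))
  diag(S) <- 1
  S <- (S + t(S)) / 2
  dimnames(S) <- dimnames(Dm)
  new_affinity_graph(S, "similarity")
}

# Indices of the k nearest neighbors of row i in similarity space
# (largest similarity first), self excluded, ties broken by smaller index.
knn_indices <- function(S_row, i, k) {
  cand <- setdiff(seq_along(S_row), i)
  ord <- cand[order(-S_row[cand], cand)]
  ord[seq_len(k)]
}

#' Row-stochastic k-nearest-neighbor affinity matrix
#'
#' Each row distributes mass \eqn{1 - \varepsilon} over the k nearest
#' neighbors proportionally to similarity and mass \eqn{\varepsilon} over
#' the remaining samples. Rows sum to one by construction. Rows whose
#' out-of-neighborhood similarity mass is zero put all mass on the
#' neighborhood (logged) instead of dividing by zero.
#'
#' @param S An `affinity_graph` of kind `"similarity"`.
#' @param k Neighborhood size, 1 <= k < n.
#' @param epsilon Off-neighborhood mass, in (0, 0.5).
#' @return An `affinity_graph` of kind `"knn_affinity"`.
#' @export
knn_affinity <- function(S, k, epsilon = 0.01) {
  stopifnot(inherits(S, "affinity_graph"), S$kind == "similarity")
  Sm <- S$matrix
  n <- nrow(Sm)
  assert_that(k >= 1 && k < n, "k must satisfy 1 <= k < n")
  assert_that(epsilon > 0 && epsilon < 0.5, "epsilon must lie in (0, 0.5)")
  A <- matrix(0, n, n, dimnames = dimnames(Sm))
  for (i in seq_len(n)) {
    nb <- knn_indices(Sm[i, ], i, k)
    out <- setdiff(seq_len(n), c(i, nb))
    in_mass <- sum(Sm[i, nb])
    out_mass <- sum(Sm[i, out])
    if (out_mass > 0) {
      A[i, nb] <- (1 - epsilon) * Sm[i, nb] / in_mass
      A[i, out] <- epsilon * Sm[i, out] / out_mass
    } else {
      jsnmf_log("debug", "row %d: zero out-of-neighborhood mass; epsilon mass folded into neighborhood", i)
      A[i, nb] <- Sm[i, nb] / in_mass
    }
  }
  new_affinity_graph(A, "knn_affinity", k_neighbors = as.integer(k),
                     epsilon = epsilon)
}

#' Fuse per-modality affinity graphs by convex combination
#'
#' \eqn{A = \sum_m w_m A^{(m)}} with nonnegative weights summing to one;
#' row-stochasticity of the inputs is preserved.
#'
#' @param affinities List of `affinity_graph`s of kind `"knn_affinity"`.
#' @param weights Simplex weight vector, one per graph (default uniform).
#' @return An `affinity_graph` of kind `"fused"`.
#' @export
fuse_affinity <- function(affinities, weights = NULL) {
  assert_that(is.list(affinities) && length(affinities) >= 1L,
              "affinities must be a non-empty list")
  for (a in affinities)
    stopifnot(inherits(a, "affinity_graph"), a$kind == "knn_affinity")
  dims <- vapply(affinities, function(a) nrow(a$matrix), integer(1))
  assert_that(length(unique(dims)) == 1L, "affinity graphs differ in size")
  weights <- weights %||% rep(1 / length(affinities), length(affinities))
  assert_that(length(weights) == length(affinities),
              "one weight per affinity graph required")
  assert_that(all(weights >= 0), "weights must be nonnegative")
  assert_that(abs(sum(weights) - 1) <= 1e-9,
              "weights must sum to 1 (got %.12g)", sum(weights))
  A <- Reduce(`+`, Map(function(a, w) w * a$matrix, affinities, weights))
  new_affinity_graph(A, "fused")
}

# Deterministic 2-means on a spectral embedding: centers seeded at the
# farthest pair of embedded points, then standard Lloyd iterations.
kmeans2_deterministic <- function(E) {
  D2 <- as.matrix(stats::dist(E))
  far <- which(D2 == max(D2), arr.ind = TRUE)[1L, ]
  centers <- E[c(far[1L], far[2L]), , drop = FALSE]
  if (all(centers[1L, ] == centers[2L, ]))
    return(rep(1L, nrow(E)))
  km <- stats::kmeans(E, centers = centers, iter.max = 100L)
  km$cluster
}

#' Spectral-clustering check of the fused network against labels
#'
#' Clusters the symmetrized fused affinity into two groups with normalized
#' spectral clustering and reports the adjusted Rand index against the
#' recurrence label. Purely diagnostic: validates that the fusion carries
#' the outcome signal; it does not alter the pipeline.
#'
#' @param A An `affinity_graph` of kind `"fused"` (or any nonnegative
#'   symmetric-after-symmetrization affinity).
#' @param labels Binary vector of length n.
#' @return List with `assignments` (integer cluster ids) and `agreement`
#'   (adjusted Rand index).
#' @export
spectral_check <- function(A, labels) {
  stopifnot(inherits(A, "affinity_graph"))
  Am <- (A$matrix + t(A$matrix)) / 2
  n <- nrow(Am)
  assert_that(length(labels) == n, "labels length != n")
  g <- Am
  diag(g) <- 0
  deg <- rowSums(g)
  if (any(deg == 0))
    warning("affinity graph has isolated nodes; clustering attempted anyway",
            call. = FALSE)
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  L <- diag(n) - (dinv * g) %*% diag(dinv)  # normalized Laplacian
  ev <- eigen(L, symmetric = TRUE)
  E <- ev$vectors[, c(n, n - 1L)]
  rn <- sqrt(rowSums(E^2))
  E <- E / ifelse(rn > 0, rn, 1)
  cl <- kmeans2_deterministic(E)
  list(assignments = cl,
       agreement = mclust::adjustedRandIndex(cl, labels))
}

#' Distill the prior matrix R from the fused affinity network
#'
#' Column-centers the fused affinity, takes the K leading principal
#' component score vectors, applies a deterministic sign convention (each
#' component's loading vector is flipped so its largest-magnitude entry is
#' positive) and min-max scales each score column into \[0, 1\] so the
#' prior is nonnegative while preserving the sample ordering within each
#' component.
#'
#' @param A An `affinity_graph` of kind `"fused"`.
#' @param K Number of components, 1 <= K < n.
#' @return A `prior_matrix`: list with `matrix` (n x K, entries in
#'   \[0, 1\]), `source_rank`, and `column_scaling` (per-column min/max of
#'   the raw scores).
#' @export
extract_prior <- function(A, K) {
  stopifnot(inherits(A, "affinity_graph"))
  Am <- A$matrix
  n <- nrow(Am)
  assert_that(K >= 1 && K < n, "K must satisfy 1 <= K < n")
  pc <- stats::prcomp(Am, center = TRUE, scale. = FALSE, rank. = K)
  scores <- pc$x[, seq_len(K), drop = FALSE]
  load <- pc$rotation[, seq_len(K), drop = FALSE]
  for (k in seq_len(K)) {
    j <- which.max(abs(load[, k]))
    if (load[j, k] < 0) {
      scores[, k] <- -scores[, k]
      load[, k] <- -load[, k]
    }
  }
  rng <- apply(scores, 2L, range)
  R <- scores
  for (k in seq_len(K)) {
    span <- rng[2L, k] - rng[1L, k]
    R[, k] <- if (span > 0) (scores[, k] - rng[1L, k]) / span else 0
  }
  dimnames(R) <- list(rownames(Am), paste0("C", seq_len(K)))
  structure(list(matrix = R, source_rank = as.integer(K),
                 column_scaling = data.frame(component = colnames(R),
                                             min = rng[1L, ], max = rng[2L, ])),
            class = "prior_matrix")
}

#' @export
print.prior_matrix <- function(x, ...) {
  cat(sprintf("prior_matrix: %d x %d, entries in [0, 1]\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Build the fused similarity network and prior from a dataset
#'
#' Convenience wrapper running distance -> kernel -> k-NN affinity per
#' modality, fusing with the configured weights, and extracting the K
#' column prior.
#'
#' @param dataset A `multiomics_dataset`.
#' @param config A `jsnmf_config`.
#' @return List with `fused` (`affinity_graph`), `prior`
#'   (`prior_matrix`), and `spectral` (the [spectral_check()] result, or
#'   `NULL` when the dataset has no labels).
#' @export
build_prior <- function(dataset, config) {
  stopifnot(inherits(dataset, "multiomics_dataset"),
            inherits(config, "jsnmf_config"))
  n <- length(dataset$sample_ids)
  k <- resolve_k_neighbors(config, n)
  graphs <- lapply(dataset$blocks, function(X) {
    D <- pairwise_distance(X)
    S <- similarity_kernel(D, k = k, mu = config$mu)
    knn_affinity(S, k = k, epsilon = config$epsilon)
  })
  fused <- fuse_affinity(graphs, config$fusion_weights)
  spectral <- if (!is.null(dataset$labels))
    spectral_check(fused, dataset$labels) else NULL
  prior <- extract_prior(fused, config$K)
  list(fused = fused, prior = prior, spectral = spectral)
}
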