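# Nonnegative double singular value decomposition (NNDSVD) initialization.
# Deterministic: removes run-to-run randomness from the multiplicative
# updates so fits are bitwise reproducible.

# Core NNDSVD on a single nonnegative matrix X (n x q) -> list(W, H).
# Zero-fill variant: structural zeros are replaced by a small floor so
# multiplicative updates can move them.
nndsvd <- function(X, K, floor_value = 1e-6) {
  n <- nrow(X); q <- ncol(X)
  assert_that(K <= min(n, q), "K must not exceed min(dim(X))")
  assert_that(all(X >= 0), "NNDSVD requires a nonnegative matrix")
  sv <- svd(X, nu = K, nv = K)
  W <- matrix(0, n, K)
  H <- matrix(0, K, q)
  # leading pair of a nonnegative matrix can be taken entrywise nonnegative
  W[, 1L] <- sqrt(sv$d[1L]) * abs(sv$u[, 1L])
  H[1L, ] <- sqrt(sv$d[1L]) * abs(sv$v[, 1L])
  if (K >= 2L) {
    for (j in 2:K) {
      u <- sv$u[, j]; v <- sv$v[, j]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      nup <- sqrt(sum(up^2)); nun <- sqrt(sum(un^2))
      nvp <- sqrt(sum(vp^2)); nvn <- sqrt(sum(vn^2))
      termp <- nup * nvp; termn <- nun * nvn
      if (termp >= termn && termp > 0) {
        scale <- sqrt(sv$d[j] * termp)
        W[, j] <- scale * up / nup
        H[j, ] <- scale * vp / nvp
      } else if (termn > 0) {
        scale <- sqrt(sv$d[j] * termn)
        W[, j] <- scale * un / nun
        H[j, ] <- scale * vn / nvn
      }
      # termp == termn == 0 (null singular triplet): left at zero, floored below
    }
  }
  rank_num <- sum(sv$d > sv$d[1L] * max(n, q) * .Machine$double.eps)
  if (K > rank_num)
    warning(sprintf("K = %d exceeds numerical rank %d; trailing components seeded at the floor value", K, rank_num), call. = FALSE)
  W[W < floor_value] <- floor_value
  H[H < floor_value] <- floor_value
  list(W = W, H = H)
}

#' NNDSVD initialization of the joint factorization
#'
#' Applies nonnegative double SVD to the column-concatenation
#' \eqn{[X_1\, X_2\, X_3]} and splits the resulting coefficient matrix
#' column-wise into the three per-modality blocks. Fully deterministic;
#' structural zeros are replaced by a small floor (default 1e-6) so the
#' multiplicative updates can escape them.
#'
#' @param dataset A `multiomics_dataset` (or a plain list of three
#'   matrices sharing rows).
#' @param K Number of components.
#' @param floor_value Replacement for structural zeros.
#' @return List with `W` (n x K) and `H` (list of three K x q_I
#'   matrices), all entries >= `floor_value`.
#' @export
nndsvd_init <- function(dataset, K, floor_value = 1e-6) {
  blocks <- if (inherits(dataset, "multiomics_dataset")) dataset$blocks
            else dataset
  Xcat <- do.call(cbind, blocks)
  res <- nndsvd(Xcat, K, floor_value)
  q <- vapply(blocks, ncol, integer(1))
  ends <- cumsum(q)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  H <- lapply(seq_along(blocks), function(i) {
    Hi <- res$H[, starts[i]:ends[i], drop = FALSE]
    dimnames(Hi) <- list(paste0("C", seq_len(K)), colnames(blocks[[i]]))
    Hi
  })
  W <- res$W
  dimnames(W) <- list(rownames(blocks[[1L]]), paste0("C", seq_len(K)))
  list(W = W, H = H)
}
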