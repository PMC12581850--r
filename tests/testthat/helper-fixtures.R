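# Shared fixtures: tiny deterministic datasets and file writers used
# across the unit tests. Everything is built in code at test time.

# A tiny valid tri-modal dataset with n samples (default 6).
toy_dataset <- function(n = 6L, q = c(3L, 4L, 2L), seed = 42L) {
  withr::with_seed(seed, {
    blocks <- lapply(seq_along(q), function(b) {
      m <- matrix(runif(n * q[b], 0.1, 2), n, q[b],
                  dimnames = list(sprintf("s%d", seq_len(n)),
                                  sprintf("b%df%d", b, seq_len(q[b]))))
      m
    })
    multiomics_dataset(blocks,
                       labels = rep_len(c(0L, 1L), n),
                       covariates = data.frame(age = runif(n, 40, 80)))
  })
}

# Write a dataset's three blocks + clinical table to a temp dir and return
# the paths, optionally permuting the sample rows of each file.
write_toy_files <- function(dataset, dir = withr::local_tempdir(.local_envir = parent.frame()),
                            permute = FALSE, seed = 7L) {
  n <- length(dataset$sample_ids)
  paths <- character(3)
  for (i in 1:3) {
    b <- dataset$blocks[[i]]
    if (permute)
      b <- b[withr::with_seed(seed + i, sample.int(n)), , drop = FALSE]
    paths[i] <- file.path(dir, sprintf("block%d.tsv", i))
    df <- cbind(id = rownames(b), as.data.frame(b))
    names(df)[1] <- ""
    write.table(df, paths[i], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  clin <- data.frame(id = dataset$sample_ids,
                     recurrence = dataset$labels,
                     age = dataset$covariates$age)
  names(clin)[1] <- ""
  clin_path <- file.path(dir, "clinical.tsv")
  write.table(clin, clin_path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(blocks = paths, clinical = clin_path)
}

# Random strictly positive factor pair for step tests.
random_factors <- function(n, q, K, seed = 1L) {
  withr::with_seed(seed, {
    W <- matrix(runif(n * K, 0.1, 1), n, K)
    H <- lapply(q, function(qi) matrix(runif(K * qi, 0.1, 1), K, qi))
    list(W = W, H = H)
  })
}

# Scalar Pearson correlation written out longhand (oracle).
pearson_oracle <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Wrap a raw symmetric matrix as a similarity-kind affinity graph.
new_affinity_similarity <- function(M) {
  structure(list(matrix = M, kind = "similarity"), class = "affinity_graph")
}

# Frobenius norm via an explicit loop-free but independent expression.
fnorm_oracle <- function(M) sqrt(sum(as.numeric(M)^2))
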