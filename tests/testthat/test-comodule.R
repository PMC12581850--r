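test_that("feature selection follows the z-score exceedance rule", {
  H <- rbind(c(0, 0, 0, 10), c(1, 1, 1, 1))
  colnames(H) <- paste0("f", 1:4)
  # mean 2.5, population sd 4.33: threshold ~9.0, only f4 exceeds
  expect_identical(select_features(H, 1L, T = 1.5), "f4")
  expect_warning(sel <- select_features(H, 2L, T = 1.5), "constant")
  expect_identical(sel, character())
  # raising T never grows the set
  Hr <- matrix(withr::with_seed(1L, runif(40)), 1, 40,
               dimnames = list("C1", paste0("f", 1:40)))
  prev <- select_features(Hr, 1L, T = 0.5)
  for (T in c(1, 1.5, 2, 3)) {
    cur <- select_features(Hr, 1L, T = T)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("clinical association finds the label-aligned component", {
  n <- 40L
  labels <- rep_len(c(0, 1), n)
  W <- cbind(labels, withr::with_seed(2L, runif(n)))
  res <- clinical_association(W, data.frame(recurrence = labels))
  tab <- res$table
  expect_equal(tab$r[tab$component == 1 & tab$variable == "recurrence"], 1,
               tolerance = 1e-12)
  expect_identical(res$selected_component, 1L)
  # sign flip of a variable flips r exactly
  res_neg <- clinical_association(W, data.frame(recurrence = -labels))
  expect_equal(res_neg$table$r, -res$table$r, tolerance = 1e-12)
})

test_that("association p-values are uniform under a permuted label null", {
  n <- 200L
  W <- withr::with_seed(3L, matrix(runif(n * 2), n, 2))
  labels <- rep_len(c(0L, 1L), n)
  ps <- vapply(1:50, function(b) {
    perm <- withr::with_seed(100L + b, sample(labels))
    res <- clinical_association(W, data.frame(recurrence = perm))
    res$table$p[1]
  }, numeric(1))
  expect_gt(mean(ps), 0.3)   # roughly uniform, not concentrated near 0
  expect_lt(mean(ps < 0.05), 0.2)
  rs <- vapply(1:50, function(b) {
    perm <- withr::with_seed(100L + b, sample(labels))
    abs(clinical_association(W, data.frame(recurrence = perm))$table$r[1])
  }, numeric(1))
  expect_lt(mean(rs), 0.1)
})

test_that("the rank-sum screen matches a scalar normal-approximation oracle", {
  x <- c(1.2, 3.4, 2.2, 5.5, 1.1)
  y <- c(0.3, 2.2, 0.9)
  X <- matrix(c(x, y), ncol = 1, dimnames = list(NULL, "f1"))
  labels <- c(rep(1L, 5), rep(0L, 3))
  got <- differential_filter(X, labels, p_thresh = 0.05)$table$p
  # oracle: ranks, U statistic, tie-corrected normal variance, two-sided z
  r <- rank(c(x, y))
  U <- sum(r[1:5]) - 5 * 6 / 2
  ties <- table(r)
  N <- 8
  sigma2 <- (5 * 3 / 12) * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- (U - 5 * 3 / 2) / sqrt(sigma2)
  expect_equal(got, 2 * pnorm(-abs(z)), tolerance = 1e-12)
})

test_that("identical group distributions survive nothing at 0.01", {
  vals <- rep(c(1, 2, 3, 4, 5), 4)
  X <- matrix(rep(vals, 5), ncol = 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  labels <- rep(c(0L, 1L), each = 10L)  # both groups see the same values
  res <- differential_filter(X, labels, p_thresh = 0.01)
  expect_length(res$selected, 0L)
  expect_true(all(res$table$p > 0.5))
})

test_that("planted location shifts are detected by the screen", {
  n1 <- 60L; n0 <- 40L; q <- 100L
  X <- withr::with_seed(4L, matrix(rnorm((n1 + n0) * q), n1 + n0, q))
  colnames(X) <- paste0("f", seq_len(q))
  labels <- c(rep(1L, n1), rep(0L, n0))
  planted <- paste0("f", 1:20)
  X[labels == 1L, 1:20] <- X[labels == 1L, 1:20] + 3
  X <- X - min(X)  # keep the block nonnegative as in real use
  res <- differential_filter(X, labels, p_thresh = 0.01)
  expect_gte(length(intersect(res$selected, planted)), 18L)
  expect_lte(length(setdiff(res$selected, planted)), 5L)
})

test_that("pairwise correlations match hand-ranked oracles", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2.3, 1.1, 5.2, 4.4, 7.8, 8.1)
  A <- cbind(fx = x); B <- cbind(fy = y)
  tab <- pairwise_correlation(A, B, method = "spearman")
  # hand-rank oracle: Pearson correlation of the rank vectors
  rho_oracle <- pearson_oracle(rank(x), rank(y))
  expect_equal(tab$r, rho_oracle, tolerance = 1e-12)
  # self-correlation and rank invariance under monotone transforms
  self <- pairwise_correlation(cbind(f = x), cbind(f = x), "pearson")
  expect_equal(self$r, 1)
  mono <- pairwise_correlation(cbind(f = exp(y)), B, "spearman")
  expect_equal(mono$r, pairwise_correlation(cbind(f = y), B, "spearman")$r,
               tolerance = 1e-12)
  # constant feature flagged as NA
  flat <- pairwise_correlation(cbind(f = rep(1, 6)), B, "pearson")
  expect_true(is.na(flat$r))
})

test_that("hypergeometric enrichment equals the exact tail-sum oracle", {
  background <- paste0("g", 1:20)
  set5 <- paste0("g", 1:5)
  selection <- c("g1", "g2", "g3", "g10")  # overlap 3 of selection 4
  col <- gene_set_collection(list(S = set5), background = background)
  res <- enrich(selection, col, background = background)
  # oracle: sum over the whole support of the hypergeometric pmf
  p_oracle <- 0
  for (j in 3:4)
    p_oracle <- p_oracle + choose(5, j) * choose(15, 4 - j) / choose(20, 4)
  expect_equal(res$p, p_oracle, tolerance = 1e-12)
  # maximal overlap is the most significant set
  col2 <- gene_set_collection(list(hit = paste0("g", 1:10),
                                   miss = paste0("g", 11:15)),
                              background = paste0("g", 1:100))
  res2 <- enrich(paste0("g", 1:10), col2)
  expect_identical(res2$set[1], "hit")
  expect_equal(res2$overlap[res2$set == "miss"], 0L, ignore_attr = TRUE)
  expect_gt(res2$p[res2$set == "miss"], 0.99)
  # empty selection yields an empty result
  expect_equal(nrow(enrich(character(), col2)), 0L)
})

test_that("the overlap ratio counts enriched-and-selected pathways", {
  expect_equal(overlap_ratio(letters[1:5], letters[1:5]), 1)
  expect_equal(overlap_ratio(letters[1:5], letters[10:12]), 0)
  expect_equal(overlap_ratio(c("a", "b", "c", "d", "e"),
                             c("a", "b", "c", "d", "x")), 0.8)
  expect_true(is.na(overlap_ratio(character(), letters[1:3])))
  # monotone non-decreasing in the significant set
  enr <- letters[1:6]
  prev <- 0
  for (m in 1:6) {
    cur <- overlap_ratio(enr, letters[1:m])
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("the rank-formulation AUC equals the all-pairs count", {
  vals <- c(3.1, 2.5, 7.7, 5.5, 6.1, 1.0, 2.2, 4.4, 0.5, 3.3)
  labels <- c(1L, 0L, 1L, 1L, 0L, 0L, 1L, 0L, 0L, 1L)
  res <- feature_auc(vals, labels)
  pos <- vals[labels == 1L]; neg <- vals[labels == 0L]
  wins <- 0
  for (p in pos) for (n in neg)
    wins <- wins + (p > n) + 0.5 * (p == n)
  expect_equal(res$auc, wins / (length(pos) * length(neg)),
               tolerance = 1e-12)
  expect_true(res$ci_lo <= res$auc && res$auc <= res$ci_hi)
  # the rank formulation agrees with the ROC-package computation
  expect_equal(res$auc,
               as.numeric(pROC::auc(labels, vals, direction = "<",
                                    levels = c(0L, 1L), quiet = TRUE)),
               tolerance = 1e-12)
  # perfectly separating feature
  sep <- feature_auc(c(1, 2, 3, 10, 11, 12), c(0L, 0L, 0L, 1L, 1L, 1L))
  expect_equal(sep$auc, 1)
  expect_error(feature_auc(1:4, c(1L, 1L, 1L, 1L)), "both classes")
})

test_that("a label-independent feature scores near-chance AUC", {
  n <- 500L
  vals <- withr::with_seed(6L, rnorm(n))
  labels <- rep_len(c(0L, 1L), n)
  res <- feature_auc(vals, labels)
  expect_lt(abs(res$auc - 0.5), 0.05)
})

test_that("co-modules recover the planted cross-modal structure", {
  sim <- generate_synthetic(synthetic_spec(seed = 301L))
  cfg <- jsnmf_config(K = 4, alpha = 0.1, beta = 0.1, max_iter = 200)
  run <- run_pipeline(sim$dataset, cfg, collection = sim$truth$collection)
  mm <- match_components(run$model$W, sim$truth$W_true)
  lc <- sim$truth$spec$label_component
  fitted_col <- mm$perm[lc]
  # the label-coupled component is the clinically selected one
  expect_identical(run$comodules$selected_component, fitted_col)
  # planted gene module recovered with high F1
  got <- run$comodules$modules[[fitted_col]]$features[[2]]
  want <- sim$truth$planted[[lc]][[2]]
  tp <- length(intersect(got, want))
  f1 <- 2 * tp / (length(got) + length(want))
  expect_gte(f1, 0.9)
  # overlap ratio against the constructed collection
  expect_gte(run$comodules$modules[[fitted_col]]$overlap_ratio, 0.8)
})
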