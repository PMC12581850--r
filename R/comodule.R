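# Co-module extraction and evaluation: per-component feature selection
# from the coefficient matrices, clinical association of the basis
# columns, rank-based differential screening, hypergeometric gene-set
# enrichment, the cross-modal overlap ratio, and ROC biomarker scoring.

#' Select features loading strongly on one component
#'
#' Z-score exceedance rule: feature j of component k is selected when
#' \eqn{H_{kj} > \mathrm{mean}(H_{k\cdot}) + T\,\mathrm{sd}(H_{k\cdot})},
#' with the population (1/n) standard deviation. A constant row yields an
#' empty set with a warning.
#'
#' @param H K x q coefficient matrix with feature ids as colnames.
#' @param k Component index.
#' @param T Threshold in standard-deviation units (default 1.5).
#' @return Character vector of selected feature ids.
#' @export
select_features <- function(H, k, T = 1.5) {
  assert_that(k >= 1 && k <= nrow(H), "component index out of range")
  assert_that(T > 0, "T must be > 0")
  row <- H[k, ]
  s <- sd_pop(row)
  if (s == 0) {
    warning(sprintf("component %d: constant coefficient row, no features selected", k), call. = FALSE)
    return(character())
  }
  sel <- row > mean(row) + T * s
  ids <- colnames(H) %||% as.character(seq_along(row))
  ids[sel]
}

#' Associate basis components with clinical variables
#'
#' Pearson correlation (with two-sided p-value) between every column of W
#' and every clinical variable; binary variables are expected coded 0/1.
#' The recurrence-associated component is the column with maximal |r|
#' against the `recurrence` variable among columns with p < 0.05 (NA when
#' none qualifies).
#'
#' @param W n x K basis matrix.
#' @param clinical Data frame of numeric variables (n rows); a
#'   `recurrence` column drives component selection when present.
#' @return List with `table` (data frame: component, variable, r, p) and
#'   `selected_component` (integer or NA).
#' @export
clinical_association <- function(W, clinical) {
  clinical <- as.data.frame(clinical)
  assert_that(nrow(clinical) == nrow(W), "clinical rows != samples in W")
  K <- ncol(W)
  rows <- list()
  for (k in seq_len(K)) {
    for (v in names(clinical)) {
      x <- W[, k]; y <- clinical[[v]]
      if (sd_pop(y) == 0 || sd_pop(x) == 0) {
        rows[[length(rows) + 1L]] <-
          data.frame(component = k, variable = v, r = NA_real_, p = NA_real_)
        next
      }
      ct <- stats::cor.test(x, y, method = "pearson")
      rows[[length(rows) + 1L]] <-
        data.frame(component = k, variable = v,
                   r = unname(ct$estimate), p = ct$p.value)
    }
  }
  tab <- do.call(rbind, rows)
  selected <- NA_integer_
  if ("recurrence" %in% names(clinical)) {
    rec <- tab[tab$variable == "recurrence" & !is.na(tab$p) & tab$p < 0.05, ]
    if (nrow(rec) > 0)
      selected <- rec$component[which.max(abs(rec$r))]
  }
  list(table = tab, selected_component = selected)
}

# Two-sided Wilcoxon rank-sum p-value by normal approximation with tie
# correction (no continuity correction), plus the U statistic.
ranksum_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  N <- n1 + n2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- (n1 * n2 / 12) * ((N + 1) - tie_term)
  if (sigma2 <= 0) return(list(U = U, p = 1))
  z <- (U - mu) / sqrt(sigma2)
  list(U = U, p = 2 * stats::pnorm(-abs(z)))
}

#' Rank-based differential screen of a feature block
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test per feature between
#' the two label groups, using the normal approximation with tie
#' correction (no continuity correction). Features with p below the
#' threshold survive; BH-adjusted q-values are reported alongside.
#'
#' @param X n x q feature block.
#' @param labels Binary vector of length n; both groups must be
#'   non-empty.
#' @param p_thresh Raw p-value threshold (0.01 default; 0.05 is common
#'   for small cohorts).
#' @return List with `table` (feature, p, q) and `selected` (feature ids
#'   with p < `p_thresh`).
#' @export
differential_filter <- function(X, labels, p_thresh = 0.01) {
  labels <- as.integer(labels)
  assert_that(all(labels %in% c(0L, 1L)), "labels must be binary 0/1")
  assert_that(any(labels == 0L) && any(labels == 1L),
              "both label groups must be non-empty")
  if (min(sum(labels == 0L), sum(labels == 1L)) < 3L)
    warning("a label group has fewer than 3 samples; normal approximation is crude", call. = FALSE)
  ids <- colnames(X) %||% as.character(seq_len(ncol(X)))
  p <- vapply(seq_len(ncol(X)), function(j)
    ranksum_test(X[labels == 1L, j], X[labels == 0L, j])$p, numeric(1))
  tab <- data.frame(feature = ids, p = p,
                    q = stats::p.adjust(p, method = "BH"))
  list(table = tab, selected = ids[p < p_thresh])
}

#' Pairwise correlations between two feature blocks
#'
#' Pearson or Spearman correlation with two-sided p-value for every pair
#' of one feature from block A and one from block B over matched samples.
#' Pairs involving a constant feature are reported as NA.
#'
#' @param A,B Numeric matrices with matched sample rows.
#' @param method `"pearson"` or `"spearman"`.
#' @param p_thresh Threshold used for the `significant` flag (default
#'   0.05).
#' @return Data frame: feature_a, feature_b, r, p, significant.
#' @export
pairwise_correlation <- function(A, B, method = c("pearson", "spearman"),
                                 p_thresh = 0.05) {
  method <- match.arg(method)
  assert_that(nrow(A) == nrow(B), "A and B must share sample rows")
  ids_a <- colnames(A) %||% as.character(seq_len(ncol(A)))
  ids_b <- colnames(B) %||% as.character(seq_len(ncol(B)))
  rows <- vector("list", ncol(A) * ncol(B))
  idx <- 0L
  for (i in seq_len(ncol(A))) {
    for (j in seq_len(ncol(B))) {
      idx <- idx + 1L
      x <- A[, i]; y <- B[, j]
      if (sd_pop(x) == 0 || sd_pop(y) == 0) {
        rows[[idx]] <- data.frame(feature_a = ids_a[i], feature_b = ids_b[j],
                                  r = NA_real_, p = NA_real_,
                                  significant = NA)
        next
      }
      ct <- suppressWarnings(stats::cor.test(x, y, method = method))
      rows[[idx]] <- data.frame(feature_a = ids_a[i], feature_b = ids_b[j],
                                r = unname(ct$estimate), p = ct$p.value,
                                significant = ct$p.value < p_thresh)
    }
  }
  do.call(rbind, rows)
}

#' Hypergeometric gene-set enrichment of a selected gene list
#'
#' One-sided hypergeometric (over-representation) p-value per gene set,
#' BH-adjusted across the collection; a set is called enriched at
#' q < 0.05.
#'
#' @param genes Character vector of selected gene ids.
#' @param collection A `gene_set_collection`.
#' @param background Optional explicit universe (default: the
#'   collection's background).
#' @param q_thresh Enrichment q-value threshold (default 0.05).
#' @return Data frame: set, set_size, overlap, p, q, enriched; empty when
#'   `genes` is empty.
#' @export
enrich <- function(genes, collection, background = NULL, q_thresh = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  background <- unique(background %||% collection$background)
  genes <- unique(genes)
  assert_that(all(genes %in% background),
              "selected genes must lie in the background universe")
  if (length(genes) == 0L)
    return(data.frame(set = character(), set_size = integer(),
                      overlap = integer(), p = numeric(), q = numeric(),
                      enriched = logical()))
  N <- length(background)
  n_sel <- length(genes)
  rows <- lapply(names(collection$sets), function(nm) {
    members <- intersect(collection$sets[[nm]], background)
    m <- length(members)
    ov <- length(intersect(genes, members))
    # P[overlap >= ov] drawing n_sel from N with m marked
    p <- stats::phyper(ov - 1L, m, N - m, n_sel, lower.tail = FALSE)
    data.frame(set = nm, set_size = m, overlap = ov, p = p)
  })
  tab <- do.call(rbind, rows)
  tab$q <- stats::p.adjust(tab$p, method = "BH")
  tab$enriched <- tab$q < q_thresh
  tab[order(tab$p), ]
}

#' Cross-modal overlap ratio of a co-module
#'
#' O = |enriched pathways that are also selected pathway-score features|
#' / |enriched pathways|. Undefined (NA) when nothing is enriched, to
#' avoid conflating "no enrichment" with "no overlap".
#'
#' @param enriched_sets Character vector of enriched gene-set names.
#' @param significant_pathways Character vector of selected
#'   pathway-score feature ids (same name space as the set names).
#' @return A scalar in \[0, 1\], or NA when `enriched_sets` is empty.
#' @export
overlap_ratio <- function(enriched_sets, significant_pathways) {
  enriched_sets <- unique(enriched_sets)
  if (length(enriched_sets) == 0L) return(NA_real_)
  length(intersect(enriched_sets, unique(significant_pathways))) /
    length(enriched_sets)
}

#' ROC AUC of a single feature against the recurrence label
#'
#' AUC via the rank (Mann-Whitney U) formulation,
#' \eqn{\mathrm{AUC} = U / (n_1 n_2)}, with a DeLong 95\% confidence
#' interval.
#'
#' @param values Numeric feature vector.
#' @param labels Binary vector (1 = positive class); both classes must be
#'   present.
#' @return List with `auc`, `ci_lo`, `ci_hi`.
#' @export
feature_auc <- function(values, labels) {
  labels <- as.integer(labels)
  assert_that(all(labels %in% c(0L, 1L)), "labels must be binary 0/1")
  assert_that(any(labels == 0L) && any(labels == 1L),
              "both classes must be present")
  pos <- values[labels == 1L]
  neg <- values[labels == 0L]
  r <- rank(c(pos, neg))
  U <- sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2
  auc <- U / (length(pos) * length(neg))
  # pROC emits an advisory warning for degenerate (AUC = 1) intervals
  ci <- suppressWarnings(suppressMessages(pROC::ci.auc(
    response = labels, predictor = values, method = "delong",
    direction = "<", levels = c(0L, 1L), quiet = TRUE)))
  list(auc = auc, ci_lo = as.numeric(ci[1L]), ci_hi = as.numeric(ci[3L]))
}

#' Extract and annotate co-modules from a fitted model
#'
#' For every component: selects features per modality by the z-score rule,
#' correlates the basis column with the clinical variables, enriches the
#' selected modality-2 (gene) features against the collection, and
#' computes the cross-modal overlap ratio against the selected modality-3
#' (pathway) features.
#'
#' @param model A `jsnmf_model`.
#' @param dataset The fitted `multiomics_dataset` (for labels and
#'   covariates).
#' @param collection Optional `gene_set_collection` for enrichment.
#' @param T Z-score selection threshold (default: the model config's
#'   `zscore_T`).
#' @return List of class `comodule_set`: `modules` (one list per
#'   component: `component`, `features` (3 id vectors), `enrichment`,
#'   `overlap_ratio`), `clinical` (the [clinical_association()] result),
#'   `selected_component`.
#' @export
extract_comodules <- function(model, dataset, collection = NULL, T = NULL) {
  stopifnot(inherits(model, "jsnmf_model"),
            inherits(dataset, "multiomics_dataset"))
  T <- T %||% model$config$zscore_T
  K <- ncol(model$W)
  assert_that(!is.null(dataset$labels),
              "dataset must carry a recurrence label for co-module selection")
  clin <- data.frame(recurrence = dataset$labels)
  if (!is.null(dataset$covariates)) clin <- cbind(clin, dataset$covariates)
  assoc <- clinical_association(model$W, clin)
  modules <- lapply(seq_len(K), function(k) {
    feats <- lapply(model$H, function(Hi) select_features(Hi, k, T))
    enr <- NULL
    ov <- NA_real_
    if (!is.null(collection) && length(feats[[2L]]) > 0L) {
      bg <- unique(c(collection$background, colnames(dataset$blocks[[2L]])))
      enr <- enrich(feats[[2L]], collection, background = bg)
      ov <- overlap_ratio(enr$set[enr$enriched], feats[[3L]])
    }
    list(component = k, features = feats, enrichment = enr,
         overlap_ratio = ov)
  })
  structure(list(modules = modules, clinical = assoc,
                 selected_component = assoc$selected_component),
            class = "comodule_set")
}

#' @export
print.comodule_set <- function(x, ...) {
  cat(sprintf("comodule_set: %d components; recurrence-selected component: %s\n",
              length(x$modules),
              ifelse(is.na(x$selected_component), "none",
                     x$selected_component)))
  for (m in x$modules) {
    sizes <- vapply(m$features, length, integer(1))
    cat(sprintf("  C%d: features %s; overlap ratio %s\n", m$component,
                paste(sizes, collapse = "/"),
                ifelse(is.na(m$overlap_ratio), "NA",
                       sprintf("%.3f", m$overlap_ratio))))
  }
  invisible(x)
}
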