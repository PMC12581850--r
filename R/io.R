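#' Construct a multi-omics dataset
#'
#' Bundles three nonnegative sample-by-feature blocks over the same samples
#' with a binary recurrence label and optional numeric covariates, and
#' enforces the container invariants: shared sample order, finiteness,
#' nonnegativity, unique feature ids, and no all-zero feature columns
#' (dropped with a warning because multiplicative updates cannot move them
#' and they break correlation metrics).
#'
#' @param blocks List of three numeric matrices (n x q_I) with rownames =
#'   sample ids and colnames = feature ids.
#' @param labels Binary vector of length n (1 = local recurrence).
#' @param covariates Optional data frame of numeric covariates, n rows.
#' @return An object of class `multiomics_dataset` with fields
#'   `sample_ids`, `blocks`, `labels`, `covariates`.
#' @export
multiomics_dataset <- function(blocks, labels = NULL, covariates = NULL) {
  assert_that(is.list(blocks) && length(blocks) == 3L,
              "blocks must be a list of three matrices")
  blocks <- lapply(blocks, function(b) {
    b <- as.matrix(b)
    storage.mode(b) <- "double"
    b
  })
  ids <- rownames(blocks[[1L]])
  assert_that(!is.null(ids), "block 1 has no sample ids (rownames)")
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    assert_that(identical(rownames(b), ids),
                "block %d sample ids differ from block 1", i)
    assert_that(!is.null(colnames(b)), "block %d has no feature ids", i)
    assert_that(!anyDuplicated(colnames(b)),
                "block %d has duplicated feature ids", i)
    assert_that(all(is.finite(b)), "block %d contains non-finite values", i)
    if (any(b < 0)) {
      neg <- which(b < 0, arr.ind = TRUE)[1L, ]
      stop(sprintf("negative value in block %d at (%s, %s)",
                   i, rownames(b)[neg[1L]], colnames(b)[neg[2L]]),
           call. = FALSE)
    }
    zero <- colSums(b) == 0
    if (any(zero)) {
      jsnmf_log("warn", "block %d: dropping %d all-zero feature column(s): %s",
                i, sum(zero), paste(utils::head(colnames(b)[zero], 5L),
                                    collapse = ", "))
      warning(sprintf("block %d: dropped %d all-zero feature column(s)",
                      i, sum(zero)), call. = FALSE)
      blocks[[i]] <- b[, !zero, drop = FALSE]
    }
  }
  n <- length(ids)
  if (!is.null(labels)) {
    assert_that(length(labels) == n, "labels length != number of samples")
    labels <- as.integer(labels)
    assert_that(all(labels %in% c(0L, 1L)), "labels must be binary 0/1")
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    assert_that(nrow(covariates) == n, "covariates rows != number of samples")
    assert_that(all(vapply(covariates, is.numeric, logical(1))),
                "covariates must be numeric")
  }
  structure(list(sample_ids = ids, blocks = blocks, labels = labels,
                 covariates = covariates),
            class = "multiomics_dataset")
}

#' @export
print.multiomics_dataset <- function(x, ...) {
  q <- vapply(x$blocks, ncol, integer(1))
  cat(sprintf("multiomics_dataset: %d samples, blocks %s\n",
              length(x$sample_ids), paste(q, collapse = " / ")))
  if (!is.null(x$labels))
    cat(sprintf("  recurrence: %d / %d positive\n", sum(x$labels),
                length(x$labels)))
  if (!is.null(x$covariates))
    cat(sprintf("  covariates: %s\n", paste(names(x$covariates), collapse = ", ")))
  invisible(x)
}

# Read one delimited sample-by-feature matrix: header = feature ids,
# first column = sample ids. Delimiter auto-detected (tab or comma).
read_block <- function(path) {
  assert_that(file.exists(path), "matrix file not found: %s", path)
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  assert_that(all(is.finite(m)), "non-finite values in %s", path)
  if (any(m < 0)) {
    neg <- which(m < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative value in %s at (%s, %s)", path,
                 rownames(m)[neg[1L]], colnames(m)[neg[2L]]), call. = FALSE)
  }
  m
}

#' Read a tri-modal dataset from delimited files
#'
#' Loads three sample-by-feature matrices and a clinical table, harmonizes
#' the sample sets (intersection, sorted id order) and validates the
#' result. The clinical table must carry a binary column named
#' `recurrence`; any further numeric columns become covariates.
#'
#' @param paths Character vector of three matrix-file paths.
#' @param clinical_path Path to the clinical table.
#' @param min_overlap Minimum fraction of each file's samples that must
#'   survive the intersection.
#' @return A [multiomics_dataset()].
#' @export
read_dataset <- function(paths, clinical_path, min_overlap = 0.5) {
  assert_that(length(paths) == 3L, "paths must list exactly three matrix files")
  blocks <- lapply(paths, read_block)
  assert_that(file.exists(clinical_path), "clinical file not found: %s",
              clinical_path)
  sep <- detect_sep(clinical_path)
  clin <- utils::read.table(clinical_path, header = TRUE, sep = sep,
                            row.names = 1L, check.names = FALSE,
                            stringsAsFactors = FALSE)
  assert_that("recurrence" %in% names(clin),
              "clinical table must contain a 'recurrence' column")
  shared <- Reduce(intersect, c(lapply(blocks, rownames), list(rownames(clin))))
  shared <- sort(shared)
  for (i in seq_along(blocks)) {
    frac <- length(shared) / nrow(blocks[[i]])
    assert_that(frac >= min_overlap,
                "sample overlap too small for %s (%.0f%% retained)",
                paths[i], 100 * frac)
  }
  blocks <- lapply(blocks, function(b) b[shared, , drop = FALSE])
  clin <- clin[shared, , drop = FALSE]
  labels <- clin[["recurrence"]]
  covars <- clin[setdiff(names(clin), "recurrence")]
  covars <- covars[vapply(covars, is.numeric, logical(1))]
  if (ncol(covars) == 0L) covars <- NULL
  multiomics_dataset(blocks, labels = labels, covariates = covars)
}

#' Write a dataset to delimited files
#'
#' Inverse of [read_dataset()]: three tab-delimited matrices plus a
#' clinical table with the `recurrence` column and any covariates.
#'
#' @param dataset A `multiomics_dataset`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named list of the written paths, invisibly.
#' @export
write_dataset <- function(dataset, dir, prefix = "block") {
  stopifnot(inherits(dataset, "multiomics_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(3)
  for (i in 1:3) {
    paths[i] <- file.path(dir, sprintf("%s%d.tsv", prefix, i))
    write_matrix(dataset$blocks[[i]], paths[i])
  }
  clin <- data.frame(recurrence = dataset$labels %||%
                       rep(NA_integer_, length(dataset$sample_ids)))
  if (!is.null(dataset$covariates)) clin <- cbind(clin, dataset$covariates)
  rownames(clin) <- dataset$sample_ids
  clin_path <- file.path(dir, "clinical.tsv")
  df <- cbind(sample_id = rownames(clin), clin)
  utils::write.table(df, clin_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(blocks = paths, clinical = clin_path))
}

# Full-precision tab-delimited matrix writer (lossless round-trip).
write_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m),
                   as.data.frame(format(m, digits = 17, trim = TRUE,
                                        scientific = TRUE)),
                   check.names = FALSE)
  names(df)[1] <- ""
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, fields `name TAB description TAB
#' member...`. Duplicate members within a line are deduplicated; duplicate
#' set names are an error.
#'
#' @param path Path to a GMT file.
#' @return A `gene_set_collection`: list with `sets` (named list of
#'   character vectors) and `background` (union of all members).
#' @export
read_gmt <- function(path) {
  assert_that(file.exists(path), "GMT file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  names_ <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    assert_that(length(fields) >= 3L,
                "GMT parse error at line %d: fewer than 3 fields", i)
    names_[i] <- fields[1L]
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    assert_that(length(members) > 0L, "GMT line %d: empty set", i)
    sets[[i]] <- members
  }
  dup <- names_[duplicated(names_)]
  assert_that(length(dup) == 0L, "duplicate gene-set name(s): %s",
              paste(unique(dup), collapse = ", "))
  names(sets) <- names_
  gene_set_collection(sets)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (set name -> member ids).
#' @param background Optional explicit universe; default is the union of
#'   all members.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, background = NULL) {
  assert_that(is.list(sets) && length(sets) > 0L && !is.null(names(sets)),
              "sets must be a non-empty named list")
  assert_that(!anyDuplicated(names(sets)), "set names must be unique")
  assert_that(all(lengths(sets) > 0L), "every set must be non-empty")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  structure(list(sets = sets,
                 background = background %||% unique(unlist(sets, use.names = FALSE))),
            class = "gene_set_collection")
}

#' Write a gene-set collection as GMT
#'
#' @param collection A `gene_set_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, "na", collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a fitted factorization model to a directory
#'
#' Writes `W.tsv`, `H1.tsv` .. `H3.tsv` as tab-delimited matrices with
#' ids, the convergence trace as `trace.tsv`, and the configuration as
#' `config.yaml`. Matrices round-trip at full double precision.
#'
#' @param model A `jsnmf_model` from [jsnmf_fit()].
#' @param trace Optional convergence-trace data frame (defaults to the
#'   trace stored in the model).
#' @param out_dir Output directory, created if needed.
#' @return Named list of written paths, invisibly.
#' @export
write_model <- function(model, trace = NULL, out_dir) {
  stopifnot(inherits(model, "jsnmf_model"))
  trace <- trace %||% model$trace
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(W = file.path(out_dir, "W.tsv"))
  write_matrix(model$W, paths$W)
  for (i in 1:3) {
    key <- sprintf("H%d", i)
    paths[[key]] <- file.path(out_dir, sprintf("%s.tsv", key))
    write_matrix(model$H[[i]], paths[[key]])
  }
  paths$trace <- file.path(out_dir, "trace.tsv")
  utils::write.table(format(trace, digits = 17, trim = TRUE,
                            scientific = TRUE),
                     paths$trace, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$config <- file.path(out_dir, "config.yaml")
  write_config(model$config, paths$config)
  if (!is.null(model$scaling)) {
    paths$scaling <- file.path(out_dir, "scaling.tsv")
    sc <- do.call(rbind, lapply(seq_along(model$scaling), function(i)
      data.frame(block = i, feature = names(model$scaling[[i]]$min),
                 min = model$scaling[[i]]$min,
                 max = model$scaling[[i]]$max)))
    utils::write.table(format(sc, digits = 17, trim = TRUE,
                              scientific = TRUE),
                       paths$scaling, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(paths)
}

#' Read a factorization model written by [write_model()]
#'
#' @param dir Directory containing `W.tsv`, `H1..3.tsv`, `trace.tsv`,
#'   `config.yaml`.
#' @return A `jsnmf_model`.
#' @export
read_model <- function(dir) {
  read_mat <- function(p) {
    df <- utils::read.table(p, header = TRUE, sep = "\t", row.names = 1L,
                            check.names = FALSE)
    m <- as.matrix(df)
    storage.mode(m) <- "double"
    m
  }
  W <- read_mat(file.path(dir, "W.tsv"))
  H <- lapply(1:3, function(i) read_mat(file.path(dir, sprintf("H%d.tsv", i))))
  trace_path <- file.path(dir, "trace.tsv")
  trace <- utils::read.table(trace_path, header = TRUE, sep = "\t")
  config <- read_config(file.path(dir, "config.yaml"))
  scaling <- NULL
  sc_path <- file.path(dir, "scaling.tsv")
  if (file.exists(sc_path)) {
    sc <- utils::read.table(sc_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    scaling <- lapply(sort(unique(sc$block)), function(i) {
      part <- sc[sc$block == i, ]
      list(min = stats::setNames(part$min, part$feature),
           max = stats::setNames(part$max, part$feature))
    })
  }
  new_jsnmf_model(W, H, config, variant = "jsnmf", trace = trace,
                  scaling = scaling)
}
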