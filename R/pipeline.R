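# Orchestration: fuse -> fit -> evaluate -> comodule as one reproducible
# run with a machine-readable manifest, plus the hyperparameter grid
# search used for model selection.

#' Run the full pipeline on a dataset
#'
#' Builds the fused affinity network and prior, fits the requested
#' factorization variant, computes reconstruction metrics, extracts
#' co-modules, and writes all artifacts (model matrices, trace, metrics,
#' co-module report, manifest) to `out_dir`. Reruns with an identical
#' configuration and inputs produce identical files.
#'
#' @param dataset A `multiomics_dataset`.
#' @param config A `jsnmf_config`.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param variant Factorization variant (default `"jsnmf"`).
#' @param collection Optional `gene_set_collection` for enrichment.
#' @return List of class `jsnmf_run`: `prior` (the [build_prior()]
#'   result), `model`, `metrics`, `comodules`, `manifest`.
#' @export
run_pipeline <- function(dataset, config = jsnmf_config(), out_dir = NULL,
                         variant = "jsnmf", collection = NULL) {
  stopifnot(inherits(dataset, "multiomics_dataset"),
            inherits(config, "jsnmf_config"))
  stage <- "fuse"
  result <- tryCatch({
    prior <- build_prior(dataset, config)
    stage <- "fit"
    model <- jsnmf_fit(dataset, prior$prior, config, variant)
    stage <- "evaluate"
    metrics <- reconstruction_metrics(dataset, model, seed = config$seed)
    stage <- "comodule"
    comodules <- if (!is.null(dataset$labels))
      extract_comodules(model, dataset, collection) else NULL
    list(prior = prior, model = model, metrics = metrics,
         comodules = comodules)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  manifest <- list(
    package_version = as.character(utils::packageVersion("jsnmf")),
    config = unclass(config), variant = variant,
    seed = config$seed,
    n_samples = length(dataset$sample_ids),
    block_widths = vapply(dataset$blocks, ncol, integer(1)),
    spectral_agreement = if (!is.null(result$prior$spectral))
      result$prior$spectral$agreement else NULL,
    relative_error = result$metrics$relative_error,
    euclidean_distance = result$metrics$euclidean_distance,
    selected_component = if (!is.null(result$comodules))
      result$comodules$selected_component else NULL,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  result$manifest <- manifest
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_model(result$model, out_dir = out_dir)
    write_matrix(result$prior$prior$matrix, file.path(out_dir, "prior.tsv"))
    write_matrix(result$prior$fused$matrix, file.path(out_dir, "fused.tsv"))
    utils::write.table(result$metrics$sample_cor,
                       file.path(out_dir, "sample_cor.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(result$comodules))
      write_comodule_report(result$comodules, out_dir)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  class(result) <- "jsnmf_run"
  result
}

write_comodule_report <- function(comodules, out_dir) {
  utils::write.table(comodules$clinical$table,
                     file.path(out_dir, "clinical_association.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  feat_rows <- do.call(rbind, lapply(comodules$modules, function(m) {
    do.call(rbind, lapply(1:3, function(b) {
      if (length(m$features[[b]]) == 0L) return(NULL)
      data.frame(component = m$component, block = b,
                 feature = m$features[[b]])
    }))
  }))
  if (is.null(feat_rows))
    feat_rows <- data.frame(component = integer(), block = integer(),
                            feature = character())
  utils::write.table(feat_rows, file.path(out_dir, "selected_features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  enr_rows <- do.call(rbind, lapply(comodules$modules, function(m) {
    if (is.null(m$enrichment) || nrow(m$enrichment) == 0L) return(NULL)
    cbind(component = m$component, m$enrichment)
  }))
  if (!is.null(enr_rows))
    utils::write.table(enr_rows, file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    selected_component = comodules$selected_component,
    overlap_ratio = lapply(comodules$modules, function(m)
      if (is.na(m$overlap_ratio)) NULL else m$overlap_ratio))
  jsonlite::write_json(summary, file.path(out_dir, "comodules.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(NULL)
}

#' Hyperparameter grid search by relative error
#'
#' Fits the model for every combination of the supplied K, alpha and beta
#' grids (defaults: K in \{5, 10, 15, 20\}, alpha and beta in
#' \{0.01, 0.1, 1, 10\}, i.e. 64 combinations) and selects the
#' combination minimizing the relative reconstruction error. Ties are
#' broken by smaller K, then smaller alpha, then smaller beta.
#'
#' @param dataset A `multiomics_dataset`.
#' @param K_grid,alpha_grid,beta_grid Numeric grids.
#' @param config Base configuration; K/alpha/beta are overridden per
#'   combination.
#' @param variant Factorization variant.
#' @return List with `summary` (data frame: K, alpha, beta,
#'   relative_error, objective, iterations), `best` (the argmin row), and
#'   `best_model`.
#' @export
grid_search <- function(dataset, K_grid = c(5, 10, 15, 20),
                        alpha_grid = c(0.01, 0.1, 1, 10),
                        beta_grid = c(0.01, 0.1, 1, 10),
                        config = jsnmf_config(), variant = "jsnmf") {
  stopifnot(inherits(dataset, "multiomics_dataset"))
  grid <- expand.grid(K = K_grid, alpha = alpha_grid, beta = beta_grid,
                      KEEP.OUT.ATTRS = FALSE)
  # deterministic tie-break order: K, then alpha, then beta
  grid <- grid[order(grid$K, grid$alpha, grid$beta), , drop = FALSE]
  priors <- new.env(parent = emptyenv())
  rows <- vector("list", nrow(grid))
  models <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- config
    cfg$K <- as.integer(grid$K[i])
    cfg$alpha <- grid$alpha[i]
    cfg$beta <- grid$beta[i]
    key <- as.character(cfg$K)
    if (is.null(priors[[key]]))
      priors[[key]] <- build_prior(dataset, cfg)$prior
    model <- jsnmf_fit(dataset, priors[[key]], cfg, variant)
    re <- model$trace$relative_error[nrow(model$trace)]
    rows[[i]] <- data.frame(K = cfg$K, alpha = cfg$alpha, beta = cfg$beta,
                            relative_error = re,
                            objective = model$trace$objective[nrow(model$trace)],
                            iterations = nrow(model$trace))
    models[[i]] <- model
    jsnmf_log("debug", "grid %d/%d: K=%d alpha=%g beta=%g -> rel.err %.4f",
              i, nrow(grid), cfg$K, cfg$alpha, cfg$beta, re)
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  # stable order + which.min give the smallest-K/alpha/beta argmin on ties
  best_idx <- which.min(summary$relative_error)
  list(summary = summary, best = summary[best_idx, ],
       best_model = models[[best_idx]])
}
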