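#' Reference sensitivity values of the published network
#'
#' The twelve relative-importance percentages reported for the published
#' MLP 6-10-16 cheese-quality network, used by
#' [reproduce_published_sensitivity()] to check the bundled weight fixture.
#'
#' @return data.frame with columns `output`, `input`, `RI_published`.
#' @export
published_ri_values <- function() {
  data.frame(
    output = c("DM", "pH", "Fat", "ProteinsDM", "aw", "Fat",
               "TP", "ABTS", "DPPH", "FRAP", "Aerobic", "Lactic"),
    input = c("day", "day", "day", "herb_salvia", "herb_salvia", "herb_thyme",
              "day", "day", "day", "day", "day", "day"),
    RI_published = c(64.98, -39.70, -22.41, -20.78, 18.78, 22.24,
                     51.97, 37.76, -29.44, -64.46, -66.98, -46.61),
    stringsAsFactors = FALSE)
}

#' Recompute the published sensitivity surface
#'
#' Loads the bundled published weight fixture, runs Yoon's connection-weight
#' analysis, and diffs the result against the published relative-importance
#' values ([published_ri_values()]).
#'
#' @param tolerance Agreement threshold in percentage points (default 0.1).
#' @return data.frame: output, input, published and computed RI, difference,
#'   and an `agree` flag.
#' @export
reproduce_published_sensitivity <- function(tolerance = 0.1) {
  ri <- yoon_relative_importance(load_printed_weights())
  ref <- published_ri_values()
  ref$RI_computed <- ri[cbind(ref$output, ref$input)]
  ref$difference <- ref$RI_computed - ref$RI_published
  ref$agree <- abs(ref$difference) <= tolerance
  ref
}

#' Run the full analysis pipeline
#'
#' Orchestrates the end-to-end workflow: obtain data (a response-table CSV
#' or the synthetic generator), standardize, split, obtain a model (train,
#' the published fixture, or a weight file), then emit the goodness-of-fit
#' table, the sensitivity table, correlation/PCA/cluster exports and the
#' Pareto front into `out_dir`, together with a JSON manifest recording
#' seeds, the files written and their MD5 hashes. Rerunning the same
#' configuration reproduces every output bit-identically.
#'
#' @param data Either a path to a response-table CSV or a
#'   [synthetic_config()].
#' @param weights `"train"` (fit a new network), `"printed"` (the published
#'   fixture), or a path to a weight-set JSON.
#' @param out_dir Output directory (created if missing).
#' @param split_seed,split_fractions Data-split parameters.
#' @param hidden_range,restarts Architecture-search parameters (used when
#'   `weights = "train"`).
#' @param objective An [objective_config()] for the optimization stage.
#' @param moo_method `"exhaustive"` or `"ga"`.
#' @param seed Master seed for training and GA stages.
#' @param chi2_params Parameter count for the reduced chi-square column of
#'   the metrics table. Defaults to 0 (plain mean squared error): a fitted
#'   network typically has more free parameters than the study has
#'   observations, which would make `SSE/(N-n)` undefined. Set it to
#'   [n_parameters()] of the model when `N` is large enough.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(data, weights = "train", out_dir,
                         split_seed = 1L,
                         split_fractions = c(0.70, 0.15, 0.15),
                         hidden_range = 5:10, restarts = 5L,
                         objective = objective_config(),
                         moo_method = "exhaustive", seed = 1L,
                         chi2_params = 0L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(writer, obj, name) {
    path <- file.path(out_dir, name)
    writer(obj, path)
    files <<- c(files, path)
    path
  }

  ## -- data stage
  if (inherits(data, "synthetic_config")) {
    ds <- generate_synthetic(data)
  } else if (is.character(data) && length(data) == 1) {
    if (!file.exists(data)) stop("run_pipeline [data]: no such file: ", data)
    ds <- read_response_table(data)
  } else stop("run_pipeline [data]: 'data' must be a file path or a ",
              "synthetic_config")
  path_data <- file.path(out_dir, "dataset.csv")
  write_response_table(ds$design, ds$responses, path_data)
  files <- c(files, path_data)

  X_raw <- encode_design(ds$design)
  in_std <- fit_standardizer(X_raw[, "day", drop = FALSE], "zscore")
  X <- X_raw
  X[, "day"] <- standardize(in_std, X_raw[, "day", drop = FALSE])
  out_std <- fit_standardizer(ds$responses, "minmax")
  Ys <- standardize(out_std, ds$responses)
  split <- split_data(nrow(X), split_fractions, split_seed)

  ## -- model stage
  trained <- FALSE
  if (identical(weights, "printed")) {
    ws <- load_printed_weights()
  } else if (identical(weights, "train")) {
    search <- architecture_search(X, Ys, hidden_range = hidden_range,
                                  restarts = restarts, split = split,
                                  seed = seed)
    ws <- search$best$weights
    trained <- TRUE
    emit(function(o, p) utils::write.csv(o, p, row.names = FALSE),
         search$table, "architecture_search.csv")
  } else if (is.character(weights) && file.exists(weights)) {
    ws <- read_weight_set(weights)
  } else stop("run_pipeline [model]: 'weights' must be \"train\", ",
              "\"printed\", or an existing weight file")
  emit(write_weight_set, ws, "weights.json")

  ## -- goodness of fit (only meaningful when the model matches the data)
  if (trained) {
    Yhat <- destandardize(out_std, mlp_forward(ws, X))
    emit(write_metrics_table,
         metrics_table(ds$responses, Yhat, chi2_params), "metrics.csv")
  }

  ## -- sensitivity
  ri <- yoon_relative_importance(ws)
  emit(write_ri_table, ri, "relative_importance.csv")

  ## -- chemometrics
  corr <- correlation_analysis(ds$responses)
  emit(function(o, p) utils::write.csv(o, p), corr$r, "correlation_r.csv")
  emit(function(o, p) utils::write.csv(o, p), corr$p, "correlation_p.csv")
  pca <- pca_responses(ds$responses)
  emit(function(o, p) utils::write.csv(o, p), pca$scores, "pca_scores.csv")
  emit(function(o, p) utils::write.csv(o, p), pca$loadings, "pca_loadings.csv")
  emit(function(o, p) utils::write.csv(o, p), pca$contributions,
       "pca_contributions.csv")
  emit(function(o, p) utils::write.csv(data.frame(
    component = seq_along(pca$explained), explained_pct = pca$explained), p,
    row.names = FALSE), NULL, "pca_explained.csv")
  tree <- hierarchical_cluster(ds$responses)
  emit(write_cluster_tree, tree, "cluster_tree.json")

  ## -- optimization (trained models predict on physical scale via the
  ##    fitted standardizers; the printed fixture stays on model scale)
  moo <- optimize_formulation(
    ws, objective, method = moo_method, seed = seed,
    standardizer = if (trained) out_std else NULL,
    input_standardizer = if (trained) in_std else NULL)
  emit(write_pareto, moo, "pareto_front.csv")

  manifest <- list(
    seeds = list(split = split_seed, model = seed,
                 data = if (inherits(data, "synthetic_config")) data$seed),
    weights_source = if (is.character(weights)) weights else "train",
    moo_method = moo_method,
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
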