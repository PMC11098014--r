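#' Configuration for the end-to-end pipeline
#'
#' @param output_dir Directory for artifacts (created if needed).
#' @param registry \code{"default"} (17 features) or \code{"augmented"}
#'   (20, adding the autocorrelation rhythm features).
#' @param smoothing A [smoothing_config()].
#' @param advanced_test_fraction Passed to [split_advanced_test()].
#' @param train A [train_config()].
#' @param importance_instances Rows explained by Shapley in the analysis
#'   stage.
#' @param seed Root seed; all stage seeds derive from it.
#' @return Object of class \code{run_config}.
#' @export
run_config <- function(output_dir = "dancekin_run",
                       registry = c("default", "augmented"),
                       smoothing = smoothing_config(),
                       advanced_test_fraction = 0.52,
                       train = NULL, importance_instances = 10L,
                       seed = 1L) {
  registry <- match.arg(registry)
  seed <- as.integer(seed)
  if (is.null(train)) train <- train_config(seed = seed)
  structure(list(output_dir = output_dir, registry = registry,
                 smoothing = smoothing,
                 advanced_test_fraction = advanced_test_fraction,
                 train = train,
                 importance_instances = as.integer(importance_instances),
                 seed = seed),
            class = "run_config")
}

# Hash of the analytical configuration (the output path does not alter
# what is computed, so it is excluded).
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$output_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, force = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage failure (", stage, "): ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full genre-classification pipeline
#'
#' Extract features, split into a basic-heavy training set and an
#' advanced-only test set, train the linear baselines and the weighted
#' ensemble, evaluate on the test set, and run the post-hoc analyses
#' (genre similarity embedding, Shapley importance, per-genre
#' fingerprints). Artifacts -- the feature table CSV and a JSON report
#' embedding the config and its hash -- are written to
#' \code{config$output_dir}. Given the same data and seed the report is
#' byte-identical across reruns.
#'
#' @param data A labelled [pose_dataset()] with basic/advanced tiers.
#' @param config A [run_config()].
#' @return Invisibly, a list with the feature matrix, split, fitted
#'   models, reports, and analysis results.
#' @export
run_pipeline <- function(data, config = run_config()) {
  registry <- feature_registry(augmented = config$registry == "augmented")
  hash <- config_hash(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  fm <- run_stage("extract",
                  extract_feature_matrix(data, registry, config$smoothing))
  sp <- run_stage("split",
                  split_advanced_test(data, config$advanced_test_fraction,
                                      seed = config$seed))
  ids <- function(ds) vapply(ds$sequences, `[[`, "", "sequence_id")
  subset_fm <- function(which_ids) {
    out <- fm[match(which_ids, fm$sequence_id), , drop = FALSE]
    attr(out, "registry") <- registry
    class(out) <- class(fm)
    out
  }
  train_fm <- subset_fm(ids(sp$train))
  test_fm <- subset_fm(ids(sp$test))

  models <- run_stage("train", list(
    ensemble = automl_fit(train_fm, config$train),
    ridge = train_baseline(train_fm, "ridge", seed = config$seed),
    perceptron = train_baseline(train_fm, "perceptron", seed = config$seed)
  ))
  reports <- run_stage("evaluate",
                       lapply(models, evaluate_model, test = test_fm))

  analysis <- run_stage("analyze", {
    k <- min(3L, length(unique(labels_of(fm))) - 1L)
    emb <- lsa_embed(genre_mean_table(fm), k = k)
    imp <- feature_importance(models$ensemble, test_fm, method = "shapley",
                              background = train_fm,
                              n_instances = config$importance_instances,
                              exact = FALSE, n_perm = 25L,
                              seed = config$seed)
    fps <- lapply(sort(unique(labels_of(fm))),
                  function(g) genre_fingerprint(fm, g))
    names(fps) <- sort(unique(labels_of(fm)))
    list(embedding = emb, importance = imp, fingerprints = fps)
  })

  write_feature_table(fm, file.path(config$output_dir, "features.csv"))
  report <- list(
    config = config, config_hash = hash, seed = config$seed,
    n_sequences = length(data$sequences),
    n_train = nrow(train_fm), n_test = nrow(test_fm),
    accuracy = lapply(reports, `[[`, "accuracy"),
    per_class = lapply(reports, `[[`, "per_class"),
    confusion = lapply(reports, function(r) as.data.frame(r$confusion)),
    embedding_coordinates = as.data.frame(analysis$embedding$coordinates),
    singular_values = analysis$embedding$singular_values,
    global_importance = as.list(analysis$importance$global)
  )
  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, force = TRUE,
                              digits = NA, pretty = TRUE),
             file.path(config$output_dir, "report.json"))

  invisible(list(features = fm, split = sp, models = models,
                 reports = reports, analysis = analysis,
                 config = config, config_hash = hash))
}
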