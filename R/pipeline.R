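#' Pipeline configuration
#'
#' Bundles every stage's tunables with the package defaults. The resolved
#' configuration is written beside the outputs of every run.
#'
#' @param feature A [feature_config()].
#' @param selection_ntree,selection_repeats Forest size and repeats for
#'   [select_variables()].
#' @param do_selection Run variable selection before training (default
#'   TRUE). When TRUE, selection runs once on the full dataset before
#'   cross-validation (the protocol used with the reference confusion
#'   matrices); set \code{selection_in_fold = TRUE} for the unbiased
#'   variant that reselects inside every training fold.
#' @param selection_in_fold See \code{do_selection}.
#' @param C_grid,gamma_grid,grid_folds Hyperparameter grid, see
#'   [grid_search_svm()].
#' @param n_members,split,mode Committee parameters, see [train_gsvn()].
#' @param k Cross-validation folds (default 10).
#' @param seed Global seed.
#' @return A \code{run_config} list.
#' @export
run_config <- function(feature = feature_config(),
                       selection_ntree = 2000L, selection_repeats = 5L,
                       do_selection = TRUE, selection_in_fold = FALSE,
                       C_grid = c(1, 3, 33), gamma_grid = seq(0.1, 5, by = 0.1),
                       grid_folds = 5L, n_members = 300L, split = 0.8,
                       mode = "boost", k = 10L, seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

read_manifest <- function(manifest) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest)
  stopifnot(all(c("file", "label") %in% names(manifest)))
  manifest
}

#' Run the full classification pipeline
#'
#' End-to-end orchestration: read every WAV named in the manifest, extract
#' the twelve-feature representation, select discriminative feature
#' families with random forests, grid-search the shared SVM
#' hyperparameters, and evaluate the grouped-support-vector network with
#' stratified k-fold cross-validation. Artifacts (feature CSV, selection
#' JSON, evaluation JSON, resolved config JSON) are written to
#' \code{out_dir} when given.
#'
#' @param manifest data.frame (or CSV path) with columns \code{file},
#'   \code{label} and optionally \code{sex}.
#' @param config A [run_config()].
#' @param out_dir Optional output directory.
#' @param verbose Log stage progress to stderr (default TRUE).
#' @return List with \code{features}, \code{selection}, \code{grid},
#'   \code{report} (an \code{eval_report}).
#' @export
run_pipeline <- function(manifest, config = run_config(), out_dir = NULL,
                         verbose = TRUE) {
  manifest <- read_manifest(manifest)
  say <- function(...) if (verbose) message(sprintf(...))
  if (length(unique(manifest$label)) < 2L) {
    stop("run_pipeline: stage 'extract': manifest holds fewer than 2 classes")
  }
  say("stage extract: %d clips", nrow(manifest))
  clips <- lapply(seq_len(nrow(manifest)), function(i) {
    read_wav(manifest$file[i], label = manifest$label[i])
  })
  features <- extract_features_all(clips, config$feature)
  if ("sex" %in% names(manifest)) features$sex <- manifest$sex[features$clip]

  selection <- NULL
  reduced <- features
  if (config$do_selection && !config$selection_in_fold) {
    say("stage select: ntree=%d", config$selection_ntree)
    selection <- select_variables(features, ntree = config$selection_ntree,
                                  n_repeats = config$selection_repeats,
                                  seed = config$seed)
    if (length(selection$interpretation_set) > 0L) {
      reduced <- apply_selection(features, selection)
    }
  }
  say("stage grid_search: %d points", length(config$C_grid) * length(config$gamma_grid))
  grid <- grid_search_svm(reduced, config$C_grid, config$gamma_grid,
                          folds = config$grid_folds, seed = config$seed)
  say("stage evaluate: k=%d, members=%d, C=%g gamma=%g",
      config$k, config$n_members, grid$C, grid$gamma)
  group <- if ("sex" %in% names(reduced)) reduced$sex else NULL
  report <- kfold_cv(reduced, k = config$k, n_members = config$n_members,
                     C = grid$C, gamma = grid$gamma, split = config$split,
                     mode = config$mode, seed = config$seed, group = group)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(features, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    if (!is.null(selection)) {
      jsonlite::write_json(
        list(importances = as.list(selection$importances),
             ranking = selection$ranking,
             threshold_kept = selection$threshold_kept,
             interpretation_set = selection$interpretation_set,
             oob_errors = as.list(selection$oob_errors),
             ntree = selection$ntree, seed = selection$seed),
        file.path(out_dir, "selection.json"), auto_unbox = TRUE, digits = NA)
    }
    jsonlite::write_json(
      list(k = report$k, seed = report$seed,
           mean_accuracy = report$mean_accuracy,
           per_class_accuracy = as.list(report$per_class_accuracy),
           confusion = unclass(report$confusion),
           macro_auc = report$roc$macro_auc,
           grid = list(C = grid$C, gamma = grid$gamma, accuracy = grid$accuracy)),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    cfg_out <- config
    cfg_out$feature <- unclass(cfg_out$feature)
    jsonlite::write_json(unclass(cfg_out), file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(features = features, selection = selection, grid = grid, report = report)
}
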