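# End-to-end orchestration: simulate -> preprocess -> select -> bench ->
# explain, under one config and one root seed, with a run manifest.

#' Run the full analysis pipeline
#'
#' Executes all stages in order: cohort generation, preprocessing (encode,
#' zero-impute, stratified split, train-fitted scaling, SMOTE), the
#' seven-method consensus feature ranking (on the balanced training
#' matrix), the classification benchmark on the top-k consensus features,
#' and Kernel SHAP attribution of the best model. Artifacts are optionally
#' written to `out_dir`; a manifest (config echo, per-stage counts,
#' leaderboard, file checksums) is assembled last.
#'
#' @param cfg a [gdm_config()]; its root seed fans out to named per-stage
#'   substreams.
#' @param models benchmark subset (default: all eleven).
#' @param k_top consensus features kept for modelling (default 10).
#' @param cv_folds stratified CV folds for grid search (default 10).
#' @param n_background,n_explain,explain_counts attribution sampling sizes.
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @return list of class `gdm_run`: `cohort`, `prep`, `consensus`,
#'   `selected_features`, `bench`, `attributions`, `manifest`.
#' @export
run_gdm_pipeline <- function(cfg = gdm_config(), models = MODEL_NAMES,
                             k_top = 10, cv_folds = 10,
                             n_background = 100,
                             explain_counts = c(positive = 33, negative = 17),
                             out_dir = NULL) {
  t0 <- Sys.time()
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s: %s", format(round(difftime(Sys.time(), t0,
                                                         units = "secs"))),
                    stage, paste0(...)))
  }

  cohort <- generate_cohort(cfg)
  log_stage("simulate", nrow(cohort), " records, ",
            round(100 * mean(cohort$gdm), 1), "% GDM-positive")

  prep <- preprocess_cohort(cohort,
                            split_seed = stage_seed(cfg$seed, "split"),
                            smote_seed = stage_seed(cfg$seed, "smote"))
  log_stage("preprocess", "train ", length(prep$split$idx_train), " / test ",
            length(prep$split$idx_test), "; balanced train ",
            nrow(prep$train_x))

  vectors <- importance_ensemble(prep$train_x, prep$train_y,
                                 seed = stage_seed(cfg$seed, "select"))
  consensus <- consensus_rank(vectors)
  selected <- select_top_k(consensus, min(k_top, nrow(consensus)))
  log_stage("select", "top features: ", paste(utils::head(selected, 3),
                                              collapse = ", "), ", ...")

  bench <- run_benchmark(prep$train_x[, selected, drop = FALSE], prep$train_y,
                         prep$test_x[, selected, drop = FALSE], prep$test_y,
                         models = models, cv_folds = cv_folds,
                         seed = stage_seed(cfg$seed, "bench"))
  best_name <- bench$leaderboard$model[1]
  log_stage("bench", "best model ", best_name, " (weighted F1 ",
            round(bench$leaderboard$f1[1], 4), ")")

  sets <- sample_explain_sets(prep$test_x[, selected, drop = FALSE],
                              prep$test_y, n_background = n_background,
                              class_counts = explain_counts,
                              seed = stage_seed(cfg$seed, "explain"))
  attributions <- attribute(bench$fits[[best_name]]$model, sets$background,
                            sets$explain_x, seed = stage_seed(cfg$seed, "shap"))
  log_stage("explain", length(sets$explain_idx), " instances attributed")

  manifest <- list(
    config = unclass(cfg),
    stage_seeds = sapply(c("demographics", "risk_factors", "labs", "outcome",
                           "split", "smote", "select", "bench", "explain"),
                         function(s) stage_seed(cfg$seed, s)),
    counts = list(n = nrow(cohort),
                  gdm_positive = sum(cohort$gdm),
                  train = as.list(prep$counts$train),
                  test = as.list(prep$counts$test),
                  train_balanced = as.list(prep$counts$train_balanced)),
    selected_features = selected,
    leaderboard = bench$leaderboard,
    best_model = best_name
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(out_dir, "cohort.csv"), cfg)
    utils::write.csv(consensus, file.path(out_dir, "consensus.csv"),
                     row.names = FALSE)
    utils::write.csv(bench$leaderboard, file.path(out_dir, "leaderboard.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(attributions$matrix),
                     file.path(out_dir, "attributions.csv"), row.names = FALSE)
    files <- list.files(out_dir, full.names = TRUE)
    manifest$checksums <- as.list(tools::md5sum(files))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  structure(list(cohort = cohort, prep = prep, consensus = consensus,
                 selected_features = selected, bench = bench,
                 attributions = attributions, manifest = manifest),
            class = "gdm_run")
}
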