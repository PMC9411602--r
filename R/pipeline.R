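#' Configuration for an end-to-end pipeline run
#'
#' Bundles every stage's settings behind one object with a single global
#' seed.  Per-stage seeds are derived from the global seed by a fixed
#' affine hash (`stage_seed()`), so any stage can be rerun in isolation
#' reproducibly.
#'
#' @param seed Global integer seed.
#' @param out_dir Output directory (created if needed); `NULL` runs the
#'   pipeline in memory without writing artifacts.
#' @param n_ckd,n_nockd,n_probable Synthetic cohort sizes.
#' @param catalog Analyte catalog.
#' @param rules Labeling rules.
#' @param filter Filter configuration.
#' @param train_fraction Training fraction of the labeled cohort.
#' @param augment Augmentation configuration.
#' @param imputer_method,imputer_trees Imputer settings (see
#'   [imputer_config()]).
#' @param features Model feature names.
#' @param hidden_layers,dropout,epochs,learning_rate,batch_size Network
#'   settings (see [net_config()]).
#' @param prevalence Population prevalence for PPV/NPV.
#' @param horizons Horizon grid in years.
#' @param t0_window_years Eligibility window around T0 for evaluation.
#' @param impute_before_split Fit the imputer on the full labeled cohort
#'   before splitting (the leakier historical convention) instead of on
#'   the training partition only.
#' @return A `run_config` list.
#' @export
run_config <- function(seed, out_dir = NULL,
                       n_ckd = 500, n_nockd = 500, n_probable = 50,
                       catalog = default_catalog(),
                       rules = labeling_rules(),
                       filter = filter_config(),
                       train_fraction = 0.67,
                       augment = augment_config(),
                       imputer_method = "rf", imputer_trees = 50,
                       features = default_features(),
                       hidden_layers = c(5, 3, 3), dropout = 0.2,
                       epochs = 8, learning_rate = 1e-3, batch_size = 1,
                       prevalence = default_prevalence(),
                       horizons = seq(0, 3.5, by = 0.5),
                       t0_window_years = 0.25,
                       impute_before_split = FALSE) {
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 n_ckd = n_ckd, n_nockd = n_nockd, n_probable = n_probable,
                 catalog = catalog, rules = rules, filter = filter,
                 train_fraction = train_fraction, augment = augment,
                 imputer_method = imputer_method,
                 imputer_trees = imputer_trees, features = features,
                 hidden_layers = hidden_layers, dropout = dropout,
                 epochs = epochs, learning_rate = learning_rate,
                 batch_size = batch_size, prevalence = prevalence,
                 horizons = horizons, t0_window_years = t0_window_years,
                 impute_before_split = impute_before_split),
            class = "run_config")
}

#' @rdname run_config
#' @param stage Stage index (1-based).
#' @export
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + stage * 104729) %% 2147483647)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  strip <- config
  strip$out_dir <- NULL
  jsonlite::write_json(jsonlite::serializeJSON(strip), tmp)
  unname(tools::md5sum(tmp))
}

pipeline_log <- function(stage, msg, ...) {
  message(sprintf("[%s] %s", stage, sprintf(msg, ...)))
}

#' Run the full study replica
#'
#' Executes simulate, label, mask, trim, filter, split, impute, augment,
#' train and evaluate in order, reconciling record counts at every stage
#' (the funnel) in a run manifest.  `PROBABLE_CKD` records are labeled and
#' counted but excluded from training and from sensitivity/specificity.
#' Reports are written under `config$out_dir` when set.  Rerunning with
#' the same configuration reproduces the reports exactly.
#'
#' @param config A `run_config`.
#' @return (Invisibly) a list with the trained net, the evaluation tables,
#'   the manifest, and the intermediate cohorts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  catalog <- config$catalog
  manifest <- list(config_hash = config_hash(config),
                   global_seed = config$seed,
                   stage_seeds = vapply(1:4, function(i) {
                     stage_seed(config$seed, i)
                   }, numeric(1)))

  pipeline_log("simulate", "generating %d CKD + %d no-CKD + %d probable",
               config$n_ckd, config$n_nockd, config$n_probable)
  spec <- cohort_spec(config$n_ckd, config$n_nockd, config$n_probable,
                      seed = stage_seed(config$seed, 1), catalog = catalog)
  sim <- simulate_cohort(spec)
  manifest$n_simulated <- length(sim$records)

  labeled <- label_cohort(sim$records, catalog, config$rules)
  statuses <- vapply(labeled, function(r) r$status, character(1))
  manifest$labeled_counts <- as.list(table(statuses))
  modelable <- labeled[statuses %in% c("CKD", "NO_CKD")]
  pipeline_log("label", "statuses: %s",
               paste(names(table(statuses)), table(statuses),
                     sep = "=", collapse = ", "))

  sds <- population_sds(modelable, catalog)
  masked <- mask_outliers(modelable, catalog, sds, config$filter)
  manifest$n_outliers_masked <- attr(masked, "n_masked")
  trimmed <- lapply(masked, drop_lab_free_visits, catalog = catalog)

  filt <- filter_eligible(trimmed, catalog, config$filter)
  manifest$n_eligible <- length(filt$kept)
  manifest$n_rejected <- nrow(filt$rejected)
  pipeline_log("filter", "kept %d, rejected %d", length(filt$kept),
               nrow(filt$rejected))
  if (length(filt$kept) < 4) stop("stage filter: too few eligible records")

  split <- split_train_test(filt$kept,
                            split_config(config$train_fraction,
                                         seed = stage_seed(config$seed, 2)))
  manifest$n_train <- length(split$train)
  manifest$n_test <- length(split$test)

  icfg <- imputer_config(trees = config$imputer_trees,
                         seed = stage_seed(config$seed, 3),
                         method = config$imputer_method)
  fit_on <- if (config$impute_before_split) filt$kept else split$train
  imp <- fit_imputer(visit_matrix(fit_on, catalog), icfg)
  manifest$imputer_iterations <- imp$iterations
  train_i <- impute_missing(split$train, imp, catalog)
  test_i <- impute_missing(split$test, imp, catalog)
  pipeline_log("impute", "converged in %d sweep(s)", imp$iterations)

  aug <- augment_truncations(train_i, config$augment)
  manifest$n_train_augmented <- length(aug)

  scaler <- fit_feature_scaler(train_i, config$features)
  samples <- build_sequences(aug, scaler)
  ncfg <- net_config(hidden_layers = config$hidden_layers,
                     dropout = config$dropout, epochs = config$epochs,
                     learning_rate = config$learning_rate,
                     batch_size = config$batch_size,
                     seed = stage_seed(config$seed, 4))
  pipeline_log("train", "training on %d sequences (%d original records)",
               length(samples), length(train_i))
  net <- train_rnn(samples, ncfg, scaler)

  t0_summary <- evaluate_at_t0(net, test_i, config$t0_window_years,
                               config$prevalence)
  horizon <- horizon_evaluation(net, test_i, config$horizons,
                                config$prevalence, config$t0_window_years)
  by_stage <- stratified_report(net, test_i, "life-stage",
                                config$prevalence, config$t0_window_years)
  by_visits <- stratified_report(net, test_i, "visit-count",
                                 config$prevalence, config$t0_window_years)
  manifest$n_eval_eligible <- t0_summary$n_pos + t0_summary$n_neg
  manifest$funnel_balanced <-
    manifest$n_eligible + manifest$n_rejected ==
      sum(statuses %in% c("CKD", "NO_CKD")) &&
    manifest$n_train + manifest$n_test == manifest$n_eligible

  out <- list(net = net, imputer = imp, t0_summary = t0_summary,
              horizon = horizon, by_life_stage = by_stage,
              by_visit_count = by_visits, manifest = manifest,
              truth = sim$truth, labeled = labeled,
              train = train_i, test = test_i)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(df, name) {
      readr::write_csv(df, file.path(config$out_dir, name), na = "")
    }
    w(t0_summary, "t0_summary.csv")
    w(horizon, "horizon_table.csv")
    w(by_stage, "by_life_stage.csv")
    w(by_visits, "by_visit_count.csv")
    save_net(net, file.path(config$out_dir, "model.json"))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out)
}
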