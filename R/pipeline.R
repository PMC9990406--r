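#' Pipeline run configuration
#'
#' Bundles every stage configuration, the input/output paths and the seeds
#' of a full analysis run into one serialisable object, so a run can be
#' reproduced from its archived configuration alone.
#'
#' @param farms a farm table (data.frame), a CSV path, or a
#'   [synthetic_config()] to simulate one.
#' @param output_dir directory for artefacts.
#' @param mixrf [mixrf_config()] for the final model and downstream refits.
#' @param rfe [rfe_config()]; set `run_rfe_stage = FALSE` to keep all
#'   retained predictors instead.
#' @param n_consistency_runs refits for the sign-consistency rule
#'   (default 10).
#' @param costs_yaml,expectations_yaml optional paths; defaults to the
#'   packaged examples.
#' @param plan_farms farm ids to produce plans for (`NULL` = none,
#'   `"first"` = the first farm).
#' @param run_rfe_stage,run_cluster_stage,run_plan_stage stage toggles.
#' @param seed master seed for stages without their own.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(farms,
                            output_dir = tempfile("amuplan_run_"),
                            mixrf = mixrf_config(),
                            rfe = rfe_config(mixrf = mixrf),
                            n_consistency_runs = 10,
                            costs_yaml = system.file("extdata",
                                                    "costs_example.yaml",
                                                    package = "amuplan"),
                            expectations_yaml = system.file(
                              "extdata", "expectations_example.yaml",
                              package = "amuplan"),
                            plan_farms = "first",
                            run_rfe_stage = TRUE,
                            run_cluster_stage = TRUE,
                            run_plan_stage = TRUE,
                            seed = 1L) {
  structure(list(farms = farms, output_dir = output_dir, mixrf = mixrf,
                 rfe = rfe, n_consistency_runs = n_consistency_runs,
                 costs_yaml = costs_yaml,
                 expectations_yaml = expectations_yaml,
                 plan_farms = plan_farms,
                 run_rfe_stage = run_rfe_stage,
                 run_cluster_stage = run_cluster_stage,
                 run_plan_stage = run_plan_stage,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# Stable hash of the run configuration; stamped into every artefact so
# outputs can be traced to the exact configuration that produced them. The
# output directory is excluded and config files enter by content, so the
# hash identifies the analysis, not where it is written from or to.
config_hash <- function(config) {
  x <- unclass(config)
  x$output_dir <- NULL
  for (fld in c("costs_yaml", "expectations_yaml")) {
    if (is.character(x[[fld]]) && file.exists(x[[fld]])) {
      x[[fld]] <- readLines(x[[fld]], warn = FALSE)
    }
  }
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage end to end: input (or simulation), outcome and
#' covariate transformation, feature filtering and encoding, cross-validated
#' recursive feature elimination, the final mixed-effects forest with its
#' proximity matrix, MDS + k-means clustering with prototypes, imputation
#' and sign-consistent effect sizes, and per-farm intervention plans with
#' costs. Artefacts are written to the output directory as CSV/JSON, each
#' recorded (with the configuration hash) in `manifest.json`.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the in-memory results of every stage and
#'   `output_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  artefacts <- character(0)
  emit <- function(obj, file, writer) {
    path <- file.path(config$output_dir, file)
    writer(obj, path)
    artefacts <<- c(artefacts, file)
    path
  }
  write_json_art <- function(obj, path)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  write_csv_art <- function(obj, path)
    utils::write.csv(obj, path, row.names = FALSE)

  # -- input ----------------------------------------------------------------
  farms <- config$farms
  if (inherits(farms, "synthetic_config")) farms <- generate_farms(farms)
  if (is.character(farms)) farms <- read_farms(farms)

  # -- preprocess -----------------------------------------------------------
  filt <- filter_features(farms)
  X <- encode_features(farms, filt$retained)
  y <- transform_amu(farms$tiddd)
  groups <- farms$country
  emit(unclass(filt$report), "preprocess_report.json", write_json_art)

  # -- recursive feature elimination ---------------------------------------
  rfe_res <- NULL
  if (config$run_rfe_stage) {
    rfe_res <- run_rfe(X, y, groups, config$rfe)
    emit(list(feature_frequencies = as.list(rfe_res$feature_frequencies),
              mean_rmse = as.list(rfe_res$mean_rmse),
              selected_threshold = rfe_res$selected_threshold,
              final_features = rfe_res$final_features),
         "rfe_result.json", write_json_art)
    X <- X[, rfe_res$final_features, drop = FALSE]
  }

  # -- final model ----------------------------------------------------------
  model <- fit_mixrf(X, y, groups, config$mixrf)
  prox <- rf_proximity(model, X)
  emit(as.data.frame(unclass(prox)), "proximity.csv", write_csv_art)
  emit(data.frame(feature = names(gini_importance(model)),
                  importance = as.numeric(gini_importance(model))),
       "importance.csv", write_csv_art)

  # -- clustering -----------------------------------------------------------
  clust <- NULL; protos <- NULL; labels <- NULL
  if (config$run_cluster_stage) {
    coords <- embed_proximity(prox, dims = 3)
    k_max <- min(10L, nrow(coords) - 1L)
    clust <- cluster_farms(coords, k_min = 2, k_max = k_max,
                           seed = config$seed)
    labels <- label_users(y, predict(model, X, groups), farms$farm_id)
    protos <- prototypes(farms, clust$assignments, labels)
    emit(protos, "prototypes.csv", write_csv_art)
    emit(data.frame(farm_id = farms$farm_id, cluster = clust$assignments,
                    real_label = labels$real_label,
                    predicted_label = labels$predicted_label),
         "clusters.csv", write_csv_art)
  }

  # -- effects with sign-consistency rule ----------------------------------
  Ximp <- impute_missing_levels(X, seed = config$seed)
  cons <- run_consistency(Ximp, y, groups,
                          n_runs = config$n_consistency_runs,
                          mixrf_cfg = config$mixrf)
  mean_eff <- colMeans(cons$effects)
  eff_tab <- data.frame(feature = names(mean_eff),
                        effect = as.numeric(mean_eff),
                        sign_consistency = as.integer(
                          cons$sign_consistency[names(mean_eff)]),
                        consistent = cons$consistent[names(mean_eff)],
                        row.names = NULL)
  emit(eff_tab, "effects.csv", write_csv_art)

  # -- per-farm plans -------------------------------------------------------
  plans <- list()
  if (config$run_plan_stage && !is.null(config$plan_farms)) {
    expectations <- read_expectations(config$expectations_yaml)
    cost_table <- read_cost_table(config$costs_yaml)
    ids <- config$plan_farms
    if (identical(ids, "first")) ids <- farms$farm_id[1]
    for (id in ids) {
      i <- match(id, farms$farm_id)
      if (is.na(i)) stop("run_pipeline: unknown farm id ", id)
      candidates <- plan_candidates(Ximp[i, , drop = FALSE], eff_tab,
                                    expectations)
      scen <- enumerate_scenarios(candidates)
      rep <- evaluate_plan(Ximp[i, , drop = FALSE], groups[i], scen,
                           cons$models, original_ti = farms$tiddd[i],
                           farm_id = id)
      rep <- attach_costs(rep, cost_table, farms[i, , drop = FALSE])
      plans[[id]] <- rep
      emit(c(list(farm_id = rep$farm_id, original_ti = rep$original_ti,
                  baseline_prediction_ti = rep$baseline_prediction_ti),
             list(scenarios = rep$scenarios)),
           paste0("plan_", id, ".json"), write_json_art)
    }
  }

  emit(list(config_hash = hash, artefacts = artefacts,
            seed = config$seed), "manifest.json", write_json_art)
  invisible(list(farms = farms, retained = filt$retained,
                 report = filt$report, rfe = rfe_res, model = model,
                 proximity = prox, clusters = clust, labels = labels,
                 prototypes = protos, effects = eff_tab,
                 consistency = cons, plans = plans,
                 output_dir = config$output_dir, config_hash = hash))
}

#' Candidate interventions for one farm
#'
#' Applies the strength/weakness cross-table and the biological-expectation
#' filter to a farm's current answers, restricted to sign-consistent
#' measures, and returns the measures eligible for scenario enumeration.
#'
#' @param farm_row one-row imputed predictor frame.
#' @param effects_table data.frame with `feature`, `effect` and
#'   `consistent` columns (as produced by [run_pipeline()]).
#' @param expectations named expected directions ([read_expectations()]).
#' @return Character vector of candidate measures.
#' @export
plan_candidates <- function(farm_row, effects_table, expectations) {
  keep <- effects_table$consistent & effects_table$effect != 0
  eff <- stats::setNames(effects_table$effect, effects_table$feature)[keep]
  if (!length(eff)) return(character(0))
  vals <- stats::setNames(as.numeric(farm_row[1, names(eff)]), names(eff))
  classified <- classify_measures(vals, eff)
  kept <- filter_by_expectation(classified, expectations)
  kept$feature
}
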