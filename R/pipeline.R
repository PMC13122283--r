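# End-to-end pipeline: ingest or simulate profiles, sequence probabilities,
# trajectory features, cross-validated and final weighted logistic models,
# source attribution and threshold calibration.

#' Run the full ASPS pipeline
#'
#' Stages: (1) read `config$input_csv` or simulate the configured cohort;
#' (2) estimate population priors from the doping-control athletes and add
#' sequence probabilities; (3) build per-athlete trajectory features of the
#' configured measurement kind; (4) stratified K-fold cross-validation
#' (laboratory athletes in every training split) producing out-of-fold ASPS
#' and the CV AUC on doping-control athletes; (5) final model on all data,
#' with backward selection down to `config$target_size` regressors when set;
#' (6) per-athlete LC attribution with flags; (7) ASPS threshold calibration
#' at the configured FPR targets, computed on the out-of-fold scores. The run
#' is fully reproducible from the config (which embeds every seed).
#'
#' @param config An [pipeline_config()].
#' @param out_dir When non-`NULL`, writes `profiles.csv`, `model.json`,
#'   `scores.csv`, `attribution.csv`, `thresholds.csv` and `manifest.json`
#'   there (directory created if needed).
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list: `profiles`, `priors`, `features`, `cv_scores`,
#'   `cv_auc`, `model`, `attribution`, `thresholds`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "asps_config"))
  say <- function(...) if (!quiet) message("[asps] ", ...)

  if (!is.null(config$input_csv)) {
    say("reading profiles from ", config$input_csv)
    profiles <- read_profiles(config$input_csv, min_obs = config$min_obs)
  } else {
    say("simulating cohort (seed ", config$simulation$seed, ")")
    profiles <- simulate_cohort(config$simulation)$profiles
  }
  if (is.null(profiles$source)) profiles$source <- "doping_control"
  if (is.null(profiles$weight)) {
    profiles$weight <- ifelse(profiles$source == "laboratory", config$lab_weight, 1)
  }
  say("athletes read: ", length(unique(profiles$athlete_id)))

  dc <- profiles[profiles$source == "doping_control", , drop = FALSE]
  priors <- estimate_priors(dc)
  profiles <- add_sequence_probabilities(profiles, priors)
  say("sequence probabilities added (priors estimated from doping-control athletes)")

  features <- build_features(profiles, kind = config$measurement_kind,
                             min_obs = config$min_obs)
  say("features built: ", nrow(features), " athletes x ", length(feature_names()), " features")

  plan <- make_cv_plan(features$athlete_id, features$label, features$source,
                       K = config$folds, seed = config$seed)
  cv_scores <- cross_validated_scores(features, plan, ridge = config$ridge)
  cv_auc <- auc(cv_scores$score, cv_scores$label)
  say(sprintf("cross-validated AUC on doping-control athletes: %.3f", cv_auc))

  model <- if (!is.null(config$target_size) &&
               config$target_size < length(feature_names())) {
    select_variables(features, target_size = config$target_size, ridge = config$ridge)
  } else {
    fit_asps_model(features, ridge = config$ridge)
  }
  say("final model: ", length(model$coefficients), " regressors (",
      model$iterations, " Newton iterations)")

  attribution <- attribute_sources(model, features, threshold = config$flag_threshold)
  attribution$label <- features$label
  thresholds <- calibrate_thresholds(cv_scores$score, cv_scores$label,
                                     config$fpr_targets)
  say("thresholds calibrated at FPR targets ",
      paste(config$fpr_targets, collapse = ", "))

  bundle <- list(profiles = profiles, priors = priors, features = features,
                 cv_scores = cv_scores, cv_auc = cv_auc, model = model,
                 attribution = attribution, thresholds = thresholds,
                 config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_profiles(profiles, file.path(out_dir, "profiles.csv"))
    write_asps_model(model, file.path(out_dir, "model.json"))
    utils::write.csv(cv_scores, file.path(out_dir, "scores.csv"), row.names = FALSE)
    utils::write.csv(attribution, file.path(out_dir, "attribution.csv"), row.names = FALSE)
    utils::write.csv(thresholds, file.path(out_dir, "thresholds.csv"), row.names = FALSE)
    manifest <- list(
      package = "asps",
      version = as.character(utils::packageVersion("asps")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      cv_auc = cv_auc,
      n_athletes = nrow(features),
      config = .config_doc(config)
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("artefacts written to ", out_dir)
  }
  invisible(bundle)
}
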