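# CSV ingestion/writing, model and config serialisation.

#' Read longitudinal profiles from CSV
#'
#' Accepts either the wide schema (`athlete_id, occasion,` one column per
#' canonical biomarker, optional `label`, `weight`, `source`, `phase`) or the
#' long schema (`athlete_id, occasion, biomarker, value`). Biomarker names are
#' canonicalised; occasions are sorted within athlete; all values must be
#' strictly positive; athletes with fewer than `min_obs` occasions are
#' excluded with a message.
#'
#' @param path CSV file path.
#' @param min_obs Minimum occasions per athlete (default 4, i.e. more than
#'   three doping-control measurements).
#' @return Wide profiles data frame sorted by athlete and occasion.
#' @export
read_profiles <- function(path, min_obs = 4L) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) {
    warning("empty profiles file: ", path)
    return(raw)
  }
  if (!all(c("athlete_id", "occasion") %in% names(raw))) {
    stop("parse error: profiles CSV needs athlete_id and occasion columns")
  }
  if (all(c("biomarker", "value") %in% names(raw))) {
    raw$biomarker <- canonical_biomarker(raw$biomarker)
    wide <- stats::reshape(raw, direction = "wide",
                           idvar = setdiff(names(raw), c("biomarker", "value")),
                           timevar = "biomarker", v.names = "value")
    names(wide) <- sub("^value\\.", "", names(wide))
    raw <- wide
  } else {
    # map display-name columns onto canonical keys where possible
    for (j in seq_along(names(raw))) {
      key <- tryCatch(canonical_biomarker(names(raw)[j]), error = function(e) NULL)
      if (!is.null(key)) names(raw)[j] <- key
    }
  }
  bm <- biomarker_keys()
  missing <- setdiff(bm, names(raw))
  if (length(missing)) stop("parse error: missing biomarker column(s): ",
                            paste(missing, collapse = ", "))
  for (k in bm) {
    bad <- which(!is.na(raw[[k]]) & (!is.finite(raw[[k]]) | raw[[k]] <= 0))
    if (length(bad)) {
      stop("validation error: non-positive ", k, " value at row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
  }
  raw <- raw[order(raw$athlete_id, raw$occasion), , drop = FALSE]
  counts <- table(raw$athlete_id)
  keep <- names(counts)[counts >= min_obs]
  excluded <- sum(counts < min_obs)
  if (excluded > 0L) {
    message("read_profiles: excluded ", excluded, " athlete(s) with fewer than ",
            min_obs, " occasions")
  }
  out <- raw[raw$athlete_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a profiles table to CSV
#'
#' @param profiles Profiles data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  utils::write.csv(profiles, path, row.names = FALSE)
  invisible(path)
}

#' Serialise a fitted ASPS model to a flat JSON document
#'
#' Stores schema version, measurement kind, intercept, named coefficients and
#' the per-feature standardisation (centre, scale) — everything needed to
#' score new athletes; fit diagnostics are not serialised.
#'
#' @param model An `asps_model`.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_asps_model <- function(model, path) {
  stopifnot(inherits(model, "asps_model"))
  doc <- list(
    schema_version = 1L,
    measurement_kind = model$measurement_kind,
    intercept = model$intercept,
    coefficients = as.list(model$coefficients),
    centre = as.list(model$centre[names(model$coefficients)]),
    scale = as.list(model$scale[names(model$coefficients)]),
    ridge = model$ridge
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a serialised ASPS model
#'
#' @param path JSON path written by [write_asps_model()].
#' @return An `asps_model` usable with [predict_asps()], [decompose_lc()] and
#'   friends.
#' @export
read_asps_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$schema_version) || doc$schema_version != 1L) {
    stop("unsupported model schema version")
  }
  structure(list(
    intercept = doc$intercept,
    coefficients = unlist(doc$coefficients),
    centre = unlist(doc$centre), scale = unlist(doc$scale),
    dropped = character(), vcov = NULL, converged = NA,
    iterations = NA_integer_, gradient_norm = NA_real_,
    log_likelihood = NA_real_, ridge = doc$ridge, n = NA_integer_,
    measurement_kind = doc$measurement_kind
  ), class = "asps_model")
}

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run; all defaults overridable and
#' the object round-trips losslessly through JSON.
#'
#' @param input_csv Optional profiles CSV; when `NULL` the synthetic cohort
#'   in `simulation` is generated instead.
#' @param measurement_kind Features built from `"abp_sp"` (default) or
#'   `"original"` values.
#' @param folds Cross-validation folds (default 5).
#' @param seed Seed for fold assignment (and the simulator unless `simulation`
#'   overrides it).
#' @param lab_weight Loss weight of laboratory athletes (default 20).
#' @param flag_threshold LC flag threshold (default 0.8).
#' @param fpr_targets FPR targets for threshold calibration.
#' @param min_obs Minimum occasions per athlete (default 4).
#' @param ridge Ridge used in every logistic fit.
#' @param target_size Regressors kept by backward selection in the final
#'   model; `NULL` keeps all 80.
#' @param simulation A [simulation_config()] used when `input_csv` is `NULL`.
#' @return A list of class `asps_config`.
#' @export
pipeline_config <- function(input_csv = NULL,
                            measurement_kind = c("abp_sp", "original"),
                            folds = 5L, seed = 1L, lab_weight = 20,
                            flag_threshold = 0.8,
                            fpr_targets = c(0.05, 0.10, 0.20),
                            min_obs = 4L, ridge = 1e-8, target_size = 21L,
                            simulation = NULL) {
  measurement_kind <- match.arg(measurement_kind)
  if (is.null(simulation)) {
    simulation <- simulation_config(lab_weight = lab_weight, seed = seed)
  }
  structure(list(
    input_csv = input_csv, measurement_kind = measurement_kind,
    folds = as.integer(folds), seed = as.integer(seed),
    lab_weight = lab_weight, flag_threshold = flag_threshold,
    fpr_targets = fpr_targets, min_obs = as.integer(min_obs),
    ridge = ridge, target_size = if (is.null(target_size)) NULL else as.integer(target_size),
    simulation = simulation
  ), class = "asps_config")
}

#' Write a pipeline configuration to JSON
#' @param config An `asps_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(.config_doc(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

# JSON-ready plain-list view of an asps_config
.config_doc <- function(config) {
  stopifnot(inherits(config, "asps_config"))
  doc <- unclass(config)
  doc$simulation <- unclass(doc$simulation)
  doc$simulation$mu0 <- as.list(doc$simulation$mu0)
  doc$simulation$tau <- as.list(doc$simulation$tau)
  doc$simulation$sigma_w <- as.list(doc$simulation$sigma_w)
  doc
}

#' Read a pipeline configuration from JSON
#' @param path Path written by [write_config()].
#' @return An `asps_config`.
#' @export
read_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- doc$simulation
  simulation <- simulation_config(
    n_clean = sim$n_clean, n_doped = sim$n_doped, n_lab = sim$n_lab,
    occasions = sim$occasions, baseline_occasions = sim$baseline_occasions,
    dosed_occasions = sim$dosed_occasions, washout_occasions = sim$washout_occasions,
    mu0 = unlist(sim$mu0), tau = unlist(sim$tau), sigma_w = unlist(sim$sigma_w),
    effect_sd = sim$effect_sd, effect_sd_other = sim$effect_sd_other,
    effect_cor = sim$effect_cor,
    regimes = as.data.frame(sim$regimes, stringsAsFactors = FALSE),
    lab_weight = sim$lab_weight, seed = sim$seed
  )
  pipeline_config(
    input_csv = doc$input_csv, measurement_kind = doc$measurement_kind,
    folds = doc$folds, seed = doc$seed, lab_weight = doc$lab_weight,
    flag_threshold = doc$flag_threshold, fpr_targets = doc$fpr_targets,
    min_obs = doc$min_obs, ridge = doc$ridge,
    target_size = doc$target_size, simulation = simulation
  )
}
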