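# Weighted logistic regression on standardised trajectory features. The
# fitted probability is the abnormal steroid profile score (ASPS). Laboratory
# athletes (known dopers) carry weight 20 in the loss; doping-control athletes
# weight 1. Cross-validation folds stratify the positives and keep laboratory
# athletes in every training split.

#' Standardise a feature matrix
#'
#' Centres each column to mean 0 and scales to sd 1 (n - 1 denominator) on
#' the supplied data. Zero-variance columns are dropped with a warning; their
#' names are recorded so downstream schema checks stay honest.
#'
#' @param x Numeric matrix or data frame of features (rows = athletes).
#' @return List with `x` (standardised matrix over retained columns),
#'   `centre`, `scale` (named vectors) and `dropped` (character).
#' @export
standardise_features <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least two rows to standardise")
  centre <- colMeans(x)
  scale <- apply(x, 2L, stats::sd)
  keep <- is.finite(scale) & scale > 0
  if (any(!keep)) {
    warning("dropping zero-variance feature(s): ",
            paste(colnames(x)[!keep], collapse = ", "))
  }
  xs <- sweep(sweep(x[, keep, drop = FALSE], 2L, centre[keep]), 2L, scale[keep], "/")
  list(x = xs, centre = centre[keep], scale = scale[keep],
       dropped = colnames(x)[!keep])
}

# Newton / IRLS maximiser of the weighted Bernoulli log likelihood with an
# optional tiny ridge on the slope coefficients (never the intercept), used
# only to keep the Hessian invertible under (near-)separation. Converges on
# max |gradient| < tol; deterministic given the input order.
.irls_logistic <- function(x, y, weights, ridge = 1e-8, maxit = 100L, tol = 1e-8) {
  x1 <- cbind(`(intercept)` = 1, x)
  p <- ncol(x1)
  pen <- c(0, rep(ridge, p - 1L))
  beta <- numeric(p)
  obj <- function(b) {
    eta <- drop(x1 %*% b)
    sum(weights * (y * eta - log1p(exp(eta)))) - sum(pen * b^2) / 2
  }
  ll <- obj(beta)
  grad_norm <- Inf
  for (iter in seq_len(maxit)) {
    eta <- drop(x1 %*% beta)
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(x1, weights * (y - mu))) - pen * beta
    grad_norm <- max(abs(grad))
    if (grad_norm < tol) break
    w <- pmax(weights * mu * (1 - mu), 1e-10)
    hess <- crossprod(x1 * sqrt(w)) + diag(pen, p)
    step <- tryCatch(solve(hess, grad), error = function(e) {
      solve(hess + diag(1e-8, p), grad)
    })
    # step halving keeps Newton honest on badly scaled or separating data
    fac <- 1
    repeat {
      cand <- beta + fac * step
      ll_new <- obj(cand)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      fac <- fac / 2
      if (fac < 1e-8) { cand <- beta; ll_new <- ll; break }
    }
    beta <- cand
    ll <- ll_new
  }
  converged <- grad_norm < tol
  if (!converged) {
    warning(sprintf("IRLS did not converge in %d iterations (max |gradient| = %.3g)",
                    maxit, grad_norm))
  }
  eta <- drop(x1 %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(weights * mu * (1 - mu), 1e-10)
  hess <- crossprod(x1 * sqrt(w)) + diag(pen, p)
  vcov <- tryCatch(solve(hess), error = function(e) matrix(NA_real_, p, p))
  dimnames(vcov) <- list(colnames(x1), colnames(x1))
  list(beta = stats::setNames(beta, colnames(x1)), vcov = vcov,
       converged = converged, iterations = iter, gradient_norm = grad_norm,
       log_likelihood = sum(weights * (y * eta - log1p(exp(eta)))))
}

#' Fit the weighted logistic ASPS model
#'
#' Standardises the feature columns, then maximises the weighted Bernoulli
#' log likelihood by Newton's method (gradient tolerance 1e-8, at most 100
#' iterations). A tiny ridge (default 1e-8, slopes only) guards against
#' perfect separation on small cohorts; set `ridge = 0` to disable.
#'
#' @param features Data frame or matrix of feature columns (e.g. the 80
#'   trajectory features), or a [build_features()] table; non-feature columns
#'   (`athlete_id`, `label`, `weight`, `source`) are ignored as predictors.
#' @param labels Binary 0/1 vector; taken from `features$label` when missing.
#' @param weights Positive per-athlete loss weights; taken from
#'   `features$weight`, defaulting to 1.
#' @param ridge Ridge penalty on standardised slope coefficients.
#' @param feature_names Optional subset of feature columns to use.
#' @return An object of class `asps_model`: `intercept`, named
#'   `coefficients`, the standardisation `centre`/`scale`, fit diagnostics
#'   and the `measurement_kind` tag when the input carries one.
#' @export
fit_asps_model <- function(features, labels = NULL, weights = NULL,
                           ridge = 1e-8, feature_names = NULL) {
  meta_cols <- c("athlete_id", "label", "weight", "source")
  feats <- as.data.frame(features, check.names = FALSE)
  if (is.null(labels)) labels <- feats$label
  if (is.null(weights)) weights <- feats$weight
  if (is.null(weights)) weights <- rep(1, nrow(feats))
  if (is.null(labels)) stop("labels are required (supply `labels` or a `label` column)")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (any(!is.finite(weights) | weights <= 0)) stop("weights must be positive")
  if (length(unique(labels)) < 2L) stop("degenerate labels: both classes must be present")
  x <- as.matrix(feats[, setdiff(names(feats), meta_cols), drop = FALSE])
  if (!is.null(feature_names)) {
    missing <- setdiff(feature_names, colnames(x))
    if (length(missing)) stop("unknown feature(s): ", paste(missing, collapse = ", "))
    x <- x[, feature_names, drop = FALSE]
  }
  std <- standardise_features(x)
  fit <- .irls_logistic(std$x, as.numeric(labels), as.numeric(weights), ridge = ridge)
  structure(list(
    intercept = unname(fit$beta[1L]),
    coefficients = fit$beta[-1L],
    centre = std$centre, scale = std$scale, dropped = std$dropped,
    vcov = fit$vcov, converged = fit$converged, iterations = fit$iterations,
    gradient_norm = fit$gradient_norm, log_likelihood = fit$log_likelihood,
    ridge = ridge, n = nrow(x),
    measurement_kind = attr(features, "measurement_kind") %||% NA_character_
  ), class = "asps_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.asps_model <- function(x, ...) {
  cat(sprintf("ASPS weighted logistic model: %d regressors, intercept %.3f (n = %d%s)\n",
              length(x$coefficients), x$intercept, x$n,
              if (x$converged) ", converged" else ", NOT converged"))
  invisible(x)
}

# internal: standardised design matrix for prediction
.standardised_design <- function(model, features) {
  feats <- as.data.frame(features, check.names = FALSE)
  need <- names(model$coefficients)
  missing <- setdiff(need, names(feats))
  if (length(missing)) {
    stop("schema error: features missing model regressor(s): ",
         paste(missing, collapse = ", "))
  }
  x <- as.matrix(feats[, need, drop = FALSE])
  sweep(sweep(x, 2L, model$centre[need]), 2L, model$scale[need], "/")
}

#' Predict the abnormal steroid profile score
#'
#' Applies the model's stored standardisation and returns
#' `plogis(intercept + sum(beta * standardised feature))`, a probability in
#' (0, 1): the ASPS. The result is nudged inside the open interval at
#' machine precision (a saturating linear predictor would otherwise round to
#' exactly 0 or 1), preserving the score ordering.
#'
#' @param model An `asps_model`.
#' @param features Data frame (or single named vector) covering all model
#'   regressor names.
#' @return Numeric vector of scores, one per row of `features`.
#' @export
predict_asps <- function(model, features) {
  stopifnot(inherits(model, "asps_model"))
  if (is.null(dim(features))) features <- as.data.frame(as.list(features), check.names = FALSE)
  xs <- .standardised_design(model, features)
  p <- stats::plogis(model$intercept + drop(xs %*% model$coefficients))
  .open_unit(p)
}

# keep probabilities strictly inside (0,1) without disturbing their order:
# clamp to the nearest representable doubles
.open_unit <- function(p) {
  pmin(pmax(p, .Machine$double.xmin), 1 - .Machine$double.eps / 2)
}

#' @export
predict.asps_model <- function(object, newdata, ...) predict_asps(object, newdata)

#' Wald z-tests of the model coefficients
#'
#' @param model An `asps_model`.
#' @return Data frame with estimate, standard error, z and two-sided p per
#'   regressor (intercept excluded).
#' @export
wald_tests <- function(model) {
  se <- sqrt(diag(model$vcov))[-1L]
  est <- model$coefficients
  z <- est / se
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             z = unname(z), p = unname(2 * stats::pnorm(-abs(z))),
             stringsAsFactors = FALSE)
}

#' Backward variable selection on Wald p-values
#'
#' Starting from a fit on all candidate features, repeatedly refits after
#' dropping the regressor with the largest Wald p-value, until `target_size`
#' regressors remain or every p-value is below `alpha`. Ties (e.g. exactly
#' collinear duplicates) are broken by dropping the lexicographically last
#' name, so the procedure is deterministic.
#'
#' @inheritParams fit_asps_model
#' @param target_size Number of regressors to keep (default 21).
#' @param alpha Early-stop significance level (default 0.05).
#' @return The selected `asps_model`.
#' @export
select_variables <- function(features, labels = NULL, weights = NULL,
                             target_size = 21L, alpha = 0.05, ridge = 1e-8,
                             feature_names = NULL) {
  model <- fit_asps_model(features, labels, weights, ridge = ridge,
                          feature_names = feature_names)
  if (target_size >= length(model$coefficients)) {
    warning("target_size >= available regressors; returning the full model")
    return(model)
  }
  current <- names(model$coefficients)
  repeat {
    if (length(current) <= target_size) break
    wt <- wald_tests(model)
    if (all(wt$p < alpha, na.rm = TRUE)) break
    worst_p <- max(wt$p, na.rm = TRUE)
    tied <- wt$term[!is.na(wt$p) & abs(wt$p - worst_p) <= 1e-12]
    drop_name <- sort(tied)[length(tied)]
    current <- setdiff(current, drop_name)
    model <- fit_asps_model(features, labels, weights, ridge = ridge,
                            feature_names = current)
    current <- names(model$coefficients)
  }
  model
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation with midrank tie handling:
#' P(score_pos > score_neg) + 0.5 P(score_pos = score_neg).
#'
#' @param scores Numeric risk scores.
#' @param labels Binary 0/1 labels; both classes must be present.
#' @return AUC in [0, 1].
#' @export
#' @examples
#' auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
auc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("undefined AUC: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Stratified cross-validation plan
#'
#' Assigns each doping-control athlete to one of `K` folds so that the
#' positives (ADRV athletes) are split as evenly as integer arithmetic allows
#' (remainder spread at most 1), and likewise for negatives. Laboratory
#' athletes never enter a fold: they join every training split. Positives and
#' negatives are shuffled by `seed` and dealt round-robin, so the plan is
#' reproducible.
#'
#' @param athlete_ids Character/vector of athlete ids.
#' @param labels Binary 0/1 per athlete.
#' @param source Per-athlete tag, `"laboratory"` or `"doping_control"`;
#'   default all doping control.
#' @param K Number of folds (default 5).
#' @param seed Integer seed for the shuffle.
#' @return Object of class `cv_plan`: data frame `folds` (athlete_id, fold)
#'   over doping-control athletes, plus `K` and `seed`.
#' @export
make_cv_plan <- function(athlete_ids, labels, source = NULL, K = 5L, seed = 1L) {
  if (K < 2L) stop("K must be >= 2")
  if (is.null(source)) source <- rep("doping_control", length(athlete_ids))
  stopifnot(length(labels) == length(athlete_ids), length(source) == length(athlete_ids))
  dc <- source == "doping_control"
  pos <- athlete_ids[dc & labels == 1]
  neg <- athlete_ids[dc & labels == 0]
  if (length(pos) < K) stop("too few positive doping-control athletes for ", K, " folds")
  deal <- function(ids) {
    ids <- ids[sample.int(length(ids))]
    stats::setNames(rep_len(seq_len(K), length(ids)), ids)
  }
  folds <- with_seed(seed, c(deal(pos), deal(neg)))
  structure(list(
    folds = data.frame(athlete_id = names(folds), fold = unname(folds),
                       stringsAsFactors = FALSE),
    K = as.integer(K), seed = as.integer(seed)
  ), class = "cv_plan")
}

#' Out-of-fold ASPS for every doping-control athlete
#'
#' For each fold, fits the model on the union of the other folds and all
#' laboratory athletes, then scores the held-out fold. Laboratory athletes are
#' never scored. Optionally runs [select_variables()] inside each fold.
#'
#' @param features A [build_features()] table with `athlete_id`, `label`,
#'   `weight` and `source` columns.
#' @param plan A [make_cv_plan()] over the same doping-control athletes.
#' @param ridge Ridge passed to the fit.
#' @param target_size When non-`NULL`, per-fold backward selection down to
#'   this many regressors.
#' @return Data frame `athlete_id`, `label`, `fold`, `score` (one row per
#'   doping-control athlete).
#' @export
cross_validated_scores <- function(features, plan, ridge = 1e-8, target_size = NULL) {
  stopifnot(inherits(plan, "cv_plan"))
  feats <- as.data.frame(features, check.names = FALSE)
  if (is.null(feats$source)) feats$source <- "doping_control"
  if (is.null(feats$weight)) feats$weight <- 1
  dc_ids <- feats$athlete_id[feats$source == "doping_control"]
  if (!setequal(plan$folds$athlete_id, dc_ids)) {
    stop("inconsistent plan: fold athletes do not match the doping-control athletes")
  }
  fold_of <- stats::setNames(plan$folds$fold, plan$folds$athlete_id)
  out <- list()
  for (k in seq_len(plan$K)) {
    test_ids <- names(fold_of)[fold_of == k]
    is_test <- feats$athlete_id %in% test_ids
    train <- feats[!is_test, , drop = FALSE]
    test <- feats[is_test, , drop = FALSE]
    model <- if (is.null(target_size)) {
      fit_asps_model(train, ridge = ridge)
    } else {
      select_variables(train, target_size = target_size, ridge = ridge)
    }
    out[[k]] <- data.frame(athlete_id = test$athlete_id, label = test$label,
                           fold = k, score = predict_asps(model, test),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Collapse per-occasion scores to one score per athlete
#'
#' Used by the laboratory-trained per-occasion protocol: an athlete's risk is
#' the largest risk score over their sampling occasions.
#'
#' @param scores Numeric per-occasion scores.
#' @param athlete_ids Grouping vector aligned with `scores`.
#' @return Named numeric vector of per-athlete maxima.
#' @export
max_score_per_athlete <- function(scores, athlete_ids) {
  if (length(scores) == 0L) stop("empty group: no scores supplied")
  if (length(scores) != length(athlete_ids)) stop("scores and athlete_ids differ in length")
  res <- tapply(scores, athlete_ids, max)
  stats::setNames(as.vector(res), names(res))
}
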