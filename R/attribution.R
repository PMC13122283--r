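# Decomposition of the logistic linear predictor into per-biomarker sources
# (LC-T/E, LC-A/Etio, LC-5a-ADiol/5b-ADiol, LC-5a-ADiol/E, LC-A/T and
# LC-Cov), the flag rule at 0.8, and FPR-targeted threshold calibration of
# the ASPS. The sources always partition the fitted regressors, so the LCs
# sum to logit(ASPS) minus the intercept for any model, not just one where
# the A/T features were eliminated by selection.

.SOURCES <- c("te", "aetio", "adiol_ratio", "adiol_e", "at", "cov")

#' Source of variation behind a feature
#'
#' Single-biomarker features (means, ranges, ranges of first/second
#' differences, and their squares) belong to that biomarker's source; every
#' covariance feature (levels or first differences, and squares) belongs to
#' the pooled covariance source `"cov"`.
#'
#' @param name Feature name(s) from the 80-name schema.
#' @return Character vector of source tags (`te`, `aetio`, `adiol_ratio`,
#'   `adiol_e`, `at`, `cov`).
#' @export
#' @examples
#' source_of_feature(c("range_te_sq", "cov_d1_adiol_ratio.aetio"))
source_of_feature <- function(name) {
  schema <- feature_schema()
  idx <- match(name, schema$name)
  if (anyNA(idx)) {
    stop("schema error: unknown feature name(s): ",
         paste(name[is.na(idx)], collapse = ", "))
  }
  schema$source[idx]
}

#' Decompose the linear predictor into source contributions
#'
#' For each source, LC = sum over that source's regressors of
#' coefficient x standardised feature value. The six LCs sum to
#' `logit(ASPS) - intercept` exactly; the intercept belongs to no source.
#'
#' @param model An `asps_model` fitted on the 80-feature schema.
#' @param features Feature data frame (or single named vector).
#' @return Data frame with one row per athlete: `lc_te`, `lc_aetio`,
#'   `lc_adiol_ratio`, `lc_adiol_e`, `lc_at`, `lc_cov`, and `asps`.
#' @export
decompose_lc <- function(model, features) {
  stopifnot(inherits(model, "asps_model"))
  if (is.null(dim(features))) features <- as.data.frame(as.list(features), check.names = FALSE)
  xs <- .standardised_design(model, features)
  contrib <- sweep(xs, 2L, model$coefficients, "*")
  src <- source_of_feature(colnames(contrib))
  out <- vapply(.SOURCES, function(s) {
    cols <- src == s
    if (!any(cols)) return(rep(0, nrow(contrib)))
    rowSums(contrib[, cols, drop = FALSE])
  }, numeric(nrow(contrib)))
  out <- matrix(out, nrow = nrow(contrib),
                dimnames = list(NULL, paste0("lc_", .SOURCES)))
  res <- as.data.frame(out)
  res$asps <- .open_unit(stats::plogis(model$intercept + rowSums(contrib)))
  res
}

#' Flag sources whose contribution exceeds a threshold
#'
#' A source is flagged iff its LC is strictly larger than `threshold`
#' (default 0.8). On the odds scale a flagged increment multiplies the doping
#' odds by `exp(threshold)` (2.2 at the default).
#'
#' @param lc A row (or data frame) from [decompose_lc()].
#' @param threshold Flagging threshold on the linear-predictor scale.
#' @return Data frame of binary flags `flag_te` ... `flag_cov`, with
#'   attributes `threshold` and `odds_multiplier`.
#' @export
flag_sources <- function(lc, threshold = 0.8) {
  lc <- as.data.frame(lc)
  cols <- paste0("lc_", .SOURCES)
  stopifnot(all(cols %in% names(lc)))
  flags <- as.data.frame(lapply(lc[cols], function(v) as.integer(v > threshold)))
  names(flags) <- paste0("flag_", .SOURCES)
  attr(flags, "threshold") <- threshold
  attr(flags, "odds_multiplier") <- exp(threshold)
  flags
}

#' Per-athlete source attribution table
#'
#' Convenience wrapper: LC decomposition, flags and ASPS in one table.
#'
#' @inheritParams decompose_lc
#' @param threshold Flag threshold (default 0.8).
#' @param athlete_ids Optional ids to prepend as a column.
#' @return Data frame with athlete id (when given), six LC columns, six flag
#'   columns and `asps`.
#' @export
attribute_sources <- function(model, features, threshold = 0.8, athlete_ids = NULL) {
  feats <- as.data.frame(features, check.names = FALSE)
  if (is.null(athlete_ids) && "athlete_id" %in% names(feats)) {
    athlete_ids <- feats$athlete_id
  }
  lc <- decompose_lc(model, feats)
  flags <- flag_sources(lc, threshold)
  out <- cbind(lc[paste0("lc_", .SOURCES)], flags, asps = lc$asps)
  if (!is.null(athlete_ids)) out <- cbind(athlete_id = athlete_ids, out)
  rownames(out) <- NULL
  out
}

#' Calibrate ASPS thresholds against false-positive-rate targets
#'
#' For each FPR target, picks the smallest score threshold whose empirical
#' FPR on the negatives (fraction of negatives with score strictly above the
#' threshold) does not exceed the target — i.e. the threshold achieving the
#' largest TPR subject to FPR <= target. Reports achieved FPR, TPR and the
#' number and percentage of all athletes flagged.
#'
#' @param scores Per-athlete ASPS values.
#' @param labels Binary 0/1; both classes required.
#' @param fpr_targets FPR targets in (0, 1); default `c(0.05, 0.10, 0.20)`.
#' @return Data frame: `target_fpr`, `threshold`, `fpr`, `tpr`, `n_flagged`,
#'   `pct_flagged`.
#' @export
calibrate_thresholds <- function(scores, labels, fpr_targets = c(0.05, 0.10, 0.20)) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (!any(labels == 1L) || !any(labels == 0L)) stop("both classes must be present")
  if (any(fpr_targets <= 0 | fpr_targets >= 1)) stop("fpr targets must lie in (0,1)")
  neg <- scores[labels == 0L]
  pos <- scores[labels == 1L]
  n_neg <- length(neg)
  cand <- sort(unique(scores))
  fpr_at <- vapply(cand, function(th) mean(neg > th), numeric(1))
  rows <- lapply(fpr_targets, function(target) {
    if (target < 1 / n_neg) {
      warning(sprintf("FPR target %.3g unattainable with %d negatives; reporting the zero-FPR threshold",
                      target, n_neg))
    }
    ok <- which(fpr_at <= target)
    th <- cand[min(ok)]
    data.frame(target_fpr = target, threshold = th,
               fpr = mean(neg > th), tpr = mean(pos > th),
               n_flagged = sum(scores > th),
               pct_flagged = 100 * mean(scores > th))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
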