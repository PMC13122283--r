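# Whole-trajectory summary features: per-biomarker means, ranges, ranges of
# first and second differences, pairwise covariances of levels and of first
# differences, plus the square of every base feature (40 base + 40 squares).

#' First differences of a series
#'
#' @param series Ordered numeric vector, length >= 2.
#' @return Vector of length `length(series) - 1`, element j equal to
#'   `series[j + 1] - series[j]`.
#' @export
#' @examples
#' first_differences(c(1, 3, 2))
first_differences <- function(series) {
  if (length(series) < 2L) stop("insufficient length: need >= 2 values to difference")
  diff(series)
}

#' Range (max minus min) of a series
#'
#' @param series Numeric vector, length >= 1; a singleton has range 0.
#' @return Non-negative scalar `max(series) - min(series)`.
#' @export
feature_range <- function(series) {
  if (length(series) < 1L) stop("insufficient length: need >= 1 value for a range")
  max(series) - min(series)
}

#' Sample covariance of two equal-length series
#'
#' Uses the unbiased n - 1 denominator.
#'
#' @param a,b Numeric vectors of equal length >= 2.
#' @return The sample covariance.
#' @export
pairwise_covariance <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch between series")
  if (length(a) < 2L) stop("insufficient length: need >= 2 paired values for a covariance")
  stats::cov(a, b)
}

# Fixed 80-name feature schema, with the source tag used by the LC
# decomposition: single-biomarker features map to that biomarker, every
# covariance feature (levels or differences) maps to the pooled "cov" source.
# Order: means, ranges, ranges of first differences, ranges of second
# differences (each in the fixed biomarker order), level covariances and
# first-difference covariances (pairs in lexicographic key order), then the
# squares of all 40 in the same order.
feature_schema <- local({
  schema <- NULL
  function() {
    if (!is.null(schema)) return(schema)
    bm <- biomarker_keys()
    pairs <- utils::combn(sort(bm), 2L)
    base <- data.frame(
      name = c(paste0("mean_", bm), paste0("range_", bm),
               paste0("range_d1_", bm), paste0("range_d2_", bm),
               paste0("cov_", pairs[1L, ], ".", pairs[2L, ]),
               paste0("cov_d1_", pairs[1L, ], ".", pairs[2L, ])),
      source = c(rep(bm, 4L), rep("cov", 2L * ncol(pairs))),
      stringsAsFactors = FALSE
    )
    sq <- transform(base, name = paste0(name, "_sq"))
    schema <<- rbind(cbind(base, squared = FALSE), cbind(sq, squared = TRUE))
    rownames(schema) <<- NULL
    schema
  }
})

#' Names of the 80 trajectory features, in schema order
#'
#' @return Character vector of length 80.
#' @export
feature_names <- function() {
  feature_schema()$name
}

#' Compute the 80-element feature vector of one trajectory
#'
#' `traj` holds one athlete's time-ordered measurements: either the raw ratio
#' values or their sequence probabilities, one column per canonical biomarker
#' key. Occasions with any missing biomarker are dropped (complete-case by
#' occasion) before differencing; at least 4 complete occasions must remain.
#'
#' @param traj Numeric matrix or data frame, occasions x 5 biomarkers, with
#'   column names containing the five canonical keys.
#' @return Named numeric vector of length 80 in [feature_names()] order.
#' @export
#' @examples
#' m <- matrix(rlnorm(20), 4, 5, dimnames = list(NULL, biomarker_keys()))
#' fv <- compute_feature_vector(m)
#' length(fv)
compute_feature_vector <- function(traj) {
  bm <- biomarker_keys()
  x <- as.matrix(as.data.frame(traj)[, bm, drop = FALSE])
  storage.mode(x) <- "double"
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < 4L) {
    stop("insufficient observations: need >= 4 complete occasions, got ", nrow(x))
  }
  d1 <- apply(x, 2L, diff)
  d2 <- apply(d1, 2L, diff)
  pairs <- utils::combn(sort(bm), 2L)
  cov_lv <- stats::cov(x)
  cov_d1 <- stats::cov(d1)
  base <- c(
    colMeans(x),
    apply(x, 2L, feature_range),
    apply(d1, 2L, feature_range),
    apply(rbind(d2), 2L, feature_range),
    cov_lv[cbind(pairs[1L, ], pairs[2L, ])],
    cov_d1[cbind(pairs[1L, ], pairs[2L, ])]
  )
  out <- c(base, base^2)
  names(out) <- feature_names()
  out
}

#' Build the per-athlete feature table from a profiles data frame
#'
#' One row per athlete with the 80 named feature columns, plus `athlete_id`
#' and, when present in `profiles`, per-athlete `label`, `weight` and
#' `source`. Athletes with fewer than `min_obs` complete occasions are
#' dropped with a message.
#'
#' @param profiles Profiles data frame; for `kind = "abp_sp"` it must carry
#'   the `abp_sp_*` columns from [add_sequence_probabilities()].
#' @param kind Measurement kind the features are built from: `"original"`
#'   (raw ratios) or `"abp_sp"` (sequence probabilities).
#' @param min_obs Minimum complete occasions per athlete (default 4).
#' @return Data frame of features, one row per athlete, with attribute
#'   `measurement_kind`.
#' @export
build_features <- function(profiles, kind = c("original", "abp_sp"), min_obs = 4L) {
  kind <- match.arg(kind)
  cols <- if (kind == "original") biomarker_keys() else paste0("abp_sp_", biomarker_keys())
  if (!all(cols %in% names(profiles))) {
    stop("profiles lack required columns: ", paste(setdiff(cols, names(profiles)), collapse = ", "))
  }
  prof <- profiles[order(profiles$athlete_id, profiles$occasion), , drop = FALSE]
  idx <- split(seq_len(nrow(prof)), prof$athlete_id)
  rows <- list(); dropped <- 0L
  for (id in names(idx)) {
    sub <- prof[idx[[id]], , drop = FALSE]
    x <- as.matrix(sub[, cols, drop = FALSE])
    colnames(x) <- biomarker_keys()
    if (sum(stats::complete.cases(x)) < min_obs) {
      dropped <- dropped + 1L
      next
    }
    fv <- compute_feature_vector(x)
    row <- c(list(athlete_id = id), as.list(fv))
    for (extra in c("label", "weight", "source")) {
      if (extra %in% names(sub)) row[[extra]] <- sub[[extra]][1L]
    }
    rows[[id]] <- as.data.frame(row, check.names = FALSE, stringsAsFactors = FALSE)
  }
  if (dropped > 0L) {
    message("build_features: dropped ", dropped, " athlete(s) with fewer than ",
            min_obs, " complete occasions")
  }
  if (length(rows) == 0L) stop("no athlete had enough complete occasions")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "measurement_kind") <- kind
  out
}
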