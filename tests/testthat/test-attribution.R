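# LC source decomposition, the 0.8 flag rule and threshold calibration

# small fitted model on simulated features, reused across blocks; labels are
# shuffled and the regressor set kept small so the fit stays far from
# separation (a saturated logistic makes the logit round-trip ill-posed)
.attr_model <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cohort <- simulate_cohort(simulation_config(n_clean = 40, n_doped = 15,
                                                n_lab = 10, seed = 55))
    feats <- build_features(add_sequence_probabilities(cohort$profiles), kind = "abp_sp")
    set.seed(56)
    feats$label <- sample(feats$label)
    keep <- feature_names()[c(1:10, 21:26, 41:44)]  # means, ranges, covs, squares
    cache <<- list(model = suppressWarnings(
      fit_asps_model(feats, ridge = 0.1, feature_names = keep)),
      features = feats)
    cache
  }
})

test_that("source_of_feature maps features to their biomarker or the covariance pool", {
  expect_equal(source_of_feature("range_te_sq"), "te")
  expect_equal(source_of_feature("mean_adiol_e"), "adiol_e")
  expect_equal(source_of_feature("cov_d1_adiol_ratio.aetio"), "cov")
  expect_equal(source_of_feature("cov_adiol_e.adiol_ratio_sq"), "cov")
  expect_equal(source_of_feature("range_d2_at"), "at")
  expect_error(source_of_feature("range_hemoglobin"), "schema error")
  # every schema name has a source
  expect_true(all(source_of_feature(feature_names()) %in%
                    c(biomarker_keys(), "cov")))
})

test_that("decompose_lc reconstructs the linear predictor from its sources", {
  fit <- .attr_model()
  lc <- decompose_lc(fit$model, fit$features)
  lc_cols <- paste0("lc_", c("te", "aetio", "adiol_ratio", "adiol_e", "at", "cov"))
  eta <- qlogis(lc$asps)
  expect_equal(rowSums(lc[lc_cols]), eta - fit$model$intercept, tolerance = 1e-10)

  # dot-product oracle: independent standardisation and full dot product
  m <- fit$model
  xs <- scale(as.matrix(fit$features[names(m$coefficients)]),
              center = m$centre[names(m$coefficients)],
              scale = m$scale[names(m$coefficients)])
  eta_oracle <- m$intercept + drop(xs %*% m$coefficients)
  expect_equal(rowSums(lc[lc_cols]), eta_oracle - m$intercept, tolerance = 1e-12)
  expect_equal(lc$asps, plogis(eta_oracle), tolerance = 1e-12)
})

test_that("single-term models attribute everything to that feature's source", {
  m <- structure(list(intercept = -1, coefficients = c(range_te = 0.8),
                      centre = c(range_te = 0), scale = c(range_te = 1),
                      measurement_kind = "abp_sp"), class = "asps_model")
  lc <- decompose_lc(m, data.frame(range_te = 1))
  expect_equal(lc$lc_te, 0.8)
  expect_equal(lc$lc_aetio, 0)
  expect_equal(lc$lc_cov, 0)
  expect_equal(lc$asps, plogis(-1 + 0.8))

  # all-zero standardised features: all LCs zero, ASPS = logistic(intercept)
  lc0 <- decompose_lc(m, data.frame(range_te = 0))
  expect_equal(unlist(lc0[paste0("lc_", c("te", "aetio", "adiol_ratio",
                                          "adiol_e", "at", "cov"))]),
               rep(0, 6), ignore_attr = TRUE)
  expect_equal(lc0$asps, plogis(-1))
})

test_that("flag_sources uses a strict 0.8 threshold and reports the odds multiplier", {
  lc <- data.frame(lc_te = c(0.8, 0.81, 0), lc_aetio = 0, lc_adiol_ratio = 2,
                   lc_adiol_e = -1, lc_at = 0, lc_cov = 0.79)
  fl <- flag_sources(lc)
  expect_equal(fl$flag_te, c(0L, 1L, 0L))      # exactly 0.8 is NOT flagged
  expect_equal(fl$flag_adiol_ratio, rep(1L, 3))
  expect_equal(fl$flag_adiol_e, rep(0L, 3))
  expect_equal(fl$flag_cov, rep(0L, 3))
  expect_equal(attr(fl, "odds_multiplier"), exp(0.8))
  expect_equal(round(attr(fl, "odds_multiplier"), 1), 2.2)

  zero <- flag_sources(data.frame(lc_te = 0, lc_aetio = 0, lc_adiol_ratio = 0,
                                  lc_adiol_e = 0, lc_at = 0, lc_cov = 0))
  expect_true(all(unlist(zero) == 0L))
})

test_that("attribute_sources returns ids, LCs, flags and ASPS per athlete", {
  fit <- .attr_model()
  att <- attribute_sources(fit$model, fit$features)
  expect_equal(nrow(att), nrow(fit$features))
  expect_true(all(c("athlete_id", "lc_te", "flag_te", "flag_cov", "asps") %in% names(att)))
  expect_true(all(att$asps > 0 & att$asps < 1))
  expect_equal(att$flag_te, as.integer(att$lc_te > 0.8))
})

test_that("calibrate_thresholds maximises TPR subject to the FPR cap", {
  # perfectly separated scores
  sep <- calibrate_thresholds(c(rep(0.1, 50), rep(0.9, 10)),
                              rep(c(0, 1), c(50, 10)), fpr_targets = 0.05)
  expect_equal(sep$fpr, 0)
  expect_equal(sep$tpr, 1)

  # scores equal to labels, 10% positives
  sl <- calibrate_thresholds(rep(c(0, 1), c(90, 10)), rep(c(0, 1), c(90, 10)),
                             fpr_targets = 0.05)
  expect_equal(sl$fpr, 0)
  expect_equal(sl$tpr, 1)
  expect_equal(sl$n_flagged, 10)

  # exhaustive sweep oracle on overlapping uniforms
  set.seed(77)
  scores <- c(runif(1000), runif(100, 0.5, 1))
  labels <- rep(c(0, 1), c(1000, 100))
  row <- calibrate_thresholds(scores, labels, fpr_targets = 0.10)
  neg <- scores[labels == 0]; pos <- scores[labels == 1]
  cand <- sort(unique(scores))
  feasible <- cand[vapply(cand, function(th) mean(neg > th), 0) <= 0.10]
  th_oracle <- min(feasible)
  expect_equal(row$threshold, th_oracle)
  expect_equal(row$tpr, mean(pos > th_oracle))
  expect_lt(abs(row$threshold - 0.9), 0.03)
  expect_lt(abs(row$tpr - 0.2), 0.08)

  expect_warning(calibrate_thresholds(scores[1:15], labels[c(1:10, 1001:1005)],
                                      fpr_targets = 0.01), "unattainable")
  expect_error(calibrate_thresholds(scores, labels, fpr_targets = 1.2), "targets")
  expect_error(calibrate_thresholds(rep(0.2, 5), rep(0, 5), 0.1), "both classes")
})

test_that("lower thresholds never decrease FPR or TPR, and flag counts are consistent", {
  set.seed(78)
  scores <- runif(400)
  labels <- rbinom(400, 1, plogis(3 * scores - 2))
  labels[1:2] <- c(0, 1)
  sweep_t <- calibrate_thresholds(scores, labels,
                                  fpr_targets = seq(0.05, 0.95, by = 0.05))
  ord <- order(sweep_t$threshold, decreasing = TRUE)
  expect_true(all(diff(sweep_t$fpr[ord]) >= 0))
  expect_true(all(diff(sweep_t$tpr[ord]) >= 0))
  expect_equal(sweep_t$n_flagged,
               vapply(sweep_t$threshold, function(th) sum(scores > th), 0L))
  expect_equal(sweep_t$pct_flagged, 100 * sweep_t$n_flagged / length(scores))
})
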