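# Weighted logistic ASPS model, selection, AUC and cross-validation

test_that("standardise_features centres, scales and drops degenerate columns", {
  x <- cbind(a = c(1, 3), b = c(2, 2))
  expect_warning(std <- standardise_features(x), "zero-variance")
  expect_equal(std$dropped, "b")
  expect_equal(std$x[, "a"], c(-1, 1) / sqrt(2), tolerance = 1e-12)

  set.seed(2)
  x2 <- matrix(rnorm(60, 5, 3), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  std2 <- standardise_features(x2)
  expect_equal(unname(colMeans(std2$x)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(std2$x, 2, sd)), rep(1, 3), tolerance = 1e-12)
  expect_error(standardise_features(x2[1, , drop = FALSE]), "two rows")
})

test_that("symmetric two-point data yields a zero intercept; equal weights match unweighted", {
  feats <- data.frame(f = c(-1, 1))
  m <- fit_asps_model(feats, labels = c(0, 1), ridge = 1e-4)
  expect_lt(abs(m$intercept), 1e-8)

  set.seed(4)
  feats2 <- as.data.frame(matrix(rnorm(200), 50, 4))
  names(feats2) <- paste0("f", 1:4)
  y <- rbinom(50, 1, plogis(feats2$f1 - feats2$f3))
  m_w <- fit_asps_model(feats2, labels = y, weights = rep(3, 50), ridge = 0)
  m_u <- fit_asps_model(feats2, labels = y, ridge = 0)
  # weights rescale the likelihood without moving its maximiser
  expect_equal(m_w$coefficients, m_u$coefficients, tolerance = 1e-7)
  expect_equal(m_w$intercept, m_u$intercept, tolerance = 1e-7)

  expect_error(fit_asps_model(feats2, labels = rep(1, 50)), "degenerate labels")
})

test_that("fit matches an independent BFGS optimiser on a 6-point dataset", {
  # interleaved labels in both coordinates keep the MLE finite
  feats <- data.frame(f1 = c(-1.2, 0.4, 1.9, -0.6, 0.8, 2.2),
                      f2 = c(0.5, -1.1, 0.3, 1.4, -0.2, -0.9))
  y <- c(0, 1, 0, 1, 1, 0)
  w <- c(1, 2, 1, 3, 1, 20)
  ridge <- 1e-8
  m <- fit_asps_model(feats, labels = y, weights = w, ridge = ridge)

  # oracle: same standardisation done with base R, then generic optimisation
  xs <- scale(as.matrix(feats))
  x1 <- cbind(1, xs)
  fit <- optim(rep(0, 3), neg_wll, x1 = x1, y = y, w = w, ridge = ridge,
               method = "BFGS", control = list(maxit = 1000, reltol = 1e-14))
  expect_equal(unname(c(m$intercept, m$coefficients)), fit$par, tolerance = 1e-4)
  expect_true(m$converged)
})

test_that("integer weight w equals the fit on w-fold replicated rows", {
  set.seed(9)
  n <- 40
  feats <- data.frame(f1 = rnorm(n), f2 = rnorm(n))
  y <- rbinom(n, 1, plogis(0.8 * feats$f1))
  w <- ifelse(seq_len(n) <= 10, 20, 1)

  rep_idx <- rep(seq_len(n), times = w)
  m_w <- fit_asps_model(feats, labels = y, weights = w, ridge = 0)
  m_r <- fit_asps_model(feats[rep_idx, , drop = FALSE], labels = y[rep_idx], ridge = 0)
  # the standardisation differs between the two data sets, so compare on the
  # raw-feature scale where the unpenalised MLE is affine-invariant
  expect_equal(m_w$coefficients / m_w$scale, m_r$coefficients / m_r$scale,
               tolerance = 1e-8)
  expect_equal(predict_asps(m_w, feats), predict_asps(m_r, feats), tolerance = 1e-8)
})

test_that("predict_asps applies the logistic link on the stored scale", {
  m <- structure(list(intercept = -3.2, coefficients = c(f = 0),
                      centre = c(f = 0), scale = c(f = 1),
                      measurement_kind = "abp_sp"), class = "asps_model")
  expect_equal(predict_asps(m, data.frame(f = 0)), plogis(-3.2))
  expect_equal(round(predict_asps(m, data.frame(f = 0)), 4), 0.0392)
  m$intercept <- 0
  expect_equal(predict_asps(m, data.frame(f = 0)), 0.5)
  m$coefficients <- c(f = 1.5)
  p <- predict_asps(m, data.frame(f = c(-1, 0, 2)))
  expect_true(all(diff(p) > 0))
  expect_error(predict_asps(m, data.frame(g = 1)), "schema error")
})

test_that("predictions are invariant to affine rescaling of raw features", {
  set.seed(12)
  feats <- data.frame(f1 = rnorm(30), f2 = rnorm(30, 100, 50))
  y <- rbinom(30, 1, plogis(feats$f1))
  m1 <- fit_asps_model(feats, labels = y, ridge = 0)
  feats2 <- transform(feats, f2 = 1000 * f2 + 5)
  m2 <- fit_asps_model(feats2, labels = y, ridge = 0)
  expect_equal(predict_asps(m1, feats), predict_asps(m2, feats2), tolerance = 1e-8)
})

test_that("backward selection keeps true signals and handles no-op / duplicates", {
  set.seed(31)
  n <- 500
  p_noise <- 20
  hits <- 0L
  reps <- 50L
  for (r in seq_len(reps)) {
    x <- matrix(rnorm(n * (3 + p_noise)), n,
                dimnames = list(NULL, sprintf("f%02d", seq_len(3 + p_noise))))
    y <- rbinom(n, 1, plogis(2 * x[, 1] - 2 * x[, 2] + 1.5 * x[, 3]))
    m <- select_variables(as.data.frame(x), labels = y, target_size = 3L)
    if (all(c("f01", "f02", "f03") %in% names(m$coefficients))) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.95)

  # target_size >= available features is a warning no-op
  feats <- as.data.frame(matrix(rnorm(200), 50, 4))
  y <- rbinom(50, 1, 0.5); y[1:2] <- c(0, 1)
  expect_warning(m_full <- select_variables(feats, labels = y, target_size = 10L),
                 "full model")
  expect_length(m_full$coefficients, 4L)

  # exact duplicate: exactly one of the pair survives
  feats$dup <- feats$V1
  m_dup <- select_variables(feats, labels = y, target_size = 4L)
  expect_equal(sum(c("V1", "dup") %in% names(m_dup$coefficients)), 1L)
})

test_that("auc matches brute-force pair counting and its definitional anchors", {
  expect_equal(auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auc(rep(0.7, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)),
               brute_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)))
  expect_error(auc(1:3, c(1, 1, 1)), "undefined AUC")

  set.seed(21)
  for (r in 1:100) {
    n <- sample(4:25, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # forces ties
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_equal(auc(scores, labels), brute_auc(scores, labels))
  }
})

test_that("auc is invariant under strictly monotone transforms of the scores", {
  set.seed(22)
  scores <- rnorm(60)
  labels <- rbinom(60, 1, 0.4); labels[1:2] <- c(0, 1)
  a0 <- auc(scores, labels)
  expect_equal(auc(exp(scores), labels), a0)
  expect_equal(auc(qlogis(plogis(scores)), labels), a0, tolerance = 1e-12)
  expect_equal(auc(3 * scores - 7, labels), a0)
})

test_that("make_cv_plan stratifies positives evenly and is seed-deterministic", {
  ids <- sprintf("a%02d", 1:50)
  labels <- rep(c(1, 0), c(10, 40))
  plan <- make_cv_plan(ids, labels, K = 5, seed = 3)
  tab <- table(plan$folds$fold, labels[match(plan$folds$athlete_id, ids)])
  expect_equal(unname(tab[, "1"]), rep(2L, 5), ignore_attr = TRUE)
  expect_equal(unname(tab[, "0"]), rep(8L, 5), ignore_attr = TRUE)

  ids2 <- sprintf("b%02d", 1:31)
  labels2 <- rep(c(1, 0), c(11, 20))
  plan2 <- make_cv_plan(ids2, labels2, K = 5, seed = 3)
  pos_counts <- table(plan2$folds$fold[plan2$folds$athlete_id %in% ids2[1:11]])
  expect_equal(sort(as.integer(pos_counts), decreasing = TRUE), c(3L, 2L, 2L, 2L, 2L))

  expect_identical(make_cv_plan(ids, labels, K = 5, seed = 3)$folds, plan$folds)
  expect_error(make_cv_plan(ids, labels, K = 12, seed = 1), "too few positive")

  # laboratory athletes never enter a fold
  src <- rep(c("laboratory", "doping_control"), c(5, 45))
  plan3 <- make_cv_plan(ids, labels, src, K = 5, seed = 1)
  expect_false(any(ids[1:5] %in% plan3$folds$athlete_id))
})

test_that("cross_validated_scores covers every doping-control athlete exactly once", {
  set.seed(14)
  n <- 30
  feats <- data.frame(athlete_id = sprintf("a%02d", 1:n),
                      f1 = rnorm(n), f2 = rnorm(n),
                      label = rep(c(1, 0), c(10, 20)),
                      weight = 1, source = "doping_control",
                      stringsAsFactors = FALSE)
  feats$source[1:5] <- "laboratory"
  feats$weight[1:5] <- 20
  plan <- make_cv_plan(feats$athlete_id, feats$label, feats$source, K = 5, seed = 2)
  sc <- cross_validated_scores(feats, plan, ridge = 1e-6)
  expect_setequal(sc$athlete_id, feats$athlete_id[feats$source == "doping_control"])
  expect_equal(anyDuplicated(sc$athlete_id), 0L)
  expect_false(any(feats$athlete_id[feats$source == "laboratory"] %in% sc$athlete_id))

  bad_plan <- plan
  bad_plan$folds <- bad_plan$folds[-1, ]
  expect_error(cross_validated_scores(feats, bad_plan), "inconsistent plan")
})

test_that("the pipeline discriminates strongly doped cohorts out of fold", {
  # strong injected effects: the two 200-mg intramuscular regimes only
  cfg <- simulation_config(n_clean = 100, n_doped = 25, n_lab = 15, seed = 33,
                           regimes = default_regimes()[3:4, ])
  cohort <- simulate_cohort(cfg)
  prof <- add_sequence_probabilities(cohort$profiles)
  feats <- build_features(prof, kind = "abp_sp")
  plan <- make_cv_plan(feats$athlete_id, feats$label, feats$source, K = 5, seed = 33)
  sc <- suppressWarnings(cross_validated_scores(feats, plan))
  expect_gt(auc(sc$score, sc$label), 0.9)
})

test_that("max_score_per_athlete takes per-group maxima", {
  expect_equal(unname(max_score_per_athlete(c(0.2, 0.9, 0.4), rep("a", 3))), 0.9)
  expect_equal(unname(max_score_per_athlete(0.3, "a")), 0.3)
  s <- max_score_per_athlete(c(0.2, 0.5, 0.8), c("a", "a", "b"))
  s2 <- max_score_per_athlete(c(0.2, 0.5, 0.6, 0.8), c("a", "a", "a", "b"))
  expect_gte(s2[["a"]], s[["a"]])
  expect_error(max_score_per_athlete(numeric(0), character(0)), "empty group")
})
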