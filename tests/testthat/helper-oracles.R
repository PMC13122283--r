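# Independent oracles and small fixture builders shared across test files.
# Each oracle re-implements the quantity from its literal definition, on a
# code path disjoint from the package implementation it checks.

# Closed-form conjugate posterior after absorbing all of `logs` at once:
# precision adds n/sigma2_w to the prior, the mean is the precision-weighted
# combination of mu0 and the sum of the log observations.
batch_posterior <- function(mu0, tau2, sigma2_w, logs) {
  n <- length(logs)
  v <- 1 / (1 / tau2 + n / sigma2_w)
  m <- v * (mu0 / tau2 + sum(logs) / sigma2_w)
  list(m = m, v = v)
}

# Literal-definition re-implementation of the 80 trajectory features using
# explicit loops; follows the written recipe, not the package code.
brute_features <- function(x) {
  bm <- colnames(x)
  n <- nrow(x)
  rng <- function(v) max(v) - min(v)
  d1 <- function(v) vapply(seq_len(length(v) - 1L), function(j) v[j + 1L] - v[j], 0)
  scov <- function(a, b) {
    ma <- sum(a) / length(a); mb <- sum(b) / length(b)
    s <- 0
    for (j in seq_along(a)) s <- s + (a[j] - ma) * (b[j] - mb)
    s / (length(a) - 1L)
  }
  out <- c()
  for (k in bm) out[paste0("mean_", k)] <- sum(x[, k]) / n
  for (k in bm) out[paste0("range_", k)] <- rng(x[, k])
  for (k in bm) out[paste0("range_d1_", k)] <- rng(d1(x[, k]))
  for (k in bm) out[paste0("range_d2_", k)] <- rng(d1(d1(x[, k])))
  pairs <- combn(sort(bm), 2L)
  for (j in seq_len(ncol(pairs))) {
    out[paste0("cov_", pairs[1L, j], ".", pairs[2L, j])] <-
      scov(x[, pairs[1L, j]], x[, pairs[2L, j]])
  }
  for (j in seq_len(ncol(pairs))) {
    out[paste0("cov_d1_", pairs[1L, j], ".", pairs[2L, j])] <-
      scov(d1(x[, pairs[1L, j]]), d1(x[, pairs[2L, j]]))
  }
  sq <- out^2
  names(sq) <- paste0(names(out), "_sq")
  c(out, sq)
}

# Brute-force AUC: exhaustive positive x negative pair counting with the
# midrank tie convention.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Negative penalised weighted Bernoulli log likelihood on an already
# standardised design; minimised by optim() as the independent fit oracle.
neg_wll <- function(beta, x1, y, w, ridge) {
  eta <- drop(x1 %*% beta)
  pen <- c(0, rep(ridge, length(beta) - 1L))
  -(sum(w * (y * eta - log(1 + exp(eta)))) - sum(pen * beta^2) / 2)
}

# Random trajectory matrix fixture
random_trajectory <- function(T = 8L) {
  matrix(stats::rlnorm(T * 5L), T, 5L, dimnames = list(NULL, asps::biomarker_keys()))
}

# Small doped/clean cohort with matched trajectory lengths between clean and
# doped athletes (so a zero-effect world really carries no signal).
matched_config <- function(..., seed) {
  base <- asps::simulation_config(seed = seed, ...)
  asps::simulation_config(
    ...,
    occasions = base$baseline_occasions + base$dosed_occasions + base$washout_occasions,
    seed = seed
  )
}

# A regime table with all effects zero (true null world)
null_regimes <- function() {
  r <- asps::default_regimes()
  r[asps::biomarker_keys()] <- 0
  r
}

# Simulate a cohort and return the cross-validated AUC of the ABP-SP
# weighted logistic pipeline on its doping-control athletes.
cv_auc_of <- function(sim_cfg, cv_seed = sim_cfg$seed) {
  cohort <- asps::simulate_cohort(sim_cfg)
  prof <- cohort$profiles
  dc <- prof[prof$source == "doping_control", , drop = FALSE]
  prof <- asps::add_sequence_probabilities(prof, asps::estimate_priors(dc))
  feats <- asps::build_features(prof, kind = "abp_sp")
  plan <- asps::make_cv_plan(feats$athlete_id, feats$label, feats$source,
                             K = 5, seed = cv_seed)
  sc <- suppressWarnings(asps::cross_validated_scores(feats, plan))
  asps::auc(sc$score, sc$label)
}
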