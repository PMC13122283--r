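# Bayesian adaptive longitudinal model per biomarker, and the sequence
# probability transform z = F(y) where F is the posterior predictive CDF of
# the next log measurement given the athlete's history.
#
# Model: log y_t = theta + eps_t, theta ~ N(mu0, tau2), eps_t ~ N(0, sigma2_w),
# with tau2 (between-athlete) and sigma2_w (within-athlete) treated as known.
# The posterior for theta after n observations is conjugate normal, so the
# predictive for the next log measurement is N(m_n, v_n + sigma2_w).

.Z_EPS <- 1e-12
.VAR_FLOOR <- 1e-6

#' Population prior for one biomarker
#'
#' Hyperparameters of the normal-normal hierarchy on the log-ratio scale.
#'
#' @param mu0 Population mean of the log ratio.
#' @param tau2 Between-athlete variance of the athlete-level log mean (> 0).
#' @param sigma2_w Within-athlete (occasion-to-occasion) variance (> 0).
#' @return An object of class `population_prior`.
#' @export
#' @examples
#' population_prior(0, 1, 1)
population_prior <- function(mu0, tau2, sigma2_w) {
  if (!is.numeric(mu0) || length(mu0) != 1L || !is.finite(mu0)) {
    stop("invalid prior: mu0 must be a finite number")
  }
  if (!is.numeric(tau2) || length(tau2) != 1L || !is.finite(tau2) || tau2 <= 0) {
    stop("invalid prior: tau2 must be > 0")
  }
  if (!is.numeric(sigma2_w) || length(sigma2_w) != 1L || !is.finite(sigma2_w) || sigma2_w <= 0) {
    stop("invalid prior: sigma2_w must be > 0")
  }
  structure(list(mu0 = mu0, tau2 = tau2, sigma2_w = sigma2_w),
            class = "population_prior")
}

#' @export
print.population_prior <- function(x, ...) {
  cat(sprintf("population prior: mu0 = %.4g, tau2 = %.4g, sigma2_w = %.4g\n",
              x$mu0, x$tau2, x$sigma2_w))
  invisible(x)
}

#' Initialise a predictive state
#'
#' @param prior A [population_prior()].
#' @return A `predictive_state`: posterior mean `m`, posterior variance `v` of
#'   the athlete-level log mean, observation count `n_obs`, and the prior.
#' @export
init_state <- function(prior) {
  if (!inherits(prior, "population_prior")) {
    prior <- do.call(population_prior, as.list(prior)[c("mu0", "tau2", "sigma2_w")])
  }
  structure(list(n_obs = 0L, m = prior$mu0, v = prior$tau2, prior = prior),
            class = "predictive_state")
}

.check_measurement <- function(y) {
  if (!is.numeric(y) || length(y) != 1L || !is.finite(y) || y <= 0) {
    stop("invalid measurement: ratio values must be finite and > 0")
  }
  invisible(y)
}

#' Posterior predictive sequence probability of a measurement
#'
#' Evaluates z = Phi((log y - m) / sqrt(v + sigma2_w)), the predictive CDF of
#' the athlete's next log measurement at the observed value. Values near 0
#' mean the measurement is much lower than the passport expects, near 1 much
#' higher. The result is clamped to (1e-12, 1 - 1e-12).
#'
#' @param state A `predictive_state`.
#' @param y Strictly positive measurement on the ratio scale.
#' @return The sequence probability, a number strictly inside (0, 1).
#' @export
#' @examples
#' st <- init_state(population_prior(0, 1, 1))
#' predictive_cdf(st, 1)  # log 1 = prior mean, so 0.5
predictive_cdf <- function(state, y) {
  stopifnot(inherits(state, "predictive_state"))
  .check_measurement(y)
  sd_pred <- sqrt(state$v + state$prior$sigma2_w)
  z <- stats::pnorm((log(y) - state$m) / sd_pred)
  min(max(z, .Z_EPS), 1 - .Z_EPS)
}

#' Absorb a measurement into the predictive state
#'
#' Conjugate normal update of the athlete-level posterior on the log scale:
#' precisions add, and the posterior mean is the precision-weighted average of
#' the current mean and log y.
#'
#' @inheritParams predictive_cdf
#' @return The updated `predictive_state` with `n_obs` incremented and `v`
#'   strictly decreased.
#' @export
update_state <- function(state, y) {
  stopifnot(inherits(state, "predictive_state"))
  .check_measurement(y)
  s2w <- state$prior$sigma2_w
  prec <- 1 / state$v + 1 / s2w
  v_new <- 1 / prec
  m_new <- v_new * (state$m / state$v + log(y) / s2w)
  structure(list(n_obs = state$n_obs + 1L, m = m_new, v = v_new,
                 prior = state$prior),
            class = "predictive_state")
}

#' Prequential sequence probabilities for a series
#'
#' Each observation is scored with [predictive_cdf()] under the state built
#' from strictly earlier observations, then absorbed with [update_state()];
#' the first observation is scored under the pure population prior. This
#' prequential order guarantees a measurement never informs its own reference
#' range, and makes the z-values of data generated from the hierarchy i.i.d.
#' Uniform(0, 1).
#'
#' @param series Ordered vector of strictly positive ratio measurements.
#' @param prior A [population_prior()].
#' @return Numeric vector of sequence probabilities, same length as `series`.
#' @export
sequence_probabilities <- function(series, prior) {
  if (length(series) == 0L) stop("empty input: series must contain at least one value")
  state <- init_state(prior)
  z <- numeric(length(series))
  for (t in seq_along(series)) {
    z[t] <- predictive_cdf(state, series[t])
    state <- update_state(state, series[t])
  }
  z
}

#' Estimate a population prior from longitudinal profiles
#'
#' Method-of-moments estimator on the log scale: `mu0` is the grand mean of
#' per-athlete log means, `sigma2_w` the pooled within-athlete variance, and
#' `tau2` the variance of per-athlete log means minus the sampling
#' contribution `sigma2_w / harmonic mean(n_i)`. Both variances are floored
#' at 1e-6.
#'
#' @param profiles A profiles data frame (see [read_profiles()]) with an
#'   `athlete_id` column and one column per canonical biomarker key.
#' @param key Canonical biomarker key to estimate.
#' @return A [population_prior()].
#' @export
estimate_prior <- function(profiles, key) {
  key <- canonical_biomarker(key)
  if (!key %in% names(profiles)) stop("profiles lack biomarker column: ", key)
  vals <- log(profiles[[key]])
  ids <- profiles$athlete_id
  keep <- is.finite(vals)
  vals <- vals[keep]; ids <- ids[keep]
  n_i <- table(ids)
  n_i <- n_i[n_i >= 2L]
  if (length(n_i) < 2L) {
    stop("estimation error: need >= 2 athletes with >= 2 observations each")
  }
  use <- ids %in% names(n_i)
  vals <- vals[use]; ids <- factor(ids[use], levels = names(n_i))
  means_i <- tapply(vals, ids, mean)
  vars_i <- tapply(vals, ids, stats::var)
  n_i <- as.numeric(n_i)
  sigma2_w <- max(sum((n_i - 1) * vars_i) / sum(n_i - 1), .VAR_FLOOR)
  n_harm <- length(n_i) / sum(1 / n_i)
  tau2 <- max(stats::var(means_i) - sigma2_w / n_harm, .VAR_FLOOR)
  population_prior(mu0 = mean(means_i), tau2 = tau2, sigma2_w = sigma2_w)
}

#' Estimate priors for all five biomarkers
#'
#' @inheritParams estimate_prior
#' @return Named list of [population_prior()] objects, one per biomarker key.
#' @export
estimate_priors <- function(profiles) {
  stats::setNames(lapply(biomarker_keys(), function(k) estimate_prior(profiles, k)),
                  biomarker_keys())
}

#' Add sequence-probability columns to a profiles table
#'
#' Computes the prequential sequence probability of every measurement within
#' each athlete (occasions processed in increasing order) and stores it in a
#' column `abp_sp_<key>` alongside the raw ratio column.
#'
#' @param profiles Profiles data frame with `athlete_id`, `occasion` and the
#'   five biomarker columns.
#' @param priors Named list of [population_prior()] per biomarker key; when
#'   `NULL` (default) priors are estimated from `profiles` with
#'   [estimate_priors()].
#' @return `profiles` with five added `abp_sp_*` columns in (0, 1).
#' @export
add_sequence_probabilities <- function(profiles, priors = NULL) {
  if (is.null(priors)) priors <- estimate_priors(profiles)
  ord <- order(profiles$athlete_id, profiles$occasion)
  prof <- profiles[ord, , drop = FALSE]
  idx <- split(seq_len(nrow(prof)), prof$athlete_id)
  for (k in biomarker_keys()) {
    zcol <- rep(NA_real_, nrow(prof))
    for (rows in idx) {
      zcol[rows] <- sequence_probabilities(prof[[k]][rows], priors[[k]])
    }
    prof[[paste0("abp_sp_", k)]] <- zcol
  }
  # restore the caller's row order
  out <- prof[match(seq_len(nrow(profiles)), ord), , drop = FALSE]
  rownames(out) <- NULL
  out
}
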