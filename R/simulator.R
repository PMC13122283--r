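# Synthetic cohort simulator. Generates clean and doped athlete trajectories
# from the same hierarchy the sequence-probability model assumes: athlete
# random intercepts and within-athlete Gaussian noise on the log-ratio scale,
# plus additive route/dose-specific doping effects that decay exponentially
# through a washout phase. Doped trajectories always contain pre-dose
# baseline and post-dose washout occasions.

#' Default doping regime effects
#'
#' Additive log-scale effects of each administration regime on the five
#' ratios. The transdermal, placebo and the two 200-mg intramuscular regimes
#' use the published mixed-model estimates from a laboratory study of
#' transdermal and intramuscular testosterone; the three weekly
#' self-administered injection regimes (50/75/100 mg) use package defaults
#' chosen to reproduce the reported dose ordering (T/E and 5a-ADiol/E rising
#' with dose, 5a-ADiol/5b-ADiol and A/T responding at 100 mg only).
#'
#' @return Data frame: `regime`, one effect column per biomarker key, and the
#'   washout `half_life` (occasions).
#' @export
default_regimes <- function() {
  data.frame(
    regime = c("transdermal", "placebo", "intramuscular_1", "intramuscular_2",
               "injection_50", "injection_75", "injection_100"),
    te          = c(0.41, 0.32, 2.53, 2.67, 1.20, 1.70, 2.20),
    aetio       = c(-0.05, -0.02, -0.02, 0.11, 0.00, 0.00, 0.05),
    adiol_ratio = c(0.16, 0.10, -0.07, -0.08, 0.00, 0.00, 0.30),
    adiol_e     = c(0.48, 0.31, 1.93, 2.10, 0.50, 0.90, 1.30),
    at          = c(-0.11, -0.14, -0.33, -0.29, 0.00, 0.00, -0.20),
    half_life = 3,
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' The stated world the tests run in. Log-scale population means reflect
#' typical urinary ratio levels (T/E about 1, A/Etio about 1,
#' 5a-ADiol/5b-ADiol about 0.9, 5a-ADiol/E about 5, A/T about 40);
#' between-athlete SD 0.5 and within-athlete SD 0.3 on the log scale give the
#' order of heterogeneity seen in steroid passport data. Athlete-level doping
#' responses vary around the regime effect with SD `effect_sd` for T/E and
#' 5a-ADiol/E — the pair correlated at `effect_cor = sqrt(0.52)` — and SD
#' `effect_sd_other` for the remaining ratios.
#'
#' @param n_clean,n_doped Doping-control athletes without/with a true doping
#'   regime (labels 0/1, weight 1).
#' @param n_lab Laboratory athletes: known dopers, label 1, weight
#'   `lab_weight`.
#' @param occasions Occasions per clean athlete.
#' @param baseline_occasions,dosed_occasions,washout_occasions Structure of a
#'   doped trajectory.
#' @param mu0 Named population log-means per biomarker key.
#' @param tau Named between-athlete SDs (log scale).
#' @param sigma_w Named within-athlete SDs (log scale).
#' @param effect_sd SD of the athlete-level T/E and 5a-ADiol/E response.
#' @param effect_sd_other SD of the other three responses.
#' @param effect_cor Correlation of the T/E and 5a-ADiol/E responses.
#' @param regimes Regime-effect table as in [default_regimes()].
#' @param lab_weight Loss weight of laboratory athletes (default 20).
#' @param seed Integer seed making the cohort reproducible.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_clean = 200L, n_doped = 40L, n_lab = 30L,
                              occasions = 12L,
                              baseline_occasions = 3L, dosed_occasions = 6L,
                              washout_occasions = 5L,
                              mu0 = log(c(te = 1, aetio = 1, adiol_ratio = 0.9,
                                          adiol_e = 5, at = 40)),
                              tau = c(te = 0.5, aetio = 0.5, adiol_ratio = 0.5,
                                      adiol_e = 0.5, at = 0.5),
                              sigma_w = c(te = 0.3, aetio = 0.3, adiol_ratio = 0.3,
                                          adiol_e = 0.3, at = 0.3),
                              effect_sd = 0.3, effect_sd_other = 0.1,
                              effect_cor = sqrt(0.52),
                              regimes = default_regimes(),
                              lab_weight = 20, seed = 1L) {
  bm <- biomarker_keys()
  cfg <- list(n_clean = as.integer(n_clean), n_doped = as.integer(n_doped),
              n_lab = as.integer(n_lab), occasions = as.integer(occasions),
              baseline_occasions = as.integer(baseline_occasions),
              dosed_occasions = as.integer(dosed_occasions),
              washout_occasions = as.integer(washout_occasions),
              mu0 = mu0[bm], tau = tau[bm], sigma_w = sigma_w[bm],
              effect_sd = effect_sd, effect_sd_other = effect_sd_other,
              effect_cor = effect_cor, regimes = regimes,
              lab_weight = lab_weight, seed = as.integer(seed))
  if (any(is.na(unlist(cfg$mu0))) || any(is.na(cfg$tau)) || any(is.na(cfg$sigma_w))) {
    stop("invalid config: mu0, tau and sigma_w must name all five biomarkers")
  }
  if (any(cfg$tau <= 0) || any(cfg$sigma_w <= 0)) stop("invalid config: SDs must be > 0")
  if (abs(effect_cor) > 1) stop("invalid config: effect correlation must lie in [-1, 1]")
  if (any(c(cfg$n_clean, cfg$n_doped, cfg$n_lab) < 0L)) stop("invalid config: counts must be >= 0")
  if (cfg$occasions < 1L || cfg$baseline_occasions < 1L || cfg$dosed_occasions < 1L) {
    stop("invalid config: occasion counts must be >= 1")
  }
  need <- c("regime", bm, "half_life")
  if (!all(need %in% names(cfg$regimes))) stop("invalid config: malformed regime table")
  if (any(cfg$regimes$half_life <= 0)) stop("invalid config: half-life must be > 0")
  structure(cfg, class = "simulation_config")
}

# athlete-level doping response: regime effect plus correlated athlete noise
.draw_effects <- function(config, regime_row) {
  bm <- biomarker_keys()
  eff <- unlist(regime_row[bm])
  sd_vec <- stats::setNames(rep(config$effect_sd_other, 5L), bm)
  sd_vec[c("te", "adiol_e")] <- config$effect_sd
  z <- stats::rnorm(5L)
  names(z) <- bm
  rho <- config$effect_cor
  z["adiol_e"] <- rho * z["te"] + sqrt(1 - rho^2) * z["adiol_e"]
  eff + sd_vec * z
}

#' Simulate one athlete's longitudinal profile
#'
#' Log value at occasion t = population mean + athlete intercept +
#' regime effect x decay(t) + within-athlete noise, exponentiated to the
#' ratio scale. Doped athletes (non-`NULL` `regime`) get
#' baseline / dosed / washout phases; the effect is full during dosing and
#' decays as `2^(-s / half_life)` through the `s`-th washout occasion.
#' Draws from the current RNG stream; seed at the cohort level.
#'
#' @param config A [simulation_config()].
#' @param regime A row of the regime table, or `NULL` for a clean athlete.
#' @param athlete_id Id string stamped on the rows.
#' @return Data frame: `athlete_id`, `occasion` (1-based), `phase`, and the
#'   five biomarker columns (strictly positive).
#' @export
simulate_athlete <- function(config, regime = NULL, athlete_id = "ath_1") {
  stopifnot(inherits(config, "simulation_config"))
  bm <- biomarker_keys()
  if (is.null(regime)) {
    decay <- rep(0, config$occasions)
    phase <- rep("baseline", config$occasions)
    eff <- stats::setNames(rep(0, 5L), bm)
  } else {
    decay <- c(rep(0, config$baseline_occasions),
               rep(1, config$dosed_occasions),
               2^(-(seq_len(config$washout_occasions)) / regime$half_life))
    phase <- c(rep("baseline", config$baseline_occasions),
               rep("dosed", config$dosed_occasions),
               rep("washout", config$washout_occasions))
    eff <- .draw_effects(config, regime)
  }
  n_occ <- length(decay)
  intercept <- stats::rnorm(5L, 0, config$tau)
  logs <- matrix(config$mu0, n_occ, 5L, byrow = TRUE) +
    matrix(intercept, n_occ, 5L, byrow = TRUE) +
    outer(decay, eff) +
    matrix(stats::rnorm(n_occ * 5L, 0, rep(config$sigma_w, each = n_occ)), n_occ, 5L)
  out <- data.frame(athlete_id = athlete_id, occasion = seq_len(n_occ),
                    phase = phase, stringsAsFactors = FALSE)
  out[bm] <- exp(logs)
  out
}

#' Simulate a full cohort
#'
#' `n_lab` doped laboratory athletes (label 1, weight `lab_weight`),
#' `n_doped` doped and `n_clean` clean doping-control athletes (weight 1).
#' Doped athletes draw their regime uniformly from the regime table. Fully
#' reproducible from `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return Object of class `asps_cohort`: `profiles` (long table of occasions
#'   with `label`, `weight`, `source` stamped per athlete), `truth`
#'   (per-athlete label / regime / source) and the generating `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    specs <- data.frame(
      athlete_id = sprintf("ath_%04d", seq_len(config$n_lab + config$n_doped + config$n_clean)),
      source = rep(c("laboratory", "doping_control", "doping_control"),
                   c(config$n_lab, config$n_doped, config$n_clean)),
      label = rep(c(1L, 1L, 0L), c(config$n_lab, config$n_doped, config$n_clean)),
      stringsAsFactors = FALSE
    )
    specs$weight <- ifelse(specs$source == "laboratory", config$lab_weight, 1)
    n_dope <- config$n_lab + config$n_doped
    specs$regime <- NA_character_
    if (n_dope > 0L) {
      specs$regime[seq_len(n_dope)] <-
        config$regimes$regime[sample.int(nrow(config$regimes), n_dope, replace = TRUE)]
    }
    profs <- vector("list", nrow(specs))
    for (i in seq_len(nrow(specs))) {
      reg <- if (is.na(specs$regime[i])) NULL else
        config$regimes[config$regimes$regime == specs$regime[i], , drop = FALSE]
      p <- simulate_athlete(config, reg, specs$athlete_id[i])
      p$label <- specs$label[i]
      p$weight <- specs$weight[i]
      p$source <- specs$source[i]
      profs[[i]] <- p
    }
    structure(list(profiles = do.call(rbind, profs), truth = specs, config = config),
              class = "asps_cohort")
  })
}

#' @export
print.asps_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d athletes (%d laboratory, %d doped dc, %d clean dc), seed %d\n",
              nrow(x$truth), x$config$n_lab, x$config$n_doped, x$config$n_clean,
              x$config$seed))
  invisible(x)
}

#' Recover the doping effects from a simulated cohort
#'
#' Change-from-baseline estimator: for each doped athlete, the mean dosed
#' log value minus the mean baseline log value; averaged per regime and
#' biomarker, with a normal-approximation standard error.
#'
#' @param cohort An [simulate_cohort()] result.
#' @return Data frame: `regime`, `biomarker`, `estimate`, `se`, `n_athletes`.
#' @export
recover_effects <- function(cohort) {
  stopifnot(inherits(cohort, "asps_cohort"))
  doped <- cohort$truth[!is.na(cohort$truth$regime), , drop = FALSE]
  if (nrow(doped) == 0L) stop("no doped athletes in the cohort")
  prof <- cohort$profiles
  bm <- biomarker_keys()
  rows <- list()
  for (rg in unique(doped$regime)) {
    ids <- doped$athlete_id[doped$regime == rg]
    deltas <- sapply(ids, function(id) {
      sub <- prof[prof$athlete_id == id, , drop = FALSE]
      vapply(bm, function(k) {
        mean(log(sub[[k]][sub$phase == "dosed"])) -
          mean(log(sub[[k]][sub$phase == "baseline"]))
      }, numeric(1))
    })
    deltas <- matrix(deltas, nrow = length(bm), dimnames = list(bm, ids))
    rows[[rg]] <- data.frame(
      regime = rg, biomarker = bm,
      estimate = rowMeans(deltas),
      se = apply(deltas, 1L, stats::sd) / sqrt(length(ids)),
      n_athletes = length(ids),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
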