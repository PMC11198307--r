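#' Attribute mix of the synthetic meta-analysis
#'
#' Marginal distributions for trial attributes, tuned to the profile of the
#' antithrombotic-trial literature the generator emulates: roughly a fifth of
#' comparisons from East Asia, enrollment years spread over 2001-2020 (about
#' half starting 2010 or earlier), follow-up clustered at 12 months with a
#' right tail to 36, TIMI and BARC the dominant bleeding definitions, and
#' endpoint reporting incomplete (major/minor bleeding and cardiovascular
#' death are the most often missing, so endpoint-specific pair counts differ).
#'
#' @return Named list of sampling weights and reporting probabilities.
#' @export
default_attribute_mix <- function() {
  list(
    p_east_asia = 0.22,
    p_acs = 0.5,
    years = 2001:2020,
    follow_up_months = c(1, 3, 6, 12, 12, 12, 15, 18, 24, 30, 36),
    mm_definitions = c(barc_235 = 0.25, barc_2345 = 0.08,
                       timi_major_minor = 0.33, other = 0.34),
    major_definitions = c(barc_35 = 0.30, barc_345 = 0.06, timi_major = 0.48,
                          gusto_mod_severe = 0.06, other = 0.10),
    p_report = c(bleed_major = 0.92, bleed_major_minor = 0.75,
                 death_all = 0.98, death_cv = 0.85),
    p_reported_hr = 0.6)
}

#' Configuration of the synthetic-trial generator
#'
#' Trial-level treatment effects (log-OR scale) are drawn from a bivariate
#' normal with correlation `rho_trial`; arm-level event counts are binomial
#' around logit-shifted control risks; trial sizes are log-uniform to mimic
#' the heavy right tail of real trial sizes. Defaults emulate a meta-analysis
#' of 58 comparisons from about 48 randomized trials of at least 500 patients
#' each, with rare bleeding/death outcomes and weak trial-level surrogacy.
#'
#' @param k_trials Number of comparisons generated (>= 4).
#' @param rho_trial True trial-level correlation of the two effects, in
#'   \[-1, 1\]; its square is the estimand of the recovery experiment.
#' @param mu_surrogate,mu_final Mean log-OR treatment effects.
#' @param sd_surrogate,sd_final Between-trial SDs of the true effects (>= 0).
#' @param baseline_risk_surrogate,baseline_risk_final Control-arm event
#'   probabilities for major/minor bleeding and all-cause death (major
#'   bleeding and cardiovascular death use fixed fractions 0.5 and 0.6 of
#'   these).
#' @param baseline_jitter_sd Per-trial logit-scale SD of the control risks.
#' @param n_min,n_max Total trial size range (log-uniform), `n_min >= 500`.
#' @param multi_arm_frac Probability that a comparison is an extra arm of the
#'   previous trial (shares its `trial_id`); default gives ~48 trials per 58
#'   comparisons.
#' @param attribute_mix See [default_attribute_mix()].
#' @param noise_free If `TRUE`, [recovery_experiment()] regresses the true
#'   effects directly, bypassing binomial sampling.
#' @param seed Mandatory integer seed; all randomness flows from it.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(k_trials = 58, rho_trial = 0.3,
                             mu_surrogate = -0.2, mu_final = -0.05,
                             sd_surrogate = 0.35, sd_final = 0.15,
                             baseline_risk_surrogate = 0.05,
                             baseline_risk_final = 0.04,
                             baseline_jitter_sd = 0.3,
                             n_min = 500, n_max = 10000,
                             multi_arm_frac = 10 / 58,
                             attribute_mix = default_attribute_mix(),
                             noise_free = FALSE, seed) {
  if (missing(seed) || !is.finite(seed)) stop("config error: seed is mandatory")
  stopifnot(k_trials >= 4, abs(rho_trial) <= 1,
            sd_surrogate >= 0, sd_final >= 0,
            baseline_risk_surrogate > 0, baseline_risk_surrogate < 1,
            baseline_risk_final > 0, baseline_risk_final < 1,
            n_min >= 500, multi_arm_frac >= 0, multi_arm_frac < 1)
  if (n_min > n_max) stop("config error: n_min > n_max")
  structure(list(k_trials = as.integer(k_trials), rho_trial = rho_trial,
                 mu_surrogate = mu_surrogate, mu_final = mu_final,
                 sd_surrogate = sd_surrogate, sd_final = sd_final,
                 baseline_risk_surrogate = baseline_risk_surrogate,
                 baseline_risk_final = baseline_risk_final,
                 baseline_jitter_sd = baseline_jitter_sd,
                 n_min = n_min, n_max = n_max,
                 multi_arm_frac = multi_arm_frac,
                 attribute_mix = attribute_mix,
                 noise_free = isTRUE(noise_free), seed = as.integer(seed)),
            class = "synthetic_config")
}

# run expr under the config seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic per-comparison dataset
#'
#' For each comparison: true effects `(theta_S, theta_T)` from the bivariate
#' normal; total size log-uniform, split 1:1; the surrogate effect shifts the
#' logit of both bleeding endpoints and the final effect that of both death
#' endpoints; counts are binomial per arm, independent across endpoints given
#' the true effects. Endpoint reporting, definitions, attributes, and a
#' reported hazard ratio for the mortality effect (used by the HR sensitivity
#' track) follow the attribute mix. Identical config and seed give an
#' identical dataset.
#'
#' @param config A [synthetic_config()].
#' @return A validated `trial_comparisons` data frame of `k_trials` rows, with
#'   the true effects attached as attribute `"true_effects"`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  mix <- config$attribute_mix
  k <- config$k_trials
  .with_seed(config$seed, {
    is_repeat <- stats::runif(k) < config$multi_arm_frac
    is_repeat[1] <- FALSE
    trial_idx <- cumsum(!is_repeat)

    z1 <- stats::rnorm(k); z2 <- stats::rnorm(k)
    theta_s <- config$mu_surrogate + config$sd_surrogate * z1
    theta_t <- config$mu_final + config$sd_final *
      (config$rho_trial * z1 + sqrt(1 - config$rho_trial^2) * z2)

    n_total <- pmax(config$n_min,
                    round(exp(stats::runif(k, log(config$n_min),
                                           log(config$n_max)))))
    n_treat <- floor(n_total / 2)
    n_control <- n_total - n_treat

    # per-trial control risks (shared across a multi-arm trial's comparisons)
    jit_s <- stats::rnorm(max(trial_idx), 0, config$baseline_jitter_sd)[trial_idx]
    jit_f <- stats::rnorm(max(trial_idx), 0, config$baseline_jitter_sd)[trial_idx]
    p_ctrl <- list(
      bleed_major_minor = stats::plogis(stats::qlogis(config$baseline_risk_surrogate) + jit_s),
      bleed_major = stats::plogis(stats::qlogis(config$baseline_risk_surrogate * 0.5) + jit_s),
      death_all = stats::plogis(stats::qlogis(config$baseline_risk_final) + jit_f),
      death_cv = stats::plogis(stats::qlogis(config$baseline_risk_final * 0.6) + jit_f))
    theta <- list(bleed_major_minor = theta_s, bleed_major = theta_s,
                  death_all = theta_t, death_cv = theta_t)

    reported <- lapply(setNames(.endpoints, .endpoints), function(ep) {
      stats::runif(k) < mix$p_report[[ep]]
    })
    counts <- list()
    for (ep in .endpoints) {
      pc <- p_ctrl[[ep]]
      pt <- stats::plogis(stats::qlogis(pc) + theta[[ep]])
      te <- stats::rbinom(k, n_treat, pt)
      ce <- stats::rbinom(k, n_control, pc)
      te[!reported[[ep]]] <- NA_integer_
      ce[!reported[[ep]]] <- NA_integer_
      counts[[paste0(ep, "_treat")]] <- te
      counts[[paste0(ep, "_control")]] <- ce
    }

    sample_def <- function(weights, n) {
      sample(names(weights), n, replace = TRUE, prob = weights)
    }
    mm_def <- ifelse(reported$bleed_major_minor,
                     sample_def(mix$mm_definitions, k), "none")
    maj_def <- ifelse(reported$bleed_major,
                      sample_def(mix$major_definitions, k), "none")

    trial_year <- sample(mix$years, max(trial_idx), replace = TRUE)[trial_idx]
    trial_fu <- sample(mix$follow_up_months, max(trial_idx),
                       replace = TRUE)[trial_idx]
    trial_region <- ifelse(stats::runif(max(trial_idx)) < mix$p_east_asia,
                           "east_asia", "non_east_asia")[trial_idx]
    trial_acs <- (stats::runif(max(trial_idx)) < mix$p_acs)[trial_idx]

    df <- data.frame(
      trial_id = sprintf("RCT%03d", trial_idx),
      comparison_id = sprintf("C%03d", seq_len(k)),
      first_enrollment_year = as.integer(trial_year),
      follow_up_months = as.numeric(trial_fu),
      region = trial_region,
      acs_population = trial_acs,
      major_minor_definition = mm_def,
      major_definition = maj_def,
      n_treat = as.integer(n_treat), n_control = as.integer(n_control),
      stringsAsFactors = FALSE)
    for (nm in names(counts)) df[[nm]] <- as.integer(counts[[nm]])
    for (nm in c("reported_or", "reported_or_lo", "reported_or_hi",
                 "reported_hr", "reported_hr_lo", "reported_hr_hi")) {
      df[[nm]] <- NA_real_
    }

    # reported HR for the mortality effect, synthesized from the realized
    # all-cause death table (the HR sensitivity track's input)
    has_hr <- stats::runif(k) < mix$p_reported_hr
    for (i in which(has_hr & reported$death_all)) {
      est <- suppressWarnings(odds_ratio(df$death_all_treat[i], df$n_treat[i],
                                         df$death_all_control[i],
                                         df$n_control[i]))
      if (!est$informative) next
      df$reported_hr[i] <- round(exp(est$log_effect), 3)
      df$reported_hr_lo[i] <- round(exp(est$log_effect - .z975() * est$se), 3)
      df$reported_hr_hi[i] <- round(exp(est$log_effect + .z975() * est$se), 3)
    }
    bad <- !is.na(df$reported_hr) &
      (df$reported_hr < df$reported_hr_lo | df$reported_hr > df$reported_hr_hi)
    df$reported_hr[bad] <- NA_real_
    df$reported_hr_lo[bad] <- NA_real_
    df$reported_hr_hi[bad] <- NA_real_

    out <- trial_comparisons(df)
    attr(out, "true_effects") <- data.frame(
      comparison_id = df$comparison_id, theta_surrogate = theta_s,
      theta_final = theta_t, stringsAsFactors = FALSE)
    out
  })
}

#' Parameter-recovery experiment for the surrogacy estimator chain
#'
#' Repeatedly generates a dataset, builds (surrogate, final) pairs for
#' major/minor bleeding versus all-cause death, runs the patient-weighted
#' regression and the delta-method interval, and summarizes the estimated
#' trial-level R-squared against the generating `rho_trial^2`. Coverage of
#' the interval at `rho_trial^2` is reported, not asserted: the delta method
#' is approximate and binomial sampling error attenuates R-squared below
#' `rho_trial^2` when trials are small relative to the event rates.
#'
#' @param config A [synthetic_config()]; replicate r uses seed `seed + r - 1`.
#' @param n_reps Number of replicates (>= 1).
#' @return List of class `recovery_summary`: `reps` (per-replicate data
#'   frame), `mean_r2`, `sd_r2`, `target` (`rho_trial^2`), `bias`,
#'   `ci_coverage`.
#' @export
recovery_experiment <- function(config, n_reps) {
  stopifnot(inherits(config, "synthetic_config"), n_reps >= 1)
  target <- config$rho_trial^2
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    ds <- generate_dataset(cfg)
    if (config$noise_free) {
      te <- attr(ds, "true_effects")
      fit <- weighted_regression(te$theta_surrogate, te$theta_final,
                                 ds$n_treat + ds$n_control)
    } else {
      pairs <- build_pairs(ds, "bleed_major_minor", "death_all")
      fit <- weighted_regression(pairs)
    }
    ci <- suppressWarnings(r2_confidence_interval(fit$r2, fit$n))
    rows[[r]] <- data.frame(rep = r, n_pairs = fit$n, r2 = fit$r2,
                            r2_lo = ci$lo, r2_hi = ci$hi,
                            covered = !is.na(ci$lo) && ci$lo <= target &&
                              target <= ci$hi)
  }
  reps <- do.call(rbind, rows)
  structure(list(reps = reps,
                 mean_r2 = mean(reps$r2), sd_r2 = stats::sd(reps$r2),
                 target = target, bias = mean(reps$r2) - target,
                 ci_coverage = mean(reps$covered, na.rm = TRUE)),
            class = "recovery_summary")
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf("<recovery_summary> %d replicate(s)\n", nrow(x$reps)))
  cat(sprintf("  mean R2 %.3f (sd %.3f) vs rho_trial^2 = %.3f (bias %+.3f)\n",
              x$mean_r2, x$sd_r2, x$target, x$bias))
  cat(sprintf("  95%% CI coverage of rho_trial^2: %.1f%%\n",
              100 * x$ci_coverage))
  invisible(x)
}
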