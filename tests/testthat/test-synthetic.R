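test_that("generation is seeded, deterministic, and schema-valid", {
  cfg <- synthetic_config(k_trials = 10, seed = 123)
  ds1 <- generate_dataset(cfg)
  ds2 <- generate_dataset(cfg)
  expect_identical(nrow(ds1), 10L)
  expect_true(validate_comparisons(ds1))

  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_comparisons(ds1, p1); write_comparisons(ds2, p2)
  expect_identical(readLines(p1), readLines(p2))

  ds3 <- generate_dataset(synthetic_config(k_trials = 10, seed = 124))
  expect_false(identical(ds1$death_all_treat, ds3$death_all_treat))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(500)
  before <- .Random.seed
  invisible(generate_dataset(synthetic_config(k_trials = 6, seed = 9)))
  expect_identical(.Random.seed, before)
})

test_that("zero between-trial SD with huge trials pins log-ORs near the means", {
  cfg <- synthetic_config(k_trials = 6, rho_trial = 0, sd_surrogate = 0,
                          sd_final = 0, mu_surrogate = -0.3, mu_final = -0.1,
                          baseline_risk_surrogate = 0.10,
                          baseline_risk_final = 0.10, baseline_jitter_sd = 0,
                          n_min = 2e6, n_max = 2e6, multi_arm_frac = 0,
                          seed = 77)
  ds <- generate_dataset(cfg)
  te <- attr(ds, "true_effects")
  expect_true(all(te$theta_surrogate == -0.3))
  expect_true(all(te$theta_final == -0.1))
  # binomial se ~ sqrt(2/(n p q))/sqrt(n)-scale: well under 0.02 at n = 1e6/arm
  pairs <- build_pairs(ds, "bleed_major_minor", "death_all")
  expect_true(all(abs(pairs$x - (-0.3)) < 0.02))
  expect_true(all(abs(pairs$y - (-0.1)) < 0.02))
})

test_that("defaults emulate the target meta-analysis scale", {
  ds <- generate_dataset(synthetic_config(seed = 2026))
  expect_identical(nrow(ds), 58L)
  n_trials <- length(unique(ds$trial_id))
  expect_gte(n_trials, 42L)
  expect_lte(n_trials, 55L)
  total_n <- sum(ds$n_treat + ds$n_control)
  expect_gt(total_n, 90000)
  expect_lt(total_n, 320000)
  expect_true(all(ds$n_treat + ds$n_control >= 500))
})

test_that("100 random configs produce datasets the pipeline validates cleanly", {
  set.seed(606)
  for (i in 1:100) {
    cfg <- synthetic_config(
      k_trials = sample(5:25, 1),
      rho_trial = runif(1, -1, 1),
      mu_surrogate = runif(1, -0.5, 0.2), mu_final = runif(1, -0.3, 0.2),
      sd_surrogate = runif(1, 0, 0.6), sd_final = runif(1, 0, 0.4),
      baseline_risk_surrogate = runif(1, 0.01, 0.3),
      baseline_risk_final = runif(1, 0.01, 0.3),
      n_min = 500, n_max = sample(c(1000, 5000, 20000), 1),
      multi_arm_frac = runif(1, 0, 0.4),
      seed = sample.int(1e6, 1))
    expect_true(validate_comparisons(generate_dataset(cfg)))
  }
})

test_that("noise-free recovery is exact at rho = 1 and config errors are caught", {
  cfg <- synthetic_config(k_trials = 12, rho_trial = 1, sd_surrogate = 0.4,
                          sd_final = 0.2, noise_free = TRUE, seed = 5)
  out <- recovery_experiment(cfg, 3)
  expect_equal(out$reps$r2, rep(1, 3), tolerance = 1e-9)

  expect_error(synthetic_config(k_trials = 10, n_min = 2000, n_max = 1000,
                                seed = 1),
               "n_min > n_max")
  expect_error(synthetic_config(k_trials = 10), "seed")
})

test_that("null surrogacy yields small mean R2 decreasing with trial count", {
  base <- function(k) synthetic_config(
    k_trials = k, rho_trial = 0, sd_surrogate = 0.5, sd_final = 0.5,
    baseline_risk_surrogate = 0.2, baseline_risk_final = 0.2,
    n_min = 5000, n_max = 20000, multi_arm_frac = 0, seed = 814)
  small <- recovery_experiment(base(10), 40)
  large <- recovery_experiment(base(60), 40)
  expect_lt(large$mean_r2, small$mean_r2)
  expect_lt(large$mean_r2, 0.06)
})
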