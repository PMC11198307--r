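test_that("odds ratio matches cross-product and Woolf-variance arithmetic", {
  sym <- odds_ratio(10, 100, 10, 100)
  expect_equal(sym$log_effect, 0, tolerance = 1e-12)
  expect_false(sym$correction_applied)

  e <- odds_ratio(10, 100, 20, 100)
  expect_equal(e$log_effect, log((10 * 80) / (90 * 20)), tolerance = 1e-12)
  expect_equal(e$se, sqrt(1 / 10 + 1 / 90 + 1 / 20 + 1 / 80),
               tolerance = 1e-12)
  expect_identical(e$n_total, 200)

  zero <- odds_ratio(0, 10, 5, 10)
  expect_true(zero$correction_applied)
  expect_equal(exp(zero$log_effect), (0.5 * 5.5) / (10.5 * 5.5),
               tolerance = 1e-12)
  expect_equal(zero$se, sqrt(1 / 0.5 + 1 / 10.5 + 1 / 5.5 + 1 / 5.5),
               tolerance = 1e-12)
})

test_that("double-zero tables are non-informative; exclusion policy widens that", {
  expect_warning(dz <- odds_ratio(0, 100, 0, 100), "double-zero")
  expect_false(dz$informative)
  expect_true(is.na(dz$log_effect))

  expect_warning(ex <- odds_ratio(0, 100, 5, 100, zero_cell = "exclude"),
                 "exclude")
  expect_false(ex$informative)

  expect_error(odds_ratio(101, 100, 5, 100), "validation error")
})

test_that("swapping arms negates the log effect and preserves the se", {
  set.seed(11)
  for (i in 1:50) {
    n1 <- sample(50:500, 1); n2 <- sample(50:500, 1)
    a <- sample(0:n1, 1); c <- sample(0:n2, 1)
    if (a == 0 && c == 0) next
    e1 <- suppressWarnings(odds_ratio(a, n1, c, n2))
    e2 <- suppressWarnings(odds_ratio(c, n2, a, n1))
    expect_equal(e1$log_effect, -e2$log_effect, tolerance = 1e-12)
    expect_equal(e1$se, e2$se, tolerance = 1e-12)
  }
})

test_that("doubling all counts fixes the OR, shrinks the se, needs no correction", {
  e1 <- odds_ratio(12, 200, 30, 180)
  e2 <- odds_ratio(24, 400, 60, 360)
  expect_equal(e1$log_effect, e2$log_effect, tolerance = 1e-12)
  expect_lt(e2$se, e1$se)
  expect_false(e1$correction_applied)
})

test_that("reported-estimate back-calculation matches the closed form", {
  e <- effect_from_reported(0.80, 0.64, 1.00)
  expect_equal(e$log_effect, log(0.8), tolerance = 1e-12)
  expect_equal(e$se, (log(1.00) - log(0.64)) / (2 * qnorm(0.975)),
               tolerance = 1e-9)

  e2 <- effect_from_reported(2.0, 1.0, 4.0)
  expect_equal(e2$log_effect, log(2), tolerance = 1e-12)
  expect_equal(e2$se, log(4) / (2 * qnorm(0.975)), tolerance = 1e-9)

  no_ci <- effect_from_reported(0.9)
  expect_true(is.na(no_ci$se))

  expect_error(effect_from_reported(1.0, 1.0, 1.0), "degenerate")
  expect_error(effect_from_reported(0.8, 1.0, 0.6), "validation error")
  expect_error(effect_from_reported(-1, 0.5, 2), "validation error")
})

test_that("build_pairs keeps exactly the comparisons both endpoints inform", {
  recs <- make_records(5)
  recs$death_all_treat[c(2, 4)] <- NA_integer_
  recs$death_all_control[c(2, 4)] <- NA_integer_
  recs <- trial_comparisons(as.data.frame(recs))
  pairs <- build_pairs(recs, "bleed_major_minor", "death_all")
  expect_identical(nrow(pairs), 3L)
  expect_identical(pairs$comparison_id, c("C001", "C003", "C005"))
  expect_identical(pairs$w, recs$n_treat[c(1, 3, 5)] + recs$n_control[c(1, 3, 5)])

  # double-zero bleeding table: excluded from bleeding pairings, still
  # usable for mortality-only pooling
  recs$bleed_major_minor_treat[1] <- 0L
  recs$bleed_major_minor_control[1] <- 0L
  recs <- trial_comparisons(as.data.frame(recs))
  pairs2 <- build_pairs(recs, "bleed_major_minor", "death_all")
  expect_identical(pairs2$comparison_id, c("C003", "C005"))
  est <- endpoint_estimates(recs, "death_all")
  expect_true("C001" %in% est$comparison_id)

  expect_error(build_pairs(recs[0, ], "bleed_major_minor", "death_all"),
               "insufficient pairs")
  expect_error(build_pairs(recs, "death_all", "death_all"), "distinct")
})

test_that("pair selection equals an independent row-by-row filter on synthetic data", {
  ds <- generate_dataset(synthetic_config(k_trials = 40, seed = 404))
  pairs <- build_pairs(ds, "bleed_major", "death_cv")
  manual <- vapply(seq_len(nrow(ds)), function(i) {
    r <- ds[i, ]
    ok <- function(te, ce) !is.na(te) && !is.na(ce) && (te + ce) > 0
    ok(r$bleed_major_treat, r$bleed_major_control) &&
      ok(r$death_cv_treat, r$death_cv_control)
  }, logical(1))
  expect_identical(pairs$comparison_id, ds$comparison_id[manual])
})

test_that("the HR sensitivity track uses reported hazard ratios as the final effect", {
  recs <- make_records(6)
  recs$reported_hr[1:4] <- c(0.8, 1.1, 0.95, 1.3)
  recs$reported_hr_lo[1:4] <- c(0.6, 0.9, 0.70, 0.9)
  recs$reported_hr_hi[1:4] <- c(1.1, 1.4, 1.20, 1.9)
  recs <- trial_comparisons(as.data.frame(recs))
  pairs <- build_pairs(recs, "bleed_major_minor", "death_all",
                       estimand_policy = "hr_reported")
  expect_identical(nrow(pairs), 4L)
  expect_equal(pairs$y, log(c(0.8, 1.1, 0.95, 1.3)), tolerance = 1e-12)
})
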