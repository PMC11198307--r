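test_that("collinear points give an exact fit regardless of weights", {
  x <- c(-2, -1, 0, 1, 3)
  fit <- weighted_regression(x, 2 * x + 1, w = c(5, 1, 9, 2, 7))
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
})

test_that("weighted fit solves the normal equations (lm as independent oracle)", {
  x <- c(-1, 0, 1, 2); y <- c(-1, 0.5, 0.5, 2); w <- c(1, 2, 2, 1)
  fit <- weighted_regression(x, y, w)
  oracle <- lm(y ~ x, weights = w)
  expect_equal(fit$intercept, unname(coef(oracle)[1]), tolerance = 1e-12)
  expect_equal(fit$slope, unname(coef(oracle)[2]), tolerance = 1e-12)
  expect_equal(fit$r2, summary(oracle)$r.squared, tolerance = 1e-12)
  expect_equal(fit$slope_ci, unname(confint(oracle)["x", ]), tolerance = 1e-9)

  # equal weights reproduce the unweighted simple regression
  fit_eq <- weighted_regression(x, y, rep(3, 4))
  un <- lm(y ~ x)
  expect_equal(fit_eq$slope, unname(coef(un)[2]), tolerance = 1e-12)
  expect_equal(fit_eq$r2, summary(un)$r.squared, tolerance = 1e-12)
})

test_that("r2 equals the squared weighted correlation; weights scale-free", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(4:40, 1)
    x <- rnorm(n); y <- 0.4 * x + rnorm(n); w <- runif(n, 500, 30000)
    fit <- weighted_regression(x, y, w)
    m <- function(v) sum(w * v) / sum(w)
    wcor <- sum(w * (x - m(x)) * (y - m(y))) /
      sqrt(sum(w * (x - m(x))^2) * sum(w * (y - m(y))^2))
    expect_equal(fit$r2, wcor^2, tolerance = 1e-9)

    scaled <- weighted_regression(x, y, w * 137.5)
    expect_equal(scaled$slope, fit$slope, tolerance = 1e-12)
    expect_equal(scaled$intercept, fit$intercept, tolerance = 1e-12)
    expect_equal(scaled$r2, fit$r2, tolerance = 1e-12)
    expect_equal(scaled$slope_ci, fit$slope_ci, tolerance = 1e-9)
  }
})

test_that("degenerate designs are rejected with specific errors", {
  expect_error(weighted_regression(c(1, 1, 1), c(1, 2, 3), c(1, 1, 1)),
               "degenerate design")
  expect_error(weighted_regression(c(1, 2, 3), c(2, 2, 2), c(1, 1, 1)),
               "r2 undefined")
  expect_error(weighted_regression(1, 1, 1), "insufficient pairs")
  expect_error(weighted_regression(c(1, 2), c(1, 2), c(1, -1)), "positive")
})

test_that("delta-method interval hits the published two-decimal bounds", {
  cases <- data.frame(r2 = c(0.09, 0.09, 0.18, 0.49, 0.21, 0.02),
                      n = c(43, 40, 23, 19, 18, 20),
                      lo = c(0.00, 0.00, 0.00, 0.14, 0.00, 0.00),
                      hi = c(0.26, 0.27, 0.48, 0.84, 0.58, 0.15))
  for (i in seq_len(nrow(cases))) {
    ci <- r2_confidence_interval(cases$r2[i], cases$n[i])
    expect_equal(round(ci$lo, 2), cases$lo[i])
    expect_equal(round(ci$hi, 2), cases$hi[i])
  }
})

test_that("interval collapses at the R2 boundaries and narrows with n", {
  expect_equal(unlist(r2_confidence_interval(1, 10)[c("lo", "hi")]),
               c(lo = 1, hi = 1))
  expect_equal(unlist(r2_confidence_interval(0, 10)[c("lo", "hi")]),
               c(lo = 0, hi = 0))
  widths <- vapply(c(5, 10, 20, 40, 80, 160), function(n) {
    ci <- r2_confidence_interval(0.3, n)
    ci$hi - ci$lo
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_warning(small <- r2_confidence_interval(0.5, 3), "undefined")
  expect_true(is.na(small$lo))
})

test_that("classification follows both threshold schemes", {
  strong <- classify_surrogacy(0.96, c(0.81, 1.00))
  expect_identical(strong$ci_scheme, "strong")
  expect_identical(strong$point_scheme, "strong")

  inconclusive <- classify_surrogacy(0.76, c(0.61, 1.00))
  expect_identical(inconclusive$ci_scheme, "inconclusive")
  expect_identical(inconclusive$point_scheme, "strong")

  weak <- classify_surrogacy(0.09, c(0.00, 0.26))
  expect_identical(weak$ci_scheme, "weak")
  expect_identical(weak$point_scheme, "weak")

  moderate <- classify_surrogacy(0.55, c(0.10, 0.90))
  expect_identical(moderate$point_scheme, "moderate")

  expect_warning(missing_ci <- classify_surrogacy(0.5, c(NA, NA)), "missing")
  expect_identical(missing_ci$ci_scheme, "inconclusive")
  expect_true(missing_ci$ci_missing)
})

test_that("regression formulas render at the table's two-decimal convention", {
  expect_identical(format_regression(-0.06, 0.14), "-0.06 + 0.14*log(OR_bleeding)")
  expect_identical(format_regression(0, 1, "x"), "0.00 + 1.00*log(OR_x)")
  expect_identical(format_regression(-0.09, -0.11), "-0.09 - 0.11*log(OR_bleeding)")
  expect_identical(format_regression(-0.001, -0.004), "0.00 + 0.00*log(OR_bleeding)")
})

test_that("surrogacy_analysis aggregates counts and never violates orderings", {
  ds <- generate_dataset(synthetic_config(k_trials = 30, seed = 99))
  pairs <- build_pairs(ds, "bleed_major_minor", "death_all")
  res <- surrogacy_analysis(pairs)
  expect_gte(res$n_pairs, res$n_trials)
  expect_identical(res$n_patients, sum(pairs$w))
  expect_true(res$r2_ci["lo"] <= res$r2 && res$r2 <= res$r2_ci["hi"])
  expect_true(res$slope_ci[1] <= res$slope && res$slope <= res$slope_ci[2])
  expect_true(res$r2_ci["lo"] >= 0 && res$r2_ci["hi"] <= 1)
})
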