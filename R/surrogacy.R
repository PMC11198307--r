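#' Patient-weighted least squares of final on surrogate log effects
#'
#' The trial-level regression: with weighted means
#' \eqn{\bar x = \sum w x / \sum w}, the slope is
#' \eqn{\sum w (x-\bar x)(y-\bar y) / \sum w (x-\bar x)^2}, the intercept
#' \eqn{\bar y - b \bar x}, and \eqn{R^2 = 1 - \sum w e^2 / \sum w (y-\bar y)^2},
#' which equals the squared weighted Pearson correlation. The slope interval
#' uses a t quantile on n-2 degrees of freedom with the weighted residual mean
#' square; all quantities are invariant to rescaling the weights.
#'
#' @param x Surrogate log effects, or a `surrogacy_pairs` data frame (then `y`
#'   and `w` are taken from its columns).
#' @param y Final-endpoint log effects.
#' @param w Positive weights (randomized patients per comparison).
#' @param level Confidence level for the slope interval.
#' @return List of class `weighted_ls`: `slope`, `intercept`, `r2`,
#'   `slope_ci`, `slope_se`, `n`, `df`, `fitted`, `residuals`.
#' @export
weighted_regression <- function(x, y = NULL, w = NULL, level = 0.95) {
  if (is.data.frame(x)) { y <- x$y; w <- x$w; x <- x$x }
  n <- length(x)
  if (n < 2L) stop("insufficient pairs: need at least 2")
  stopifnot(length(y) == n, length(w) == n)
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite effects")
  if (any(w <= 0)) stop("weights must be positive")

  xb <- sum(w * x) / sum(w)
  yb <- sum(w * y) / sum(w)
  sxx <- sum(w * (x - xb)^2)
  syy <- sum(w * (y - yb)^2)
  if (sxx <= 0) stop("degenerate design: all surrogate effects equal")
  if (syy <= 0) stop("r2 undefined: all final-endpoint effects equal")
  slope <- sum(w * (x - xb) * (y - yb)) / sxx
  intercept <- yb - slope * xb
  res <- y - (intercept + slope * x)
  sse <- sum(w * res^2)
  r2 <- 1 - sse / syy
  r2 <- min(max(r2, 0), 1)  # guard fp wobble at the boundaries

  slope_se <- NA_real_
  slope_ci <- c(NA_real_, NA_real_)
  if (n >= 3L) {
    s2 <- sse / (n - 2)
    slope_se <- sqrt(s2 / sxx)
    tq <- stats::qt((1 + level) / 2, df = n - 2)
    slope_ci <- c(slope - tq * slope_se, slope + tq * slope_se)
  }
  structure(list(slope = slope, intercept = intercept, r2 = r2,
                 slope_ci = slope_ci, slope_se = slope_se,
                 n = n, df = n - 2L,
                 fitted = intercept + slope * x, residuals = res),
            class = "weighted_ls")
}

#' @export
print.weighted_ls <- function(x, ...) {
  cat(sprintf("<weighted_ls> n = %d: y = %.4f + %.4f x, R2 = %.4f\n",
              x$n, x$intercept, x$slope, x$r2))
  invisible(x)
}

#' Delta-method confidence interval for the trial-level R-squared
#'
#' Uses the first-order approximation
#' `sd = sqrt(4 R2 (1 - R2)^2 / (n - 3))` with a standard-normal quantile,
#' clipping the limits to \[0, 1\]. With fewer than 4 pairs the interval is
#' undefined and returned as missing with a warning; the point estimate is
#' unaffected.
#'
#' @param r2 Coefficient of determination in \[0, 1\].
#' @param n_pairs Number of comparison pairs behind `r2`.
#' @param level Confidence level, default 0.95.
#' @return List `lo`, `hi` (raw, unrounded), `sd`.
#' @export
r2_confidence_interval <- function(r2, n_pairs, level = 0.95) {
  stopifnot(is.finite(r2), r2 >= 0, r2 <= 1)
  if (n_pairs <= 3) {
    warning("n_pairs <= 3: R2 confidence interval undefined", call. = FALSE)
    return(list(lo = NA_real_, hi = NA_real_, sd = NA_real_))
  }
  sd <- sqrt(4 * r2 * (1 - r2)^2 / (n_pairs - 3))
  z <- .z975(level)
  list(lo = max(0, r2 - z * sd), hi = min(1, r2 + z * sd), sd = sd)
}

#' Classify surrogacy strength
#'
#' Two prespecified schemes. Confidence-bound scheme: strong when the lower
#' 95% limit of R2 exceeds 0.72, weak when the upper limit is below 0.50,
#' inconclusive otherwise (or when the interval is missing). Point-estimate
#' scheme: strong when R2 >= 0.7, moderate in \[0.5, 0.7), weak below 0.5.
#'
#' @param r2 Point estimate.
#' @param r2_ci Numeric `c(lo, hi)` or a list with `lo`/`hi`; may be missing.
#' @return List `ci_scheme` (`strong`/`weak`/`inconclusive`), `point_scheme`
#'   (`strong`/`moderate`/`weak`), and `ci_missing`.
#' @export
classify_surrogacy <- function(r2, r2_ci) {
  if (is.list(r2_ci)) r2_ci <- c(r2_ci$lo, r2_ci$hi)
  ci_missing <- is.null(r2_ci) || length(r2_ci) < 2L || anyNA(r2_ci)
  if (ci_missing) {
    warning("missing R2 confidence interval: CI-scheme label is inconclusive",
            call. = FALSE)
    ci_label <- "inconclusive"
  } else if (r2_ci[1] > 0.72) {
    ci_label <- "strong"
  } else if (r2_ci[2] < 0.50) {
    ci_label <- "weak"
  } else {
    ci_label <- "inconclusive"
  }
  point_label <- if (r2 >= 0.7) "strong" else if (r2 >= 0.5) "moderate" else "weak"
  list(ci_scheme = ci_label, point_scheme = point_label, ci_missing = ci_missing)
}

#' Render the regression formula at table precision
#'
#' Two-decimal convention, e.g. `-0.06 + 0.14*log(OR_bleeding)`; a negative
#' slope absorbs its sign into the operator (`-0.09 - 0.11*log(...)`).
#'
#' @param intercept,slope Finite reals.
#' @param surrogate_label Label inside `log(OR_...)`.
#' @return Character scalar.
#' @export
format_regression <- function(intercept, slope, surrogate_label = "bleeding") {
  stopifnot(is.finite(intercept), is.finite(slope))
  r2dp <- function(v) { v <- round(v, 2); if (v == 0) 0 else v }  # avoid -0.00
  i2 <- r2dp(intercept); s2 <- r2dp(slope)
  sprintf("%.2f %s %.2f*log(OR_%s)", i2, if (s2 < 0) "-" else "+", abs(s2),
          surrogate_label)
}

#' Full surrogacy evaluation for one endpoint pairing
#'
#' Runs the weighted regression, the delta-method R2 interval, and both
#' classification schemes, and gathers the counts the summary tables report.
#'
#' @param pairs `surrogacy_pairs` from [build_pairs()].
#' @param level Confidence level.
#' @param surrogate_label Label for the rendered formula.
#' @return List of class `surrogacy_result`: endpoints, `n_pairs`, `n_trials`,
#'   `n_patients`, `slope`, `slope_ci`, `intercept`, `r2`, `r2_ci`,
#'   `label_ci_scheme`, `label_point_scheme`, `formula_text`, `fit`.
#' @export
surrogacy_analysis <- function(pairs, level = 0.95, surrogate_label = "bleeding") {
  fit <- weighted_regression(pairs, level = level)
  ci <- if (fit$n >= 4L) {
    r2_confidence_interval(fit$r2, fit$n, level = level)
  } else {
    suppressWarnings(r2_confidence_interval(fit$r2, fit$n, level = level))
  }
  labels <- suppressWarnings(classify_surrogacy(fit$r2, ci))
  structure(list(
    surrogate_endpoint = attr(pairs, "surrogate_endpoint"),
    final_endpoint = attr(pairs, "final_endpoint"),
    estimand_policy = attr(pairs, "estimand_policy"),
    n_pairs = fit$n,
    n_trials = length(unique(pairs$trial_id)),
    n_patients = sum(pairs$w),
    slope = fit$slope, slope_ci = fit$slope_ci,
    intercept = fit$intercept,
    r2 = fit$r2, r2_ci = c(lo = ci$lo, hi = ci$hi),
    label_ci_scheme = labels$ci_scheme,
    label_point_scheme = labels$point_scheme,
    formula_text = format_regression(fit$intercept, fit$slope, surrogate_label),
    fit = fit), class = "surrogacy_result")
}

#' @export
print.surrogacy_result <- function(x, ...) {
  fmt_ci <- function(ci) {
    if (anyNA(ci)) "CI n/a" else sprintf("%.2f to %.2f", ci[1], ci[2])
  }
  cat(sprintf("<surrogacy_result> %s -> %s\n", x$surrogate_endpoint,
              x$final_endpoint))
  cat(sprintf("  %d pairs, %d trials, %s patients\n", x$n_pairs, x$n_trials,
              format(x$n_patients, big.mark = ",")))
  cat(sprintf("  %s\n", x$formula_text))
  cat(sprintf("  slope %.2f (%s); R2 %.2f (%s) [%s / %s]\n",
              x$slope, fmt_ci(x$slope_ci), x$r2, fmt_ci(x$r2_ci),
              x$label_ci_scheme, x$label_point_scheme))
  invisible(x)
}
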