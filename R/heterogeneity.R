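#' Pool per-comparison effects with heterogeneity statistics
#'
#' Inverse-variance pooling on the log scale via `metafor::rma.uni`:
#' fixed-effect, or random-effects with the DerSimonian-Laird tau-squared
#' (truncated at zero). Cochran's Q is computed against the fixed-effect
#' pooled value and `I2 = max(0, (Q - df) / Q) * 100`, which for the
#' DerSimonian-Laird estimator coincides with the tau-squared-based
#' definition. The 95% interval uses a normal quantile on the pooled
#' standard error.
#'
#' @param estimates Data frame with columns `log_effect` and `se` (positive),
#'   optionally `comparison_id`; or a list of `effect_estimate` objects.
#' @param model `"random_dl"` (default) or `"fixed"`.
#' @param level Confidence level.
#' @return List of class `heterogeneity_result`: `k`, `pooled_log_effect`,
#'   `pooled_ci`, `pooled_se`, `q`, `df`, `tau2`, `i2_percent`, `model`.
#' @export
pool_effects <- function(estimates, model = c("random_dl", "fixed"),
                         level = 0.95) {
  model <- match.arg(model)
  estimates <- .as_estimate_frame(estimates)
  if (nrow(estimates) < 2L) stop("insufficient studies: need k >= 2")
  bad_se <- is.na(estimates$se) | estimates$se <= 0
  if (any(bad_se)) {
    stop("missing or non-positive se for comparison: ",
         paste(estimates$comparison_id[bad_se], collapse = ", "))
  }
  fit <- metafor::rma.uni(yi = estimates$log_effect, sei = estimates$se,
                          method = if (model == "fixed") "FE" else "DL",
                          level = level * 100)
  q <- as.numeric(fit$QE)
  k <- nrow(estimates)
  df <- k - 1L
  structure(list(k = k,
                 pooled_log_effect = as.numeric(fit$beta),
                 pooled_ci = c(fit$ci.lb, fit$ci.ub),
                 pooled_se = as.numeric(fit$se),
                 q = q, df = df,
                 tau2 = if (model == "fixed") 0 else as.numeric(fit$tau2),
                 i2_percent = if (q > 0) max(0, (q - df) / q) * 100 else 0,
                 model = model),
            class = "heterogeneity_result")
}

.as_estimate_frame <- function(estimates) {
  if (is.data.frame(estimates)) {
    if (is.null(estimates$comparison_id)) {
      estimates$comparison_id <- as.character(seq_len(nrow(estimates)))
    }
    return(estimates[, c("comparison_id", "log_effect", "se")])
  }
  do.call(rbind, lapply(seq_along(estimates), function(i) {
    e <- estimates[[i]]
    data.frame(comparison_id = if (!is.null(e$comparison_id)) e$comparison_id
               else as.character(i),
               log_effect = e$log_effect, se = e$se,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("<heterogeneity_result> k = %d (%s)\n", x$k, x$model))
  cat(sprintf("  pooled log effect %.4f (%.4f to %.4f)\n",
              x$pooled_log_effect, x$pooled_ci[1], x$pooled_ci[2]))
  cat(sprintf("  Q = %.3f on %d df, tau2 = %.4f, I2 = %.1f%%\n",
              x$q, x$df, x$tau2, x$i2_percent))
  invisible(x)
}

#' Funnel-plot substrate
#'
#' Points (log effect, se) sorted by precision, with the fixed-effect pooled
#' value attached as the funnel centerline (for a single estimate the
#' centerline is the estimate itself). Estimates with missing standard errors
#' are excluded.
#'
#' @param estimates As in [pool_effects()].
#' @return Data frame `comparison_id`, `log_effect`, `se` sorted by `se`
#'   ascending, with attribute `center`.
#' @export
funnel_data <- function(estimates) {
  estimates <- .as_estimate_frame(estimates)
  estimates <- estimates[!is.na(estimates$se) & estimates$se > 0, , drop = FALSE]
  if (nrow(estimates) == 0L) stop("no estimates with standard errors")
  out <- estimates[order(estimates$se), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "center") <- if (nrow(out) == 1L) {
    out$log_effect
  } else {
    pool_effects(out, model = "fixed")$pooled_log_effect
  }
  out
}

#' Per-endpoint effect estimates from a comparison table
#'
#' Computes the count-based log odds ratio of one endpoint for every
#' comparison reporting it; non-informative (double-zero) tables are dropped.
#'
#' @param records `trial_comparisons`.
#' @param endpoint Endpoint name.
#' @param zero_cell Passed to [odds_ratio()].
#' @return Data frame `comparison_id`, `log_effect`, `se`, `n_total`.
#' @export
endpoint_estimates <- function(records, endpoint,
                               zero_cell = c("haldane", "exclude")) {
  zero_cell <- match.arg(zero_cell)
  stopifnot(endpoint %in% .endpoints)
  rows <- lapply(seq_len(nrow(records)), function(i) {
    row <- records[i, , drop = FALSE]
    e <- .endpoint_estimate(row, endpoint, zero_cell)
    if (is.null(e) || !e$informative) return(NULL)
    data.frame(comparison_id = row$comparison_id, log_effect = e$log_effect,
               se = e$se, n_total = e$n_total, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(comparison_id = character(), log_effect = numeric(),
                      se = numeric(), n_total = integer())
  }
  rownames(out) <- NULL
  out
}
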