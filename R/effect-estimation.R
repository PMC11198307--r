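#' Log odds ratio from a 2x2 event table
#'
#' Cross-product odds ratio with the Woolf variance. If any cell of the table
#' (events or non-events, either arm) is zero, 0.5 is added to all four cells
#' (Haldane-Anscombe) before taking logs, and `correction_applied` is set.
#' A comparison with zero events in both arms carries no information about the
#' odds ratio and is returned as a non-informative sentinel that downstream
#' stages exclude.
#'
#' @param treat_events,n_treat Events and randomized patients, treatment arm.
#' @param control_events,n_control Same for the control arm.
#' @param zero_cell `"haldane"` (default) corrects single-zero tables;
#'   `"exclude"` marks any zero-cell table non-informative instead.
#' @return An `effect_estimate`: list with `log_effect`, `se`, `or`,
#'   `estimand = "or_from_counts"`, `n_total`, `correction_applied`,
#'   `informative`.
#' @export
odds_ratio <- function(treat_events, n_treat, control_events, n_control,
                       zero_cell = c("haldane", "exclude")) {
  zero_cell <- match.arg(zero_cell)
  if (n_treat <= 0 || n_control <= 0) stop("validation error: arm sizes must be positive")
  if (treat_events < 0 || control_events < 0 ||
      treat_events > n_treat || control_events > n_control) {
    stop("validation error: events outside [0, arm size]")
  }
  # doubles: integer cross-products overflow 32-bit for very large trials
  a <- as.numeric(treat_events); b <- as.numeric(n_treat - treat_events)
  c <- as.numeric(control_events); d <- as.numeric(n_control - control_events)
  non_informative <- function(msg) {
    warning(msg, call. = FALSE)
    structure(list(log_effect = NA_real_, se = NA_real_, or = NA_real_,
                   estimand = "or_from_counts",
                   n_total = n_treat + n_control,
                   correction_applied = FALSE, informative = FALSE),
              class = "effect_estimate")
  }
  if (a == 0 && c == 0) {
    return(non_informative("double-zero table: no events in either arm; excluded"))
  }
  any_zero <- any(c(a, b, c, d) == 0)
  if (any_zero && zero_cell == "exclude") {
    return(non_informative("zero cell with zero_cell = 'exclude'; excluded"))
  }
  if (any_zero) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  structure(list(log_effect = log(a * d / (b * c)),
                 se = sqrt(1 / a + 1 / b + 1 / c + 1 / d),
                 or = a * d / (b * c),
                 estimand = "or_from_counts",
                 n_total = n_treat + n_control,
                 correction_applied = any_zero, informative = TRUE),
            class = "effect_estimate")
}

#' Log effect from a reported OR or HR with its confidence interval
#'
#' Back-calculates the standard error from a reported 95% interval:
#' `se = (log(hi) - log(lo)) / (2 * 1.959964)`. With no interval the standard
#' error is left missing.
#'
#' @param value Reported ratio estimate (> 0).
#' @param lo,hi Reported confidence limits, optional.
#' @param estimand `"or_reported"` or `"hr_reported"`.
#' @param n_total Randomized patients behind the estimate (analysis weight).
#' @return An `effect_estimate`.
#' @export
effect_from_reported <- function(value, lo = NA_real_, hi = NA_real_,
                                 estimand = c("hr_reported", "or_reported"),
                                 n_total = NA_integer_) {
  estimand <- match.arg(estimand)
  if (!is.finite(value) || value <= 0) stop("validation error: value must be positive")
  se <- NA_real_
  if (!is.na(lo) || !is.na(hi)) {
    if (is.na(lo) || is.na(hi) || lo <= 0 || hi <= 0) {
      stop("validation error: both CI limits must be positive")
    }
    if (lo > hi || value < lo || value > hi) {
      stop("validation error: require 0 < lo <= value <= hi")
    }
    se <- (log(hi) - log(lo)) / (2 * .z975())
    if (se <= 0) stop("validation error: degenerate CI (se must be > 0)")
  }
  structure(list(log_effect = log(value), se = se, or = value,
                 estimand = estimand, n_total = n_total,
                 correction_applied = FALSE, informative = TRUE),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("<effect_estimate> %s: log effect %.4f (se %s)%s%s\n",
              x$estimand, x$log_effect,
              ifelse(is.na(x$se), "NA", sprintf("%.4f", x$se)),
              if (isTRUE(x$correction_applied)) ", 0.5 correction" else "",
              if (!isTRUE(x$informative)) ", NON-INFORMATIVE" else ""))
  invisible(x)
}

# per-row log-OR for one endpoint; NULL when the endpoint is unreported
.endpoint_estimate <- function(row, endpoint, zero_cell = "haldane") {
  te <- row[[paste0(endpoint, "_treat")]]
  ce <- row[[paste0(endpoint, "_control")]]
  if (is.na(te) || is.na(ce)) return(NULL)
  suppressWarnings(
    odds_ratio(te, row$n_treat, ce, row$n_control, zero_cell = zero_cell)
  )
}

#' Build (surrogate, final) effect pairs for the trial-level regression
#'
#' One pair per comparison reporting both endpoints informatively; double-zero
#' tables and missing endpoints are excluded. The weight is the number of
#' randomized patients in the comparison. Under
#' `estimand_policy = "hr_reported"` the final-endpoint effect is the log of
#' the trial's reported hazard ratio and only comparisons reporting an HR
#' contribute (the HR sensitivity track).
#'
#' @param records `trial_comparisons`.
#' @param surrogate_endpoint,final_endpoint Endpoint names (distinct), among
#'   `bleed_major`, `bleed_major_minor`, `death_all`, `death_cv`.
#' @param estimand_policy `"or_from_counts"` (default) or `"hr_reported"`.
#' @param zero_cell Passed to [odds_ratio()].
#' @return Data frame `comparison_id`, `trial_id`, `x`, `y`, `w`, class
#'   `surrogacy_pairs`, in input order.
#' @export
build_pairs <- function(records, surrogate_endpoint, final_endpoint,
                        estimand_policy = c("or_from_counts", "hr_reported"),
                        zero_cell = c("haldane", "exclude")) {
  estimand_policy <- match.arg(estimand_policy)
  zero_cell <- match.arg(zero_cell)
  stopifnot(surrogate_endpoint %in% .endpoints, final_endpoint %in% .endpoints)
  if (surrogate_endpoint == final_endpoint) stop("endpoints must be distinct")

  rows <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    row <- records[i, , drop = FALSE]
    sx <- .endpoint_estimate(row, surrogate_endpoint, zero_cell)
    if (is.null(sx) || !sx$informative) next
    if (estimand_policy == "or_from_counts") {
      sy <- .endpoint_estimate(row, final_endpoint, zero_cell)
    } else {
      if (is.na(row$reported_hr)) next
      sy <- effect_from_reported(row$reported_hr, row$reported_hr_lo,
                                 row$reported_hr_hi, estimand = "hr_reported",
                                 n_total = row$n_treat + row$n_control)
    }
    if (is.null(sy) || !sy$informative) next
    rows[[i]] <- data.frame(comparison_id = row$comparison_id,
                            trial_id = row$trial_id,
                            x = sx$log_effect, y = sy$log_effect,
                            w = row$n_treat + row$n_control,
                            se_x = sx$se, se_y = sy$se,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || nrow(out) < 2L) {
    stop("insufficient pairs: fewer than 2 comparisons report both endpoints")
  }
  rownames(out) <- NULL
  attr(out, "surrogate_endpoint") <- surrogate_endpoint
  attr(out, "final_endpoint") <- final_endpoint
  attr(out, "estimand_policy") <- estimand_policy
  class(out) <- c("surrogacy_pairs", "data.frame")
  out
}
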