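#' Column schema of the per-comparison table
#'
#' One row per randomized pairwise comparison. Multi-arm trials contribute
#' several rows sharing a `trial_id`; `comparison_id` is unique. Event counts
#' are left empty (not zero) when a trial did not report that endpoint, so a
#' comparison silently drops out of analyses whose endpoint it lacks.
#'
#' @return Character vector of column names, in file order.
#' @export
comparison_schema <- function() {
  c("trial_id", "comparison_id", "first_enrollment_year", "follow_up_months",
    "region", "acs_population", "major_minor_definition", "major_definition",
    "n_treat", "n_control",
    "bleed_major_treat", "bleed_major_control",
    "bleed_major_minor_treat", "bleed_major_minor_control",
    "death_all_treat", "death_all_control",
    "death_cv_treat", "death_cv_control",
    "reported_or", "reported_or_lo", "reported_or_hi",
    "reported_hr", "reported_hr_lo", "reported_hr_hi")
}

.integer_cols <- function() {
  c("first_enrollment_year", "n_treat", "n_control",
    paste0(rep(.endpoints, each = 2), c("_treat", "_control")))
}

.numeric_cols <- function() {
  c("follow_up_months", "reported_or", "reported_or_lo", "reported_or_hi",
    "reported_hr", "reported_hr_lo", "reported_hr_hi")
}

#' Construct a validated comparison table
#'
#' @param df Data frame following [comparison_schema()].
#' @return `df` with class `trial_comparisons`, after validation.
#' @export
trial_comparisons <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  validate_comparisons(df)
  class(df) <- c("trial_comparisons", "data.frame")
  df
}

#' Validate comparison records
#'
#' Checks the schema, enum values, uniqueness of `comparison_id`, year and
#' follow-up ranges, and that no event count exceeds its arm size.
#'
#' @param df Data frame of comparisons.
#' @return Invisibly `TRUE`; stops with an informative error otherwise.
#' @export
validate_comparisons <- function(df) {
  missing_cols <- setdiff(comparison_schema(), names(df))
  if (length(missing_cols) > 0L) {
    stop("schema error: missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0L) return(invisible(TRUE))

  dup <- df$comparison_id[duplicated(df$comparison_id)]
  if (length(dup) > 0L) {
    stop("validation error: duplicate comparison_id: ",
         paste(unique(dup), collapse = ", "))
  }
  bad <- function(cond, what) {
    idx <- which(cond)
    if (length(idx) > 0L) {
      stop("validation error: ", what, " for comparison_id: ",
           paste(df$comparison_id[idx], collapse = ", "))
    }
  }
  bad(!is.finite(df$n_treat) | df$n_treat <= 0 |
        !is.finite(df$n_control) | df$n_control <= 0,
      "arm sizes must be positive")
  bad(!is.finite(df$follow_up_months) | df$follow_up_months <= 0,
      "follow_up_months must be positive")
  bad(!is.finite(df$first_enrollment_year) |
        df$first_enrollment_year < 1990 | df$first_enrollment_year > 2025,
      "first_enrollment_year outside [1990, 2025]")
  bad(!(df$region %in% .regions), "unknown region")
  bad(!(df$major_minor_definition %in% .mm_definitions),
      "unknown major_minor_definition")
  bad(!(df$major_definition %in% .major_definitions), "unknown major_definition")
  bad(!(df$acs_population %in% c(TRUE, FALSE)), "acs_population must be logical")

  for (ep in .endpoints) {
    te <- df[[paste0(ep, "_treat")]]
    ce <- df[[paste0(ep, "_control")]]
    bad(!is.na(te) & (te < 0 | te > df$n_treat),
        paste0(ep, " treat events exceed arm size or are negative"))
    bad(!is.na(ce) & (ce < 0 | ce > df$n_control),
        paste0(ep, " control events exceed arm size or are negative"))
    bad(xor(is.na(te), is.na(ce)),
        paste0(ep, " has events for one arm only"))
  }
  for (stem in c("reported_or", "reported_hr")) {
    v <- df[[stem]]; lo <- df[[paste0(stem, "_lo")]]; hi <- df[[paste0(stem, "_hi")]]
    bad(!is.na(v) & v <= 0, paste0(stem, " must be positive"))
    bad(!is.na(lo) & !is.na(hi) & (lo > hi), paste0(stem, " CI has lo > hi"))
    bad(!is.na(v) & !is.na(lo) & !is.na(hi) & (v < lo | v > hi),
        paste0(stem, " outside its own CI"))
  }
  invisible(TRUE)
}

#' Read a per-comparison CSV
#'
#' @param path CSV file following [comparison_schema()]; empty cells are
#'   missing values, booleans written as `true`/`false`.
#' @param apply_eligibility Drop comparisons with fewer than `min_n` randomized
#'   patients in total (the trial-size eligibility rule). The number dropped is
#'   reported via `message()`.
#' @param min_n Minimum total randomized patients, default 500.
#' @return A `trial_comparisons` data frame in file order.
#' @export
read_comparisons <- function(path, apply_eligibility = TRUE, min_n = 500) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character", na.strings = "",
                        check.names = FALSE)
  missing_cols <- setdiff(comparison_schema(), names(df))
  if (length(missing_cols) > 0L) {
    stop("schema error: missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[, comparison_schema(), drop = FALSE]
  for (col in .integer_cols()) df[[col]] <- as.integer(df[[col]])
  for (col in .numeric_cols()) df[[col]] <- as.numeric(df[[col]])
  df$acs_population <- df$acs_population == "true"
  records <- trial_comparisons(df)
  if (apply_eligibility) records <- filter_eligibility(records, min_n = min_n)
  records
}

#' Apply the trial-size eligibility rule
#'
#' @param records `trial_comparisons`.
#' @param min_n Minimum `n_treat + n_control`.
#' @return Filtered records; idempotent.
#' @export
filter_eligibility <- function(records, min_n = 500) {
  keep <- (records$n_treat + records$n_control) >= min_n
  if (any(!keep)) {
    message(sum(!keep), " comparison(s) dropped by eligibility (total n < ",
            min_n, ")")
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("trial_comparisons", "data.frame")
  out
}

#' Write comparisons to CSV
#'
#' Lossless round trip with [read_comparisons()]: missing counts stay empty
#' cells, booleans are written as `true`/`false`.
#'
#' @param records `trial_comparisons` (or schema-conformant data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparisons <- function(records, path) {
  validate_comparisons(records)
  out <- as.data.frame(records)[, comparison_schema(), drop = FALSE]
  out$acs_population <- ifelse(out$acs_population, "true", "false")
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @export
print.trial_comparisons <- function(x, ...) {
  cat(sprintf("<trial_comparisons> %d comparison(s), %d trial(s), %s patients\n",
              nrow(x), length(unique(x$trial_id)),
              format(sum(x$n_treat + x$n_control), big.mark = ",")))
  if (nrow(x) > 0L) print(utils::head(as.data.frame(x)[, 1:10]), ...)
  invisible(x)
}
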