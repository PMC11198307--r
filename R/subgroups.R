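#' Define a prespecified subgroup
#'
#' A conjunction of optional filters over comparison attributes. The era split
#' is keyed on the year of first patient enrollment with 2010/2011 as the
#' boundary (2010 goes to the early stratum); follow-up of exactly 12 months
#' belongs to the "<= 12 months" stratum.
#'
#' @param name Subgroup label used in reports.
#' @param bleeding_criteria `NULL`, `"study_defined"` (no restriction),
#'   `"barc_only"` or `"timi_only"` (restrict by bleeding-definition enums).
#' @param era `NULL`, `"before_2010"` or `"after_2011"`.
#' @param follow_up `NULL`, `"le_12m"` or `"gt_12m"`.
#' @param region `NULL`, `"east_asia"` or `"non_east_asia"`.
#' @param acs_only `NULL` or `TRUE` (restrict to acute-coronary-syndrome
#'   populations).
#' @param estimand_policy `"or_from_counts"` or `"hr_reported"`.
#' @return List of class `subgroup_spec`.
#' @export
subgroup_spec <- function(name, bleeding_criteria = NULL, era = NULL,
                          follow_up = NULL, region = NULL, acs_only = NULL,
                          estimand_policy = "or_from_counts") {
  chk <- function(v, allowed) is.null(v) || (length(v) == 1L && v %in% allowed)
  stopifnot(is.character(name), length(name) == 1L,
            chk(bleeding_criteria, c("study_defined", "barc_only", "timi_only")),
            chk(era, c("before_2010", "after_2011")),
            chk(follow_up, c("le_12m", "gt_12m")),
            chk(region, .regions),
            is.null(acs_only) || isTRUE(acs_only) || isFALSE(acs_only),
            estimand_policy %in% c("or_from_counts", "hr_reported"))
  structure(list(name = name, bleeding_criteria = bleeding_criteria, era = era,
                 follow_up = follow_up, region = region, acs_only = acs_only,
                 estimand_policy = estimand_policy),
            class = "subgroup_spec")
}

#' Filter comparisons by a subgroup definition
#'
#' Keeps records satisfying all non-null filters of `spec`; order-independent
#' conjunction. An empty result is allowed (downstream stages report
#' insufficient pairs).
#'
#' @param records `trial_comparisons`.
#' @param spec A [subgroup_spec()].
#' @return Filtered `trial_comparisons`.
#' @export
filter_subgroup <- function(records, spec) {
  stopifnot(inherits(spec, "subgroup_spec"))
  keep <- rep(TRUE, nrow(records))
  if (!is.null(spec$bleeding_criteria) && spec$bleeding_criteria != "study_defined") {
    stem <- if (spec$bleeding_criteria == "barc_only") "barc" else "timi"
    keep <- keep & (startsWith(records$major_minor_definition, stem) |
                      startsWith(records$major_definition, stem))
  }
  if (!is.null(spec$era)) {
    keep <- keep & if (spec$era == "before_2010") {
      records$first_enrollment_year <= 2010
    } else {
      records$first_enrollment_year >= 2011
    }
  }
  if (!is.null(spec$follow_up)) {
    keep <- keep & if (spec$follow_up == "le_12m") {
      records$follow_up_months <= 12
    } else {
      records$follow_up_months > 12
    }
  }
  if (!is.null(spec$region)) keep <- keep & (records$region == spec$region)
  if (isTRUE(spec$acs_only)) keep <- keep & records$acs_population
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("trial_comparisons", "data.frame")
  out
}

#' The prespecified subgroup grid
#'
#' Era (before 2010 / after 2011), follow-up duration (<= 12 / > 12 months),
#' trial region (East Asia / elsewhere), and acute-coronary-syndrome
#' populations.
#'
#' @return List of [subgroup_spec()] objects.
#' @export
default_subgroups <- function() {
  list(subgroup_spec("before_2010", era = "before_2010"),
       subgroup_spec("after_2011", era = "after_2011"),
       subgroup_spec("follow_up_le_12m", follow_up = "le_12m"),
       subgroup_spec("follow_up_gt_12m", follow_up = "gt_12m"),
       subgroup_spec("east_asia", region = "east_asia"),
       subgroup_spec("non_east_asia", region = "non_east_asia"),
       subgroup_spec("acs_only", acs_only = TRUE))
}

#' Analysis configuration
#'
#' @param eligibility_min_n Minimum randomized patients per comparison
#'   (default 500).
#' @param weighting `"patients"` (randomized patients per comparison, the
#'   primary weighting) or `"inverse_variance"` (sensitivity).
#' @param zero_cell `"haldane"` or `"exclude"` for zero-cell 2x2 tables.
#' @param ci_level Confidence level (default 0.95).
#' @param estimand_policy `"or_from_counts"` or `"hr_reported"`.
#' @param subgroups List of [subgroup_spec()]; default [default_subgroups()].
#' @param surrogate_label Label used in rendered regression formulas.
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(eligibility_min_n = 500,
                            weighting = c("patients", "inverse_variance"),
                            zero_cell = c("haldane", "exclude"),
                            ci_level = 0.95,
                            estimand_policy = c("or_from_counts", "hr_reported"),
                            subgroups = default_subgroups(),
                            surrogate_label = "bleeding") {
  structure(list(eligibility_min_n = eligibility_min_n,
                 weighting = match.arg(weighting),
                 zero_cell = match.arg(zero_cell),
                 ci_level = ci_level,
                 estimand_policy = match.arg(estimand_policy),
                 subgroups = subgroups,
                 surrogate_label = surrogate_label),
            class = "analysis_config")
}
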