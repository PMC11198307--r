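#' Bleeding-definition families of the main analysis grid
#'
#' Six rows: the trial-defined major/minor and major families, each overall
#' ("study defined", all definitions pooled) and restricted to BARC or TIMI
#' definitions.
#'
#' @return List of family descriptors (`key`, `label`, `endpoint`, `defs`).
#' @export
definition_families <- function() {
  list(
    list(key = "study_major_minor", label = "Study defined major or minor",
         endpoint = "bleed_major_minor", defs = NULL),
    list(key = "barc_major_minor", label = "BARC 2,3,5",
         endpoint = "bleed_major_minor", defs = c("barc_235", "barc_2345")),
    list(key = "timi_major_minor", label = "TIMI major or minor",
         endpoint = "bleed_major_minor", defs = "timi_major_minor"),
    list(key = "study_major", label = "Study defined major",
         endpoint = "bleed_major", defs = NULL),
    list(key = "barc_major", label = "BARC 3,5",
         endpoint = "bleed_major", defs = c("barc_35", "barc_345")),
    list(key = "timi_major", label = "TIMI major",
         endpoint = "bleed_major", defs = "timi_major"))
}

.final_endpoints <- c("death_all", "death_cv")

.subset_family <- function(records, fam) {
  if (is.null(fam$defs)) return(records)
  col <- if (fam$endpoint == "bleed_major_minor") "major_minor_definition"
         else "major_definition"
  out <- records[records[[col]] %in% fam$defs, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("trial_comparisons", "data.frame")
  out
}

# one grid cell -> a table row (estimable or not), plus the full result object
.run_cell <- function(records, fam, final_endpoint, subgroup_name, config) {
  base_row <- data.frame(
    analysis = fam$label, endpoint = final_endpoint, subgroup = subgroup_name,
    comparison_pairs = NA_integer_, rcts = NA_integer_, n = NA_integer_,
    regression_formula = NA_character_,
    slope = NA_real_, slope_lo = NA_real_, slope_hi = NA_real_,
    r2 = NA_real_, r2_lo = NA_real_, r2_hi = NA_real_,
    label_ci = NA_character_, label_point = NA_character_,
    reason = NA_character_, stringsAsFactors = FALSE)
  res <- tryCatch({
    pairs <- build_pairs(records, fam$endpoint, final_endpoint,
                         estimand_policy = config$estimand_policy,
                         zero_cell = config$zero_cell)
    if (config$weighting == "inverse_variance") {
      if (anyNA(pairs$se_y)) stop("inverse-variance weighting needs se for every pair")
      pairs$w <- 1 / (pairs$se_x^2 + pairs$se_y^2)
    }
    surrogacy_analysis(pairs, level = config$ci_level,
                       surrogate_label = config$surrogate_label)
  }, error = function(e) conditionMessage(e))
  if (is.character(res)) {
    base_row$reason <- res
    message(sprintf("cell %s | %s | %s: not estimable (%s)",
                    fam$label, final_endpoint, subgroup_name, res))
    return(list(row = base_row, result = NULL))
  }
  base_row$comparison_pairs <- res$n_pairs
  base_row$rcts <- res$n_trials
  base_row$n <- res$n_patients
  base_row$regression_formula <- res$formula_text
  base_row$slope <- res$slope
  base_row$slope_lo <- res$slope_ci[1]; base_row$slope_hi <- res$slope_ci[2]
  base_row$r2 <- res$r2
  base_row$r2_lo <- unname(res$r2_ci["lo"]); base_row$r2_hi <- unname(res$r2_ci["hi"])
  base_row$label_ci <- res$label_ci_scheme
  base_row$label_point <- res$label_point_scheme
  message(sprintf("cell %s | %s | %s: %d pairs, %d trials, %d patients",
                  fam$label, final_endpoint, subgroup_name,
                  res$n_pairs, res$n_trials, res$n_patients))
  list(row = base_row, result = res)
}

#' Run the full surrogacy evaluation
#'
#' Applies the eligibility filter, evaluates every bleeding-definition family
#' against each mortality endpoint (the 12-row main grid), repeats the grid
#' within each configured subgroup, and attaches random-effects heterogeneity
#' per endpoint. Cells with too few informative pairs are reported with a
#' reason code, never silently omitted. Output order is deterministic and the
#' whole computation is free of randomness.
#'
#' @param records `trial_comparisons`.
#' @param config An [analysis_config()].
#' @return List of class `analysis_report`: `table1` (main grid), `table2`
#'   (subgroup grid), `results` (named list of `surrogacy_result`),
#'   `heterogeneity` (per-endpoint `heterogeneity_result`), `metadata`.
#' @export
run_full_analysis <- function(records, config = analysis_config()) {
  if (nrow(records) == 0L) stop("empty dataset")
  validate_comparisons(records)
  records <- filter_eligibility(records, min_n = config$eligibility_min_n)
  if (nrow(records) == 0L) stop("no comparisons pass the eligibility filter")
  multi <- unique(records$trial_id[duplicated(records$trial_id)])
  if (length(multi) > 0L) {
    message("multi-arm trials contributing several comparisons: ",
            paste(multi, collapse = ", "))
  }

  results <- list()
  grid_rows <- function(recs, subgroup_name, cfg) {
    rows <- list()
    for (fam in definition_families()) {
      fam_recs <- .subset_family(recs, fam)
      for (fe in .final_endpoints) {
        cell <- .run_cell(fam_recs, fam, fe, subgroup_name, cfg)
        rows[[length(rows) + 1L]] <- cell$row
        if (!is.null(cell$result)) {
          key <- paste(fam$key, fe, subgroup_name, sep = ".")
          results[[key]] <<- cell$result
        }
      }
    }
    do.call(rbind, rows)
  }

  table1 <- grid_rows(records, "overall", config)
  table2_parts <- lapply(config$subgroups, function(sg) {
    sub_cfg <- config
    sub_cfg$estimand_policy <- sg$estimand_policy
    grid_rows(filter_subgroup(records, sg), sg$name, sub_cfg)
  })
  table2 <- if (length(table2_parts)) do.call(rbind, table2_parts)
            else table1[0, , drop = FALSE]
  rownames(table1) <- NULL
  rownames(table2) <- NULL

  heterogeneity <- list()
  for (ep in .endpoints) {
    est <- endpoint_estimates(records, ep, zero_cell = config$zero_cell)
    heterogeneity[[ep]] <- if (nrow(est) >= 2L) {
      pool_effects(est, model = "random_dl", level = config$ci_level)
    } else {
      NULL
    }
  }

  structure(list(
    table1 = table1, table2 = table2, results = results,
    heterogeneity = heterogeneity,
    metadata = list(
      dataset_hash = rlang::hash(as.data.frame(records)),
      n_comparisons = nrow(records),
      n_trials = length(unique(records$trial_id)),
      n_patients = sum(records$n_treat + records$n_control),
      config = unclass(config)[setdiff(names(config), "subgroups")],
      subgroups = vapply(config$subgroups, `[[`, character(1), "name"),
      package_version = as.character(utils::packageVersion("surrotrial")))),
    class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> %d comparisons, %d trials, %s patients\n",
              x$metadata$n_comparisons, x$metadata$n_trials,
              format(x$metadata$n_patients, big.mark = ",")))
  cat("main grid:\n")
  print(.round_table(x$table1)[, c("analysis", "endpoint", "comparison_pairs",
                                   "r2", "r2_lo", "r2_hi", "label_ci")])
  invisible(x)
}

.round_table <- function(tab) {
  num <- c("slope", "slope_lo", "slope_hi", "r2", "r2_lo", "r2_hi")
  for (col in num) tab[[col]] <- round(tab[[col]], 2)
  tab
}

#' Serialize an analysis report
#'
#' `csv` writes `table1.csv` and `table2.csv` at the two-decimal table
#' convention; `json` writes `report.json` at full precision; `markdown`
#' writes `report.md`. Reports contain no wall-clock timestamps, so reruns on
#' identical input are byte-identical.
#'
#' @param report An `analysis_report`.
#' @param format `"csv"`, `"json"` or `"markdown"`.
#' @param dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
render_report <- function(report, format = c("csv", "json", "markdown"),
                          dir = ".") {
  format <- match.arg(format)
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  if (format == "csv") {
    f1 <- file.path(dir, "table1.csv"); f2 <- file.path(dir, "table2.csv")
    utils::write.csv(.round_table(report$table1), f1, row.names = FALSE, na = "")
    utils::write.csv(.round_table(report$table2), f2, row.names = FALSE, na = "")
    files <- c(f1, f2)
  } else if (format == "json") {
    f <- file.path(dir, "report.json")
    payload <- list(metadata = report$metadata,
                    table1 = report$table1, table2 = report$table2,
                    heterogeneity = lapply(report$heterogeneity, function(h) {
                      if (is.null(h)) NULL else unclass(h)
                    }))
    jsonlite::write_json(payload, f, auto_unbox = TRUE, digits = NA,
                         na = "null", null = "null", pretty = TRUE)
    files <- f
  } else {
    f <- file.path(dir, "report.md")
    files <- f
    md_table <- function(tab) {
      tab <- .round_table(tab)
      cols <- c("analysis", "endpoint", "subgroup", "comparison_pairs", "rcts",
                "n", "regression_formula", "slope", "r2", "r2_lo", "r2_hi",
                "label_ci", "label_point")
      tab <- tab[, cols]
      fmt <- function(v) ifelse(is.na(v), "", as.character(v))
      lines <- c(paste0("| ", paste(cols, collapse = " | "), " |"),
                 paste0("|", paste(rep("---", length(cols)), collapse = "|"), "|"))
      for (i in seq_len(nrow(tab))) {
        lines <- c(lines, paste0("| ", paste(vapply(tab[i, ], fmt, character(1)),
                                             collapse = " | "), " |"))
      }
      lines
    }
    writeLines(c("# Surrogacy evaluation report", "", "## Main analyses", "",
                 md_table(report$table1), "", "## Subgroup analyses", "",
                 md_table(report$table2)), f)
  }
  invisible(files)
}
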