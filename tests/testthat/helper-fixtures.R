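# fixtures are built in code: one schema-conformant comparison row with
# overridable fields, and a small hand-specified dataset

make_comparison <- function(comparison_id = "C001", trial_id = "RCT001",
                            first_enrollment_year = 2012L,
                            follow_up_months = 12, region = "non_east_asia",
                            acs_population = FALSE,
                            major_minor_definition = "barc_235",
                            major_definition = "barc_35",
                            n_treat = 400L, n_control = 400L,
                            bleed_major_treat = 8L, bleed_major_control = 12L,
                            bleed_major_minor_treat = 20L,
                            bleed_major_minor_control = 30L,
                            death_all_treat = 10L, death_all_control = 11L,
                            death_cv_treat = 6L, death_cv_control = 7L,
                            reported_or = NA_real_, reported_or_lo = NA_real_,
                            reported_or_hi = NA_real_,
                            reported_hr = NA_real_, reported_hr_lo = NA_real_,
                            reported_hr_hi = NA_real_) {
  data.frame(trial_id = trial_id, comparison_id = comparison_id,
             first_enrollment_year = first_enrollment_year,
             follow_up_months = follow_up_months, region = region,
             acs_population = acs_population,
             major_minor_definition = major_minor_definition,
             major_definition = major_definition,
             n_treat = n_treat, n_control = n_control,
             bleed_major_treat = bleed_major_treat,
             bleed_major_control = bleed_major_control,
             bleed_major_minor_treat = bleed_major_minor_treat,
             bleed_major_minor_control = bleed_major_minor_control,
             death_all_treat = death_all_treat,
             death_all_control = death_all_control,
             death_cv_treat = death_cv_treat, death_cv_control = death_cv_control,
             reported_or = reported_or, reported_or_lo = reported_or_lo,
             reported_or_hi = reported_or_hi,
             reported_hr = reported_hr, reported_hr_lo = reported_hr_lo,
             reported_hr_hi = reported_hr_hi, stringsAsFactors = FALSE)
}

make_records <- function(n = 5, ...) {
  rows <- lapply(seq_len(n), function(i) {
    make_comparison(comparison_id = sprintf("C%03d", i),
                    trial_id = sprintf("RCT%03d", i), ...)
  })
  trial_comparisons(do.call(rbind, rows))
}

# printed Table-1 main grid: (r2, lo, hi, n_pairs) as published, used by the
# classification acceptance check
table1_printed <- function() {
  data.frame(
    analysis = c("study_mm", "barc_mm", "timi_mm", "study_mm", "barc_mm",
                 "timi_mm", "study_major", "barc_major", "timi_major",
                 "study_major", "barc_major", "timi_major"),
    endpoint = rep(c("death_all", "death_all", "death_all", "death_cv",
                     "death_cv", "death_cv"), 2),
    r2 = c(0.09, 0.18, 0.49, 0.09, 0.05, 0.21,
           0.03, 0.00, 0.06, 0.01, 0.02, 0.01),
    lo = c(0.00, 0.00, 0.14, 0.00, 0.00, 0.00,
           0.00, 0.00, 0.00, 0.00, 0.00, 0.00),
    hi = c(0.26, 0.48, 0.84, 0.27, 0.26, 0.58,
           0.13, 0.02, 0.23, 0.05, 0.15, 0.06),
    n_pairs = c(43, 23, 19, 40, 21, 18, 53, 22, 35, 49, 20, 32))
}
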