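---
title: "Trial-level surrogacy of bleeding for mortality: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trial-level surrogacy of bleeding for mortality: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surrotrial)
```

## The question and the unit of analysis

Antithrombotic trials in coronary artery disease report bleeding as a safety
endpoint and frequently fold it into composites alongside death. Treating a
bleeding effect as if it stood in for a mortality effect presumes
*trial-level surrogacy*: across randomized comparisons, the treatment effect
on bleeding should predict the treatment effect on death. `surrotrial`
evaluates exactly that association. The unit of analysis is a randomized
pairwise comparison — a two-arm trial contributes one row, a multi-arm trial
one row per experimental-versus-control contrast, sharing a `trial_id`.
Rows are treated as independent; no shared-control adjustment is applied,
and repeated `trial_id`s are flagged in the log so the analyst can judge the
(typically small) induced correlation. Counts use randomized
(intention-to-treat) denominators, which also supply the regression weights.

Four endpoints are carried per comparison: trial-defined major bleeding,
trial-defined major/minor bleeding, all-cause death, and cardiovascular
death, each definable under BARC, TIMI, or GUSTO-style criteria. A trial
that did not report an endpoint has empty cells — deliberately distinct from
zero events — and simply drops out of analyses needing that endpoint, which
is why the pair count differs between endpoint pairings.

## Effect estimation

Each 2×2 table yields the cross-product odds ratio on the natural-log scale
with the Woolf variance `1/a + 1/b + 1/c + 1/d`. Zero cells: the package
adds 0.5 to all four cells whenever any cell is zero (Haldane–Anscombe), the
dominant meta-analytic convention; `zero_cell = "exclude"` drops zero-cell
tables instead, as a sensitivity switch. Tables with zero events in *both*
arms carry no information about a ratio under either convention and are
always excluded (with a warning), never imputed. Reported ratio estimates
with confidence intervals are converted by
`se = (log hi − log lo) / (2 × 1.959964)`; a degenerate interval is rejected
rather than silently producing `se = 0`.

The per-comparison table has single `reported_or` / `reported_hr` fields.
The package reads the reported hazard ratio as the trial's published
treatment effect on the *final* (mortality) endpoint, since that is the
effect trials report as an HR; the HR sensitivity track
(`estimand_policy = "hr_reported"`) therefore restricts to comparisons with
a reported HR and regresses log HR(death) on the count-based log OR
(bleeding), keeping patient weights. The primary analysis always recomputes
odds ratios from counts, even when a ratio was published.

## The trial-level regression

With weights `w` (randomized patients), the final-endpoint log-ORs `y` are
regressed on surrogate log-ORs `x` by weighted least squares; `R²` is
`1 − Σw e² / Σw (y − ȳ_w)²`, identical to the squared weighted Pearson
correlation. Patient weighting (rather than inverse-variance) is the primary
specification because the weight should reflect the amount of randomized
evidence per trial, not the rarity of one endpoint;
`weighting = "inverse_variance"` (weights `1/(se_x² + se_y²)`) is available
as a sensitivity. All outputs are invariant to rescaling the weights. The
slope interval uses a t quantile on `n − 2` degrees of freedom with the
weighted residual mean square — a choice the literature rarely states
explicitly, flagged here as the package's own convention.

The confidence interval for `R²` is the first-order delta method:
`sd = sqrt(4 R² (1 − R²)² / (n − 3))` with a standard-normal quantile,
limits clipped to [0, 1]. This closed form reproduces, at the two-decimal
table convention, the published bounds of the motivating meta-analysis from
their printed `(R², n)` inputs across six independent rows, which is the
package's acceptance check (`scripts/acceptance.R`). Two caveats are worth
recording. First, the interval degenerates to a point at `R² ∈ {0, 1}` and
is unreliable for very small `n`; below 4 pairs it is reported as missing
(the smallest supported cell, 4 pairs, mirrors the smallest published
subgroup with an interval). Second, applying the formula to *rounded* point
estimates cannot always reproduce published bounds — with `R²` printed at
two decimals the reconstructed bound can be off by one unit in the second
decimal, and one published 8-pair subgroup bound is not reproducible from
its printed inputs at all; such rows are simply outside what desk
recomputation can check.

Classification uses two prespecified schemes: by confidence bound (lower
limit > 0.72 strong, upper limit < 0.50 weak, otherwise inconclusive) and by
point estimate (≥ 0.7 strong, 0.5–0.69 moderate, < 0.5 weak). They answer
different questions — the first demands demonstrated strength, the second
describes the estimate — and can disagree: an `R²` of 0.76 with interval
0.61–1.00 is "strong" by point estimate yet inconclusive by bound. A wide
interval straddling 0.50 is inconclusive even when the point estimate is
tiny; weakness, too, must be demonstrated.

## Heterogeneity

Per-endpoint pooling is standard inverse-variance meta-analysis and is
delegated to `metafor::rma.uni`: DerSimonian–Laird `tau²` (truncated at
zero) by default, fixed-effect as a flag, normal-quantile intervals,
Cochran's `Q` and `I² = max(0, (Q − df)/Q) × 100` (which coincides with the
`tau²`-based definition under DerSimonian–Laird). Pooling is per-comparison;
collapsing multi-arm trials to one record first is left to the analyst. No
small-study asymmetry test is run — funnel substrates are exported for
visual inspection only.

## The synthetic meta-analysis

`generate_dataset()` draws, per comparison, true log-OR effects
`(θ_S, θ_T)` from a bivariate normal with correlation `rho_trial`, shifts
logit-scale control risks by the relevant `θ`, and draws binomial counts per
arm; `rho_trial²` is thus the true trial-level `R²` in the no-measurement-
error limit. Defaults emulate the meta-analysis the package was built
around: 58 comparisons from ~48 trials of ≥ 500 patients (log-uniform sizes
500–10,000, total ≈ 180,000 patients), control-arm risks of 5% (major/minor
bleeding; major fixed at half) and 4% (all-cause death; cardiovascular at
0.6), per-trial logit jitter 0.3, mean effects −0.2 (bleeding) and −0.05
(death) with between-trial SDs 0.35 and 0.15, `rho_trial = 0.3`, about a
fifth of comparisons East Asian, enrollment years 2001–2020, follow-up
clustered at 12 months, TIMI/BARC-dominated definitions, and incomplete
endpoint reporting so pair counts differ by pairing. Where the motivating
study reports no value (SDs, risks, jitter, reporting rates) the defaults
are one-time choices of plausible magnitudes for contemporary DAPT trials,
not tuned quantities.

What the generator does *not* emulate: within-trial correlation between
bleeding and death counts (fatal bleeds are both), time-to-event structure
(reported HRs are synthesized from the realized death table), shared control
arms, and publication selection. Passing tests therefore validate the
estimator chain under the stated sampling model, not the epidemiology of
real extraction.

Two structural facts about the estimator matter when interpreting recovery
experiments. Binomial sampling error *attenuates* the estimated `R²` below
`rho_trial²` when within-trial error is non-negligible relative to the
between-trial SDs — an expected property, documented rather than corrected.
The parameter-recovery acceptance run therefore uses a low-attenuation
regime chosen analytically (attenuation `λ = sd²/(sd² + se²) ≈ 0.98` per
axis: 200 trials of 5,000–50,000 patients, control risks 0.25, SDs 0.5),
where the chain is near-unbiased for `rho² = 0.81`; at the paper-scale
defaults the same chain legitimately reports much smaller `R²`. Conversely,
at `rho_trial = 0` the weighted `R²` is biased *up* by roughly `1/(k − 1)`,
vanishing as the number of trials grows. Coverage of the delta-method
interval at `rho_trial²` is reported by `recovery_experiment()`, not
asserted: the delta method is approximate (observed ≈ 94% in the validation
regime) and attenuation shifts the estimand at small trial sizes.

## Numerical and reporting conventions

Natural logs throughout; `z_0.975 = 1.959964`. Era splits on first
enrollment year with 2010 in the early stratum ("before 2010" vs "after
2011"); follow-up of exactly 12 months is "≤ 12 months". "Study defined"
rows pool all definitions of a family. Cells with fewer than 2 informative
pairs are reported with a reason code, never dropped silently; 2–3 pairs
give point estimates without an `R²` interval. Tables render at two
decimals (negative zero normalized to `0.00`); JSON keeps full precision.
Reports embed a dataset hash, a config echo and the package version, and are
free of wall-clock timestamps so identical inputs give byte-identical
output. Computations in the test suite and acceptance script run at sizes
chosen for tightness of the Monte-Carlo check (e.g. 200 replicates of 200
trials), each completing in seconds to a couple of minutes.

## Known limitations

Trial-level surrogacy only: no individual-level association, no surrogate
threshold effect, no Bayesian bivariate meta-analytic model. No
reconstruction of time-to-event data from curves, no risk-difference or
rate-ratio estimands, no literature-screening or risk-of-bias tooling. The
published per-trial extraction behind the motivating analysis is not
machine-readable, so printed slopes, `I²` values and subgroup rows that
depend on it are context for interpretation, not recomputable targets.
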