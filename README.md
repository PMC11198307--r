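# surrotrial

Trial-level surrogate-endpoint evaluation for meta-analyses of randomized
coronary-artery-disease trials: does a treatment's effect on **nonfatal
bleeding** predict its effect on **death**?

Composite endpoints in antithrombotic trials routinely mix major (or
major/minor) bleeding with all-cause or cardiovascular mortality, implicitly
treating a prevented bleed like a prevented death. Whether that is justified
is an empirical question about *trial-level surrogacy*: across randomized
comparisons, the treatment effect on the surrogate should predict the
treatment effect on the final endpoint. `surrotrial` implements that
evaluation for meta-analysts working from per-comparison event tables, and
ships a seeded synthetic-trial generator so the whole chain can be validated
without any external data.

## The model

Each randomized comparison *i* contributes a 2×2 table per endpoint, turned
into a log odds ratio by the cross-product with the Woolf variance

> log OR = log(ad/bc),  se² = 1/a + 1/b + 1/c + 1/d,

adding 0.5 to all four cells when any cell is zero (Haldane–Anscombe);
comparisons with zero events in both arms are non-informative and excluded.
The final-endpoint effects are regressed on the surrogate effects, weighted
by the number of randomized patients n_i:

> ŷ_i = α + β·x_i,   minimizing Σ n_i (y_i − ŷ_i)²,

and the trial-level coefficient of determination R²_trial (the squared
weighted correlation) measures surrogacy: 1 is a perfect trial-level
surrogate, 0 none. Its 95% confidence interval uses the delta-method
standard deviation

> sd(R²) = √( 4 R² (1 − R²)² / (n − 3) ),

clipped to [0, 1]. Surrogacy is classified under two prespecified schemes:
by confidence bound (lower limit > 0.72 → strong; upper limit < 0.50 → weak;
otherwise inconclusive) and by point estimate (R² ≥ 0.7 strong, 0.5–0.69
moderate, < 0.5 weak). Per-endpoint effects are additionally pooled by
inverse-variance meta-analysis (DerSimonian–Laird random effects) with
Cochran's Q, tau², and I², and funnel-plot substrates.

## Worked example

```r
library(surrotrial)

# a synthetic meta-analysis: 58 comparisons, weak surrogacy (rho = 0.3)
config <- synthetic_config(rho_trial = 0.3, seed = 42)
trials <- generate_dataset(config)

pairs <- build_pairs(trials, "bleed_major_minor", "death_all")
surrogacy_analysis(pairs)
#> <surrogacy_result> bleed_major_minor -> death_all
#>   48 pairs, 41 trials, 157,902 patients
#>   -0.05 + 0.09*log(OR_bleeding)
#>   slope 0.09 (-0.05 to 0.23); R2 0.04 (0.00 to 0.14) [weak / weak]
```

The slope says a halving of bleeding odds predicts only a ~6% change in
death odds (0.09 × log 0.5), and R² = 0.04 (95% CI 0.00–0.14) means the
bleeding effect explains almost none of the between-comparison variation in
the mortality effect — its upper confidence limit below 0.50 labels the
pairing *weak* under the confidence-bound scheme, as expected when the
generating trial-level correlation is 0.3 and event counts add noise.

The full grid (6 bleeding-definition families × 2 mortality endpoints, plus
subgroups by era, follow-up, region, and ACS population) with per-endpoint
heterogeneity:

```r
report <- run_full_analysis(trials)
report
#> <analysis_report> 58 comparisons, 49 trials, 176,544 patients
#> main grid:
#>                        analysis  endpoint comparison_pairs   r2 r2_lo r2_hi label_ci
#> 1  Study defined major or minor death_all               48 0.04     0  0.14     weak
#> 2  Study defined major or minor  death_cv               38 0.00     0  0.01     weak
#> ...
render_report(report, "csv", "results/")   # table1.csv, table2.csv
render_report(report, "json", "results/")  # full precision

report$heterogeneity$bleed_major_minor
#> <heterogeneity_result> k = 48 (random_dl)
#>   pooled log effect -0.2299 (-0.3415 to -0.1184)
#>   Q = 211.926 on 47 df, tau2 = 0.1024, I2 = 77.8%
```

A shell entry point wraps the same functions:

```sh
SCRIPT=$(Rscript -e 'cat(system.file("scripts","surrotrial.R",package="surrotrial"))')
Rscript "$SCRIPT" simulate --config sim.json --out trials.csv
Rscript "$SCRIPT" run --input trials.csv --out results/
Rscript "$SCRIPT" plot --input trials.csv --pairing bleed_major_minor:death_all --out scatter.pdf
Rscript "$SCRIPT" recover --config sim.json --reps 200 --out recovery.json
```

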