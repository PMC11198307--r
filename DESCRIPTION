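Package: surrotrial
Title: Trial-Level Surrogacy Evaluation for Bleeding and Mortality Endpoints
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Evaluates whether a treatment effect on a candidate surrogate
    endpoint (nonfatal major or major/minor bleeding) predicts the treatment
    effect on a final endpoint (all-cause or cardiovascular death) across
    randomized trials of antithrombotic strategies in coronary artery disease.
    Computes per-comparison odds ratios from 2x2 event tables with
    Haldane-Anscombe handling of zero cells, regresses final-endpoint log odds
    ratios on surrogate log odds ratios weighted by the number of randomized
    patients, attaches a delta-method confidence interval to the trial-level
    coefficient of determination, classifies surrogacy under confidence-bound
    and point-estimate threshold schemes, pools effects with DerSimonian-Laird
    random-effects heterogeneity statistics, runs the prespecified subgroup
    grid, and provides a seeded synthetic-trial generator with
    parameter-recovery experiments so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    metafor,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
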