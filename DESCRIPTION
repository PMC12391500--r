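Package: cismr
Title: Cis-Mendelian Randomisation of Drug-Target Effects from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-sample cis-Mendelian randomisation for drug-target proxies,
    built around a CRP-weighted IL-6 receptor instrument and a binary infection
    outcome. Reads and validates GWAS summary statistics, constructs cis-pQTL
    instruments (region selection, significance and concordance filters, greedy
    LD clumping, F-statistic screen), harmonises exposure and outcome alleles,
    and estimates causal effects with Wald ratios, fixed-effects inverse-variance
    weighting, MR-Egger, Cochran's Q, radial outlier removal, leave-one-out and
    Steiger directionality tests. Includes a summary-statistics simulator with
    known ground truth so every stage is testable without external data, and a
    config-driven pipeline reproducing the full sensitivity battery in one run.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
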