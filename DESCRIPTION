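Package: helminthscan
Title: Environmental-Correlation Selection Scans Against Helminth Diversity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects human SNPs whose population allele frequencies track the
    diversity of helminth (parasitic worm) species transmitted across
    geographic regions. Builds country-level environmental variables from
    pathogen presence/absence and prevalence-survey tables, runs a genome-wide
    tie-corrected Kendall rank-correlation scan with a two-gate significance
    call (Bonferroni plus a MAF-matched empirical 95th-percentile null),
    re-tests hits against climate confounders, assigns SNPs to genes under
    strand-aware upstream-window rules, and tests gene sets for enrichment by
    SNP-count-matched resampling. Ships a Balding-Nichols simulator that
    generates complete synthetic panels with planted selected SNPs so the whole
    pipeline is testable end to end with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
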