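Package: mrpipe
Title: Cross-Species Master Regulator Discovery and Clinical Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies conserved master regulators (MRs) of disease progression
    from two-group expression cohorts in two species. Builds Welch t-statistic
    differential signatures, translates mouse signatures into human gene space
    through ortholog maps, scores regulon enrichment with a weighted
    Kolmogorov-Smirnov running sum and gene-permutation normalized enrichment
    scores, infers MR activity from signed regulons (MARINa-style), integrates
    species-level MR lists with Stouffer's method, and prioritizes candidates
    clinically with univariate Cox screening, k-means patient stratification,
    Kaplan-Meier/log-rank analysis and an empirical random-MR-set null model.
    Includes a synthetic-data generator with planted regulator activity so the
    whole pipeline is testable end to end without external cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    optparse
Config/testthat/edition: 3
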