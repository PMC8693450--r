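Package: dysbindex
Title: Gut Microbial Dysbiosis Index and Cohort Microbiome Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits and applies a disease-associated gut microbial dysbiosis
    index from genus-level 16S feature tables: prevalence filtering, Wilcoxon
    rank-sum differential-genus selection (exact small-sample p-values by
    complete enumeration), and a weighted enriched-minus-depleted relative
    abundance score. Companion beta-diversity tools compute unweighted and
    weighted UniFrac distances from a rooted phylogeny, principal coordinates
    ordination, per-sample distance-to-reference summaries and PERMANOVA.
    Association tools provide Spearman correlation with exact permutation
    p-values at small n, index-versus-clinical-score analysis, taxon-versus-
    outcome screens, Pearson chi-square and comparative-Ct relative
    expression. A Dirichlet-multinomial cohort simulator with planted
    enriched and depleted genera, clinical severity scores linked to latent
    dysbiosis, and a germfree-mouse outcome study generator make the whole
    pipeline testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
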