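Package: nrf2screen
Title: SWI/SNF Mutation and NRF2 Pathway Activity Screening in Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline linking SWI/SNF chromatin-remodeling subunit
    mutations (ARID1A, ARID1B, ARID2, PBRM1) to KEAP1-NRF2-CUL3 pathway
    transcriptional activity across tumor cohorts. Provides readers for
    count/MAF/Gistic/GMT inputs, alteration calling with confound-filtered
    group construction, TMM normalization and moderated-t differential
    expression, derivation of a centroid-classifier NRF2 activity signature
    with high-confidence sample filtering and cross-cohort intersection,
    signal-to-noise ranked gene set enrichment with a permutation null,
    two-proportion co-occurrence statistics, and a negative-binomial
    synthetic cohort generator with planted ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    edgeR,
    limma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
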