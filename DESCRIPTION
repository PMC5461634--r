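Package: LncRIndiv
Title: Individual-Level Differential Expression of lncRNAs from
    Reversed Expression Orderings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Calls differentially expressed lncRNAs in individual cancer
    samples from the reversal of within-sample expression orderings that
    are stable across normal tissue. Pairs of lncRNAs whose expression
    order holds in more than 95% of normal samples are tested for
    significant reversal in cancer (one-sided Fisher's exact test,
    Benjamini-Hochberg FDR); each lncRNA is then called up- or
    down-regulated per sample by a strict majority vote over its three
    lowest-variation reversal partners. Includes a synthetic-data
    generator and evaluation protocol (sensitivity, specificity,
    F-score, paired-sample consistency), a forward-selection procedure
    for prognostic signatures ranked by Harrell's concordance index with
    exportable threshold-free decision rules, and a hypergeometric test
    of concordance between individual DE calls and copy-number states.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    survival
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'pairs.R'
    'indiv.R'
    'simulate.R'
    'evaluate.R'
    'cna.R'
    'io.R'
    'prognosis.R'
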