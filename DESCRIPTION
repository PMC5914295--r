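Package: editscope
Title: A-to-I RNA Editing Detection, Differential Editing, and
    Editing-Isoform Quantification
Version: 0.1.0
Authors@R:
    person("editscope", "developers", email = "editscope@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for A-to-I RNA editing analysis from
    stranded RNA-seq and amplicon deep re-sequencing data.  Calls
    candidate A-to-G editing sites from strand-resolved pileups with
    coverage and mean-frequency thresholds, masks known variants, and
    screens candidates with strand-bias, read-position-bias and
    variant-distance-bias filters.  Tests differential editing between
    genotypes by per-site binomial logistic regression with
    likelihood-ratio analysis of deviance and Benjamini-Hochberg FDR
    control.  Quantifies phased multi-site editing isoforms of an
    amplicon by enumerating all 2^k edited haplotypes ("artificial
    chromosomes") and assigning reads by their base pattern at the
    editable positions.  A synthetic-read generator with fully known
    editing truth makes every stage verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    methods,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
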