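Package: svcohort
Title: Population-Scale Structural Variant Callset Assembly, Merging and
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for assembling population-scale structural variation
    (SV) callsets from per-sample breakpoint discovery VCFs.  Cross-sample
    merging models positional uncertainty with per-base breakpoint
    probability distributions (LUMPY-style PRPOS/PREND annotations),
    refining coordinates by the weight of evidence at each base.  Merged
    callsets are assembled into cohort-level VCFs, annotated with allele
    frequencies and copy number, and re-classified into deletions,
    duplications, inversions, mobile-element insertions and generic
    break-ends using regression of copy number on allele balance, a
    naive-Bayes read-depth classifier, mobile-element annotation overlap
    and inverted-breakpoint pairing.  Includes redundancy pruning,
    confidence scoring, trio Mendelian-error QC, truth-set sensitivity
    evaluation, VCF/BEDPE interconversion and a synthetic-cohort generator
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
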