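Package: poolDEG
Title: Pooled Extreme-Phenotype Candidate-Gene Discovery from Expression Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential-expression analysis for bulked-segregant style
    transcriptomics, in which RNA pools of seedlings with opposite extreme
    phenotypes are contrasted on a microarray. Implements joint fold-change
    and Student t-test DEG calling, three-way reference-concordance
    filtering against a reference variety, Venn/union assembly of
    candidate sets, random gene-set Kruskal-Wallis validation, Poisson
    set-overlap significance, generic GO term enrichment with
    Benjamini-Hochberg FDR, and qPCR delta-Ct concordance checks, together
    with a synthetic-data generator with planted truth that reproduces the
    9-group, 3-replicate study structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
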