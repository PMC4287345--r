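Package: edrug
Title: Region-Centric Pharmacogenomic Association Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Associates missense mutations in protein functional regions
    (Pfam-style domains, predicted domains and intrinsically disordered
    regions) with the activity of anticancer drugs in cell-line panels.
    Implements a three-stage Wilcoxon rank-sum testing procedure that
    contrasts region-mutated against unmutated and other-region-mutated
    samples and excludes signals already visible at the whole-gene level,
    a charge/hydropathy (FoldIndex-style) disorder predictor for defining
    disordered regions, a synthetic-cohort simulator with planted
    region-drug effects for power and calibration studies, and downstream
    validation analyses: Kaplan-Meier/log-rank patient stratification,
    expression-by-mutation-status group tests, drug-target overlap testing
    with Tanimoto chemical-similarity expansion, and GO term enrichment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
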