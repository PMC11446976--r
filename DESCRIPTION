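Package: proteoSubtype
Title: Proteogenomic Subtyping of Driver-Negative Never-Smoker Lung Adenocarcinoma
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Signature-based molecular subtyping of paired RNA/protein tumour
    cohorts, built around never-smoker lung adenocarcinoma without EGFR/ALK
    driver alterations. Provides single-sample GSEA (rank-weighted running-sum)
    scoring of expression matrices against gene-set collections, ESTIMATE-style
    immune/stromal scores, a cascaded four-subgroup classifier (proliferation,
    immune, angiogenesis, metabolism), integrative copy-number cis/trans
    correlation mapping, cancer-germline-antigen outlier detection,
    subgroup-level statistics, protein co-expression network modules with
    k-core filtering, Kaplan-Meier/log-rank/Cox survival analysis, and a fully
    labelled synthetic cohort generator so the whole pipeline is testable
    without access-controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    survival,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cga.R'
    'io.R'
    'enrichment.R'
    'integration.R'
    'stats.R'
    'network.R'
    'survcurves.R'
    'subtype.R'
    'simulate.R'
    'pipeline.R'
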