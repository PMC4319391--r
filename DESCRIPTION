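Package: pascloud
Title: Pathway Activation Scoring and Signaling Pathway Cloud Drug Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies signaling pathway activation strength (PAS) and
    signaling pathway cloud disturbance (SPCD) from case-versus-control gene
    expression data, using role-annotated pathway gene sets in which each
    member gene carries a signed activator/repressor weight. Pathway-level
    scores gate each gene's fold change through a tolerance filter (fold
    bounds plus a standard-deviation criterion) before summing signed log
    ratios. The resulting set of activated and repressed pathways (the
    signaling pathway cloud) serves as a transcriptomic fingerprint of a
    condition; candidate drugs are ranked by how well their own pathway
    activation signatures mimic, reverse, or exaggerate that cloud.
    Includes Fisher's-exact pathway enrichment for gene lists, a seeded
    synthetic-data generator with known ground truth, and a command-line
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    limma,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
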