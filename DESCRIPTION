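Package: ptmdriver
Title: Detection of Proteins with Mutation-Enriched Post-Translational
    Modification Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate disease-driver proteins whose
    post-translational modification (PTM) motif regions carry a
    significantly elevated somatic mutation rate relative to the rest of
    the protein. Known modification sites are expanded into +/-7 residue
    motif regions and merged per protein; cohort mutation counts in the
    merged modification region and the remaining background are modelled
    as Poisson with conjugate Gamma priors on the two rates, and each
    protein is scored by the posterior probability that the relative rate
    R = lambda1/lambda2 does not exceed one. Benjamini-Hochberg correction
    across proteins yields driver calls at a chosen q-value threshold.
    Includes readers for PTM catalogs, proteomes and protein-level
    mutation tables (TSV or pre-annotated VCF), a truth-labelled synthetic
    cohort generator for calibration and power studies, per-mutation
    functional annotation, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    VariantAnnotation,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
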