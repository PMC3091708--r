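Package: ventannot
Title: Annotation Triage for De Novo 454 Transcriptome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the annotation triage of de novo transcriptome
    assemblies from pyrosequencing EST projects without a reference
    genome, as applied to hydrothermal-vent mussel gill tissue. Covers
    adapter trimming, poly-A masking and length gating; a three-tier
    reading-frame cascade (strict and relaxed homology tiers plus a
    codon-usage log-odds coding scanner with null-calibrated threshold);
    Gene Ontology DAG propagation counting with once-per-product
    deduplication; a bacterial-fingerprint screen over ranked homology
    hits with taxonomy lineage verification; a two-database comparison
    with shared-annotation percentages; and comparative-CT (delta-delta
    CT) expression quantification. A synthetic-data module generates
    every pipeline input with ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
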