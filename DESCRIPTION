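Package: mqtlnet
Title: Marker-Metabolite Multi-Omics QTL Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of trait-marker metabolites in a crop
    association panel: two-year consistent trait-metabolite correlation with
    broad-sense heritability, linear-mixed-model genome-wide association for
    metabolites and gene expression (mGWAS/eGWAS) with kinship correction,
    per-gene transcriptome-wide association (mTWAS), positional 100-kb QTL
    blocking and hotspot detection, soft-thresholded co-expression modules
    with eigengenes, haplotype group tests at lead variants, and assembly of
    the tripartite metabolite-QTL-gene colocalization network.  Ships a
    synthetic multi-omics cohort generator with planted ground truth so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
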