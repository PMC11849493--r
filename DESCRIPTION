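Package: nitrivir
Title: Soil Nitrifier Virome Analysis with Synthetic Ground Truth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for targeted-incubation soil virome
    analysis centred on nitrifying prokaryotes (ammonia-oxidizing archaea and
    bacteria, and Nitrospira). Clusters viral contigs into viral operational
    taxonomic units (vOTUs) at the MIUViG thresholds (95% average nucleotide
    identity over 85% of the shorter contig), predicts nitrifier hosts with a
    criteria-explicit shared-homolog procedure backed by hallmark genes, CRISPR
    spacer scans and a hypergeometric gene-sharing network, quantifies virus and
    host enrichment under differential-inhibition treatments (urea with DMPP,
    1-octyne or acetylene), demarcates putative virus families from normalized
    translated genome similarity, and quantifies auxiliary metabolic genes
    against a gene-length and copy-number host-contamination null. A synthetic
    community generator emits hosts, proviruses, viruses, treatment dynamics and
    virome reads with full ground truth, so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    data.table,
    igraph,
    ape,
    car,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
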