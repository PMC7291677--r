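Package: ppinet
Title: Integration, Quality Control and Confidence Scoring of Curated
    Protein-Protein Interaction Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds seed-centred protein-protein interaction (PPI) networks
    by integrating PSI-MITAB evidence from multiple primary interaction
    databases. Records are acquired per query protein (live through
    PSICQUIC, or from local per-provider files for fully reproducible
    offline runs), quality-filtered on completeness of curation (single
    PubMed identifier, annotated detection method, matching taxonomy),
    detection-method codes are clustered into technique categories via a
    conversion table, and evidence is merged across databases into unique
    undirected interactions scored by the number of distinct method
    categories plus the number of distinct publications. Includes a
    Caenorhabditis elegans mode driven by a local WormBase-style
    interaction dump, a synthetic fixture generator with ground-truth
    manifests for end-to-end validation, and writers for the
    Cytoscape-ready network table and run log files.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
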