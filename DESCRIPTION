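Package: rleinhib
Title: Rate-Limiting Enzymes in Metabolic Inhibitory Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs product-mediated enzyme inhibiting pairs from enzyme,
    product and inhibitor tables, quantifies the role of rate-limiting enzymes
    (RLEs) as inhibitor providers and targets per pathway category and across
    pathways, scores the functional linkage of pair members with the Jaccard
    similarity of phylogenetic presence/absence profiles over a reference
    genome panel, and identifies inhibiting pairs conserved across organisms,
    including compound-initiation comparisons such as ADP versus AMP. A
    parameterised synthetic-data generator with planted enrichment,
    profile-coupling and conservation structure makes every pipeline stage
    testable without database access.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stats,
    utils,
    tools,
    jsonlite,
    ggplot2,
    generics,
    digest
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
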