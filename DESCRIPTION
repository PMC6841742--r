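Package: comorbnet
Title: Shared-Gene Analysis for Comorbid Disease Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies and characterizes genes shared between two comorbid
    diseases by integrating heterogeneous evidence channels (monogenic
    phenotype annotations, coding GWAS variants, eQTL-regulated genes,
    differential expression, text mining, drug targets), detecting
    overlapping functional modules on a gene interaction network with a
    clique-seeded agglomerative algorithm selected by extended modularity,
    and testing drug-target overrepresentation and eQTL-sharing hypotheses
    with exact tests and a matched permutation null. Ships a synthetic-data
    generator that plants known structure (shared genes, network modules,
    cross-disease drug overlaps, eQTL sharing) so the whole pipeline is
    testable without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    fgsea,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
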