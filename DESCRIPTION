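Package: doeqtl
Title: Expression QTL Mapping, Hotspot Detection, and Mediation Analysis
    for Multiparent Mouse Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for systems-genetics analysis of gene expression in
    multiparent populations such as the Diversity Outbred (DO) mouse stock.
    Simulates eight-founder haplotype mosaics, genotype probabilities and
    two-cell-type expression with planted genetic architecture; filters,
    normalizes and rank-transforms expression; maps expression QTL with a
    founder-haplotype linear mixed model using leave-one-chromosome-out
    kinship correction; estimates permutation-based significance thresholds
    and Storey q-values; detects distant-eQTL hotspots by sliding window;
    classifies eQTL shared between cell types by peak proximity and founder
    effect correlation; and identifies candidate mediator genes with the
    LOD-drop statistic and genotype-controlled partial correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    IRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
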