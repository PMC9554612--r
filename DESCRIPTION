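Package: metaqtl
Title: Meta-QTL Analysis from Multi-Study QTL Compendia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for meta-analysis of quantitative trait loci (QTLs)
    collected from multiple linkage-mapping studies, as applied to grain
    protein content in wheat. Covers the full workflow: validation and
    completion of a QTL compendium (population-specific confidence-interval
    formulas, flanking-marker midpoints), construction of an order-consistent
    consensus linkage map by linear programming, projection of QTLs onto the
    consensus map, per-chromosome Gaussian-mixture clustering with
    five-criterion model selection (AIC, AICc, AIC3, BIC, AWE) to delineate
    meta-QTLs and QTL hotspots, anchoring of meta-QTL intervals to physical
    coordinates, cross-verification against genome-wide association hits,
    candidate-gene window extraction with expression filtering, and
    breeders'-MQTL selection. Includes a synthetic multi-study data generator
    with known ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    quantreg,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
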