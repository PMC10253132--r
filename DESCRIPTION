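Package: binmapqtl
Title: Bin-Map Construction and Composite Interval Mapping for F2 Resequencing Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building recombination-bin genetic maps from low-coverage
    whole-genome resequencing of biparental F2 populations and mapping
    quantitative trait loci on them. Implements marker filtering for aa x bb
    segregation (parent/offspring depth floors, minor allele frequency,
    chi-square segregation tests), 15-marker sliding-window genotyping with
    population-wide bin merging, EM estimation of pairwise recombination
    fractions, Kosambi map construction with minimum-spanning-tree marker
    ordering, composite interval mapping (Haley-Knott regression) with
    permutation-based genome-wide LOD thresholds and 1-LOD support intervals,
    and candidate-gene prioritisation that intersects QTL physical intervals
    with differential expression and soft-threshold coexpression networks
    (topological overlap, module eigengenes). A calibrated simulator of F2
    meiosis, low-coverage variant calls, correlated seed-colour phenotypes and
    structured expression matrices makes every stage testable against known
    ground truth.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    vcfR,
    rtracklayer,
    GenomicRanges
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
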