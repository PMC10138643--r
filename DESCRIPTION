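Package: cuticleR
Title: Identification, Classification and Expression Profiling of Insect
    Cuticular Protein Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Annotates insect proteomes for structural cuticular protein (CP)
    families. Detects the CPR family by scoring against extended
    Rebers-Riddiford (R&R) chitin-binding consensus sequences and splits it
    into the RR-1/RR-2/RR-3/RR-NC subfamilies; recognises CPAP1/CPAP3 by
    ChtBD2 cysteine-spacing motifs, Tweedle proteins by their four conserved
    blocks, and the low-complexity families (CPCFC, CPLCP, CPG, CPH, CPF,
    CPFL, 18aa) by diagnostic repeats, composition and homology to a verified
    reference catalog. Downstream stages assign ortholog-based names via
    reciprocal best hits, detect tandem gene arrays on chromosomes, build
    neighbor-joining trees with Poisson-corrected pairwise-deletion distances
    and bootstrap support, compute sequence-logo information matrices, and
    turn FPKM tables into expression bins, family-by-tissue summary tables
    and log10 heat-map matrices. A synthetic-data module generates proteomes,
    gene layouts, reference catalogs, alignments and FPKM tables with known
    ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    ape,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
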