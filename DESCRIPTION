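Package: hifipolish
Title: Repeat-Aware, Haplotype-Preserving Polishing of HiFi Genome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Corrects residual base errors in genome assemblies built from
    PacBio HiFi long reads without introducing overcorrections or haplotype
    switch errors. Implements a K-mer score chain (KSC) consensus over read
    pileups with traceback, detection and merging of low-quality regions,
    short-read-validated K-mer extraction, signed read-graph construction,
    Louvain community detection to separate haplotypes and near-identical
    repeat copies, conflict-community resolution, and residual-region
    rules that fall back to the input assembly to avoid overcorrection.
    Ships evaluation metrics (changed and potential-overcorrection K-mers,
    K-mer and alignment-identity quality values, haplotype switch error)
    and a deterministic diploid/repeat read simulator for desk-scale
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    igraph,
    data.table,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'hifipolish-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'kmer_db.R'
    'alignment_io.R'
    'ksc.R'
    'phasing.R'
    'polish.R'
    'eval.R'
    'simulate.R'
    'cli.R'
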