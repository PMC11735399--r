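Package: tumourEvo
Title: Multi-Region Tumour Evolution: Genome Doubling, Mutation Timing,
    Parallel Copy-Number Evolution and HRD Scar Scores
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing tumour evolution from multi-region
    allele-specific copy-number and mutation data. Calls whole-genome
    doubling (WGD) status from the genome fraction with major-allele copy
    number of at least two, times clonal mutations relative to WGD via
    mutation multiplicity, estimates timing-stratified dN/dS selection with
    exact Poisson confidence intervals, detects mirrored subclonal allelic
    imbalance (MSAI) by phasing heterozygous SNPs across regions with
    permutation empirical P values per cytoband, and computes HRD-related
    genomic scar scores (LST, TAI, HRD-LOH) together with the weighted
    genome instability index (wGII) and permutation confidence bands. A
    multi-region tumour simulator with complete ground truth exercises the
    whole pipeline without controlled-access data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    jsonlite,
    vcfR
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
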