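Package: methdiverge
Title: Differential DNA Methylation Analysis Across Divergent Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for valid whole-genome bisulfite sequencing (WGBS) analysis
    when samples come from highly divergent genotypes, such as distant inbred
    mouse strains or rearranged cancer genomes. Builds personal (pseudo)
    genomes from a reference plus variant calls and exposes liftOver-style
    coordinate maps between genomes; classifies every CpG of one genome by its
    dinucleotide status in another (shared, mutated to TG/CA, otherwise lost,
    or unmappable) and summarises CpG mutation rates genome-wide, in bins and
    across features; reads Bismark methylation counts, lifts all samples into
    a common coordinate system, and applies site filters (shared-only,
    heterozygous removal, variation filtering, coverage masks); smooths
    per-sample methylation with kernel-weighted local polynomial regression so
    genotype-unique CpGs contribute, via imputation, to the detection of
    differentially methylated regions; finds DMRs and large blocks from
    t-statistic tracks and assigns genome-wide family-wise error rates by
    balanced label permutation; and provides quantification-bias diagnostics
    (global and per-category methylation, wrong-reference simulation, the
    unique-shared disparity). A synthetic-data generator produces toy genome
    pairs and count data with planted DMRs so the whole pipeline can be
    exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
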