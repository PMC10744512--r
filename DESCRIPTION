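Package: pgxphase
Title: Star-Allele Diplotyping and Read-Backed Phasing for Complex Pharmacogenes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates diploid samples at three difficult pharmacogene loci
    (a NAT2-like single-exon gene, a UGT1A1-like promoter TA-repeat locus and
    a CYP2D6-like locus with a CYP2D7 paralog) under short-read and long-read
    HiFi sequencing regimes, calls star-allele diplotypes from the simulated
    reads (SNV haplotypes, promoter TA-repeat lengths, gene copy number and
    hybrid structural forms), phases heterozygous variants directly from reads
    by minimum error correction or by frequency-driven statistical joining of
    phase blocks, translates diplotypes into activity scores and metabolizer
    or acetylator phenotypes, and quantifies haplotype, diplotype and
    phenotype concordance between call sets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    BiocGenerics
Config/testthat/edition: 3
biocViews: Software, Genetics, Pharmacogenomics, VariantDetection, Sequencing
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'diplotype.R'
    'catalog.R'
    'scoring.R'
    'concordance.R'
    'simulate.R'
    'io.R'
    'phasing.R'
    'star_calling.R'
    'pipeline.R'
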