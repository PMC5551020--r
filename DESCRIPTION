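Package: gbspoly
Title: Genotyping-by-Sequencing Analytics for Highly Polyploid Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genotyping-by-sequencing (GBS) studies of highly
    polyploid, heterozygous species such as sugarcane and its wild
    relatives. Implements in-silico restriction digestion with fragment
    size selection and genic-overlap annotation; a binomial read-depth
    model giving the minimum sequencing depth needed to detect single-dose
    minor alleles at arbitrary ploidy; subsample-saturation analysis of
    SNP discovery; multi-caller SNP concordance, per-sample depth
    filtering, allele-dosage classification (single-dose, multi-dose,
    multi-allelic), heterozygosity and transition/transversion summaries;
    and presence/absence (PAV) and copy-number (CNV) variation calling
    from normalized region read counts. A synthetic-data generator
    produces every input with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    stats,
    utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
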