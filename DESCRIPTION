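Package: estmine
Title: EST Mining for Allotetraploid Transcriptomes: Digital Gene
    Expression, Homoeo/Allelic SNP Classification, SSR and Primer Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for marker and expression mining in expressed sequence
    tag (EST) collections from allotetraploid species sequenced as pooled
    cDNA libraries (genotype x developmental stage). Includes a synthetic
    tetraploid transcriptome and 454-style read generator with full ground
    truth; read-length filtering and contig pileups (native table or ACE
    alignments); sub-genome read tagging against two diploid progenitor
    transcript panels by seeded ungapped alignment; digital gene expression
    from read counts with the Stekel-Git-Falciani R statistic and Fisher's
    exact test over a factorial of pairwise comparisons; SNP mining with
    depth and minor-allele-frequency rules and partitioning into homoeo
    versus allelic (inter-genotypic) classes with transition/transversion
    accounting, flank export and VCF output; MISA-style microsatellite
    detection with compound repeats; and allele-specific PCR primer-triplet
    construction with tailed forward primers and a destabilizing mismatch.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    BiocGenerics,
    jsonlite,
    SummarizedExperiment,
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
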