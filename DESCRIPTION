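Package: coreselect
Title: Core Collection Selection and Evaluation from SNP Marker Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and compares core collections (reduced, diversity-preserving
    subsets) from biallelic SNP genotype matrices. Implements the Modified
    Rogers and Cavalli-Sforza-Edwards genetic distances, PAM k-medoids
    clustering on a precomputed distance matrix, stochastic local-search
    selection under five diversity objectives (entry-to-nearest-entry,
    accession-to-nearest-entry, Shannon diversity, expected heterozygosity,
    allele coverage), SNP array probe placement from flanking-sequence
    alignments, a marker QC cascade (missingness, monomorphism, duplicates,
    MAF, heterozygosity, perfect-LD collapse), principal coordinate analysis,
    and a replicated stability and quality evaluation harness with
    selection-frequency ecdfs. Includes a seeded generator of structured
    synthetic genotype data (Balding-Nichols model) so the full pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Rcpp,
    withr,
    yaml,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    ape,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
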