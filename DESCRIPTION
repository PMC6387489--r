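Package: fstgblup
Title: SNP Prioritization by Phenotype-Tail FST for Genomic Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to study how prioritizing SNP markers by Wright's fixation
    index (FST) between phenotype tails affects genomic selection. Includes a
    forward-in-time simulator of structured livestock populations with a
    tunable level of linkage disequilibrium, per-locus Nei FST scoring between
    high and low phenotype tails, construction of VanRaden genomic
    relationship matrices, pedigree additive relationship matrices and
    identity-by-state similarity matrices from arbitrary marker subsets, a
    single-kernel GBLUP mixed model fitted by average-information REML with
    an expectation-maximisation fallback, genotype quality control, PLINK
    text import/export, and an experiment driver that compares FST-based and
    random marker subsets across a ladder of panel densities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
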