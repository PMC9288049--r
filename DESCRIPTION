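Package: apyblup
Title: Genomic Prediction with the Algorithm for Proven and Young
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reference implementation of the Algorithm for Proven and Young
    (APY) family of genomic prediction models. Builds pedigree (A) and genomic
    (G) relationship matrices, the APY decomposition with its structured sparse
    inverse, and assembles and solves the equivalent mixed-model formulations:
    GBLUP and SNP-BLUP, APY-GBLUP (joint and partitioned), APY-SNP-BLUP with
    and without a residual polygenic effect, and the single-step variants for
    populations with non-genotyped animals. Provides marker-effect back-solving
    from core-animal breeding values, indirect predictions for young genotyped
    animals, and their reliabilities, together with a seeded gene-dropping
    simulator for multi-generation pedigrees.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
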