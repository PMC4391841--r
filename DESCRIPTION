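Package: regjoint
Title: Large-Region Joint Association Testing for Quantitative Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection and quantification of joint associations of SNP sets
    over large chromosomal regions with quantitative traits. Implements five
    competing regional association models (additive, pairwise-interaction,
    genotypic, EM-based haplotype probability, and a Haseman-Elston variance
    component with Davies-type quadratic-form testing), a normalized measure
    of non-additivity of haplotype effects with analytic non-central-F power,
    a simulation engine for common- and rare-variant tagging scenarios, a
    sliding-window additive-model scan over PLINK-format genotypes,
    permutation-based estimation of regional variance explained, and
    ROC/odds-ratio enrichment of candidate loci among window results.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    vcfR,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
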