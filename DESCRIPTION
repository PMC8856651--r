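Package: famseg
Title: Family Co-Segregation Analysis, Linkage LOD Scoring, ACMG
    Classification and Downstream Expression Analysis for Dominant
    Mendelian Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for identifying and classifying a causal
    variant in a family segregating a fully penetrant autosomal-dominant
    trait. Provides pedigree handling (PED import, obligate-carrier
    inference, informative-meiosis counting), co-segregation filtering of
    multi-sample variant calls under the dominant model, two-point linkage
    LOD scores, an ACMG/ClinGen evidence-combining engine, a two-group
    negative-binomial exact test for RNA-seq counts with
    Benjamini-Hochberg correction and hypergeometric gene-set enrichment,
    delta-delta-Ct relative quantification for qPCR, and seeded synthetic
    data generators (family genotypes, count matrices, Ct tables) with
    planted truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
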