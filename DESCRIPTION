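Package: rnmkit
Title: Reaction Norm Models for Genome-Wide Gene-Environment Interaction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Whole-genome reaction norm modelling of quantitative traits:
    restricted maximum likelihood (AI-REML) estimation of genetic and
    residual intercept-slope variance components on a genomic relationship
    matrix, likelihood-ratio tests for genotype-by-environment (GxE) and
    residual-by-environment (RxE) interaction, best linear unbiased
    prediction of individual genetic and interaction effects, risk
    trajectory stratification, and SNP-heritability comparison between
    additive and interaction models. Includes genotype and phenotype
    quality control, PLINK and GCTA-format readers and writers, and a
    synthetic data generator with known reaction-norm structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
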