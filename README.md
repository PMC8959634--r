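# rnmkit

Reaction norm models for genome-wide gene–environment interaction in
quantitative traits.

## The problem

Lifestyle exposures (alcohol intake, smoking, physical activity, diet)
modulate metabolic traits such as glucose, HbA1c, BMI or C-reactive
protein — but not identically for everyone. Two kinds of modulation can
be distinguished with genome-wide SNP data:

* **GxE interaction** — the *genetic* effects on the trait change with
  the exposure level;
* **RxE interaction** — the *residual* (non-genetic) effects change with
  the exposure level.

`rnmkit` fits the reaction norm model (RNM) that captures both. Each
individual carries a genetic intercept and a genetic slope on the
standardized covariate c, with covariance structure given by the genomic
relationship matrix (GRM) K, plus a residual intercept and slope:

    y_i = b0 + a0_i + a1_i c_i + e0_i + e1_i c_i

    Cov[(a0, a1)] = [[s2_a0, s_a01], [s_a01, s2_a1]] (x) K
    Var(e0_i + e1_i c_i) = s2_t0 + 2 s_t01 c_i + s2_t1 c_i^2

so the phenotypic covariance is

    V = s2_a0 K + s_a01 (K o (c1' + 1c')) + s2_a1 (K o cc') + D,
    D_ii = s2_t0 + 2 s_t01 c_i + s2_t1 c_i^2

with `o` the elementwise product. `s2_a1` is the genome-wide GxE
variance and `s2_t1` the RxE variance. Four nested models (null /
GxE-only / RxE-only / full) are estimated by AI-REML, and their
restricted likelihoods give five tests, including the *orthogonal* GxE
and RxE tests (full vs RxE-only and full vs GxE-only) that correct each
interaction for its collinearity with the other. BLUPs of the
individual effects drive risk prediction `yhat = a0 + (a1 + t1) c`,
20% trajectory stratification, and the comparison of SNP heritability
`h2 = s2_a0 / (s2_a0 + s2_t0)` between the additive (GREML) and
interaction fits — unmodelled interaction variance is absorbed into the
additive model's residual, so h2 rises when interactions are modelled
("still-missing heritability").

## Worked example

```r
library(rnmkit)

vc  <- variance_components(sigma2_a0 = 0.4, sigma2_a1 = 0.2,
                           sigma2_t0 = 0.3, sigma2_t1 = 0.1)
sim <- simulate_rnm_data(n = 800, m = 600, vc, seed = 11)
K   <- compute_grm(sim$genotypes)
cs  <- standardize_covariate(sim$covariate)

fits <- rnm_nested(sim$y, K, cs)      # null, gxe, rxe, full
fits$full
#> Reaction norm model (full), n = 800
#> REML logL = -319.3388 (7 iterations, converged)
#>           estimate     se
#> sigma2_a0   0.4137 0.0539
#> sigma_a01  -0.0069 0.0395
#> sigma2_a1   0.1853 0.0557
#> sigma2_t0   0.2758 0.0400
#> sigma_t01   0.0044 0.0297
#> sigma2_t1   0.1246 0.0612

interaction_tests(fits$null, fits$gxe, fits$rxe, fits$full)
#>             test      chi2 df            p legitimate available
#> 1        OVERALL 90.432267  4 1.065802e-18       TRUE      TRUE
#> 2      GXE_UNADJ 85.588500  2 2.598325e-19       TRUE      TRUE
#> 3      RXE_UNADJ 75.718872  2 3.612900e-17       TRUE      TRUE
#> 4 GXE_ORTHOGONAL 14.713395  2 6.383029e-04       TRUE      TRUE
#> 5 RXE_ORTHOGONAL  4.843767  2 8.875429e-02       TRUE      TRUE
```

The full fit recovers the planted components (0.4, 0.2, 0.3, 0.1)
within one standard error. The orthogonal GxE test stays strongly
significant after removing the collinearity with RxE (p = 6.4e-04),
while the orthogonal RxE test does not reach the usual thresholds on
this replicate — the unadjusted chi-squared statistics are much larger
than the orthogonal ones, which is the collinearity the orthogonal
comparisons are designed to remove. On the same replicate
`heritability(fits$null)` is 0.392 while `heritability(fits$full)` is
0.600: the additive model absorbs the planted interaction variance
into its residual and deflates the intercept heritability.

`run_pipeline()` chains the whole analysis (SNP QC, GRM, relatedness
pruning, PC outliers, sample splits, per-split fits, five tests with
Fisher meta-analysis, Bonferroni calls, risk trajectories by prospective
case status, heritability comparison) from a single config list and
writes TSV tables plus a log. PLINK bed/bim/fam and GCTA GRM binary
formats are read and written by `read_plink()` / `write_plink()` /
`read_grm()` / `write_grm()`.

## Acceptance script

`scripts/acceptance.R` regenerates a synthetic cohort with planted GxE
and RxE interaction and prospective case status, runs the full pipeline
on it (QC → GRM → two sample splits → four REML fits per split → five
meta-analysed interaction tests → trajectories → heritability), and
writes the acceptance JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
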