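---
title: "Reaction norm models for genome-wide GxE and RxE interaction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reaction norm models for genome-wide GxE and RxE interaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnmkit)
```

## The model

`rnmkit` asks whether the genetic and the residual (non-genetic) effects
on a quantitative trait are modulated by an environmental covariate —
genome-wide gene-by-environment (GxE) and residual-by-environment (RxE)
interaction. Both are modelled as *reaction norms*: each individual's
random effect is a linear function (intercept + slope) of the
standardized covariate $c$,

$$y_i = \beta_0 + \alpha_{0i} + \alpha_{1i} c_i + \tau_{0i} + \tau_{1i} c_i,$$

where the genetic pair $(\alpha_0, \alpha_1)$ has covariance
$\begin{pmatrix} \sigma^2_{\alpha_0} & \sigma_{\alpha_{01}} \\ \sigma_{\alpha_{01}} & \sigma^2_{\alpha_1} \end{pmatrix} \otimes K$
with $K$ the genomic relationship matrix, and the residual pair is
independent across individuals with the analogous $\tau$ block. The
phenotypic covariance is

$$V = \sigma^2_{\alpha_0} K + \sigma_{\alpha_{01}} (K \circ (c\mathbf{1}' + \mathbf{1}c')) + \sigma^2_{\alpha_1} (K \circ cc') + D, \qquad
D_{ii} = \sigma^2_{\tau_0} + 2\sigma_{\tau_{01}} c_i + \sigma^2_{\tau_1} c_i^2.$$

$\sigma^2_{\alpha_1}$ is the genome-wide GxE variance and
$\sigma^2_{\tau_1}$ the RxE variance. Assumptions: the trait is
(transformed to be) Gaussian; the covariate is measured without error
and standardized to mean 0, SD 1 (slopes are per-SD of exposure); all
mean effects of the covariate and confounders have been removed
upstream, so the model targets the *variance* structure across
covariate values; SNP effects are many and small (GRM kernel).

Four nested models are fitted: **null** (intercept variances only, the
usual additive GREML), **GxE-only**, **RxE-only**, and **full**. Each
interaction block contributes two parameters (slope variance and
intercept–slope covariance), so the likelihood-ratio tests have

* OVERALL: full vs null, 4 df;
* GXE_UNADJ / RXE_UNADJ: single-interaction model vs null, 2 df each;
* GXE_ORTHOGONAL: full vs RxE-only, 2 df — the GxE signal *after*
  removing its collinearity with RxE;
* RXE_ORTHOGONAL: full vs GxE-only, 2 df.

Because the GxE and RxE variance terms both grow with $c^2$ (one scaled
by the GRM, one on the diagonal), they are partially collinear: the
unadjusted statistics absorb part of each other's signal, the orthogonal
ones do not. The intercept–slope covariances are included in the
blocks; this is the standard random-regression parameterization, and
the per-test df (2) are reported in every output row so alternative
parameterizations remain comparable.

## Estimation and its numerics

Variance components are estimated by restricted maximum likelihood with
average-information (AI) updates, an EM-flavoured first step, and
step-halving; the restricted log-likelihood is
$-\tfrac12(\log|V| + \log|X'V^{-1}X| + y'Py)$ with an intercept-only
$X$ (no $2\pi$ constant — it cancels in every likelihood ratio).
Estimation is **unconstrained** by default: slope variances may go
slightly negative under a null truth, which keeps the LRT statistics
$\chi^2$-calibrated (a nonnegativity constraint would pile estimates on
the boundary and make the tests conservative). The *legitimacy rule*
is applied downstream instead: a full fit with
$\hat\sigma^2_{\alpha_1} + \hat\sigma^2_{\tau_1} < 0$ is excluded from
any significant set regardless of its p-value. A fully constrained
mode (`constrain = TRUE`, PSD projection of both blocks) is available.

Unconstrained variance-function models have a known degeneracy: if the
implied residual variance $D_{ii}(c)$ is driven toward zero at an
extreme covariate value, the restricted likelihood diverges along a
spurious boundary ridge. The optimizer therefore restricts the
parameter space to fits whose per-individual residual variance stays
above a small floor (`tau_floor`, default 1% of the phenotypic
variance) and whose smallest conditional variance (squared Cholesky
pivot of $V$) stays above half that floor — the second guard catches
the same ridge approached through an indefinite genetic block. Any
realistic fit for an inverse-normal-transformed trait sits far inside
these bounds.

Further numerical choices, all visible in `rnm_control()`:

* convergence requires both a likelihood change below `tol_logl`
  (1e-6) and a *proposed* (not step-halved) AI update below `tol_step`
  (1e-4, relative to the phenotypic variance) — accepting the halved
  step here would declare convergence on boundary-pinned fits;
* when AI and EM steps stall against the feasibility boundary, a
  coordinate pattern search polishes the fit along the boundary; fits
  that still cannot improve are accepted as boundary optima only if the
  likelihood had already stabilized, otherwise flagged
  `converged = FALSE` (a small fraction of null-simulated replicates),
  and the inference layer drops them;
* `rnm_nested()` fits the four models with warm starts — each
  interaction model starts *at* the null optimum (new components exactly
  zero), the full model at the better single-interaction optimum — so
  the likelihood ordering of nested models holds in practice and LRT
  statistics are nonnegative;
* for small-n problems the unconstrained restricted likelihood can be
  multimodal; `rnm(n_starts = k)` adds a deterministic lattice of
  starting values (sign combinations of the slope blocks around three
  heritability splits, including a slightly negative genetic fraction)
  and finishes with an annealed log-barrier Nelder–Mead polish, which
  can track likelihood valleys that run along the feasibility boundary.
  The default (`n_starts = 1`) is the right choice at cohort scale;
* starting values: half the phenotypic variance on each intercept
  variance, 1% on interaction terms; standard errors come from the
  inverse AI matrix at the optimum.

## Phenotype preparation

The pipeline order is fixed: (1) OLS adjustment of the trait for the
interaction covariate itself plus confounders — otherwise mean effects
of the covariate masquerade as variance heterogeneity; (2) removal of
values beyond ±3 SD of the adjusted trait (single pass); (3) rank-based
inverse normal transform, Blom offset 3/8 (the most common convention;
the offset is configurable), ties sharing average ranks. The covariate
is standardized with the sample (n−1) SD on the final analysis sample.
Ordinal exposures (e.g. coded intake frequencies) are standardized like
continuous ones. Provenance of every step is recorded in the returned
object.

## Genotype QC and GRM

Defaults mirror common biobank practice: SNPs are dropped for duplicate
ids, call rate < 95%, minor allele frequency < 1%, and Hardy–Weinberg
equilibrium p < 1e-4 (1-df $\chi^2$ on the three genotype counts — the
large-sample test, appropriate at these sample sizes and directly
checkable against a hand computation). The GRM is
$K = WW'/m$ over column-standardized dosages (centered by $2\hat p$,
scaled by $\sqrt{2\hat p(1-\hat p)}$, missing dosages mean-imputed);
allele frequencies are computed in-sample after QC. Relatedness
pruning removes one random member (seeded) of each pair above 0.05,
greedily from the largest relationship down; PC outliers beyond ±6 SD
on PC1/PC2 of the GRM eigendecomposition are removed after pruning
(whether pruning or PC screening comes first is not fixed by
convention; this package prunes first). At desk scale note that with m
SNPs the GRM off-diagonal noise is ~$1/\sqrt m$, so the cohort-scale
0.05 cutoff flags unrelated pairs when m is small — raise
`relatedness_max` accordingly in toy runs.

## The synthetic generator

`simulate_rnm_data()` draws unlinked biallelic SNPs at uniform MAFs,
per-SNP effect pairs from the genetic block scaled by $1/m$ (so the
total genetic variance equals the stated components regardless of SNP
count, matching the GRM standardization), residual pairs from the
$\tau$ block, optional fixed effects, and prospective case status from
a liability threshold: the standardized generative risk
$g_0 + (g_1 + e_1)c$ scaled to a chosen liability $h^2$ (default 0.5)
plus independent normal noise, thresholded at the empirical
$(1-\text{prevalence})$ quantile. The truth record (per-individual
genetic intercepts/slopes and residual slopes) is kept alongside so
recovery can be tested.

What the generator does **not** emulate: linkage disequilibrium,
imputation dosage uncertainty, genotype–covariate correlation (a
heritable covariate would need a bivariate treatment of the covariate
as a second trait; the generator and fitter deliberately leave this
out, so a green test establishes performance under
exposure-independent genotypes only), population structure beyond what
random genotypes produce, and ascertainment of cases. Defaults used in
the tests — n in the hundreds to low thousands, a few hundred SNPs,
variance components summing to ~1 on the INT scale, prevalence 5–25% —
are desk-scale stand-ins for a cohort with ~290k individuals and ~1.1M
SNPs; at that real scale one would also split samples (the pipeline's
`n_splits`) and meta-analyse.

## Risk trajectories and heritability change

From the full-model BLUPs, the predicted phenotype is
$\hat y_i = \hat\alpha_{0i} + (\hat\alpha_{1i} + \hat\tau_{1i}) c_i$.
Individuals are ranked by estimated interaction effect
($\hat\alpha_1 + \hat\tau_1$, or either alone for the GxE-/RxE-only
variants); the bottom and top 20% and the 20% band centred on the
median form the strata (ties broken by a stable sort on individual id).
Within each stratum × prospective case/control cell an OLS line of
$\hat y$ on $c$ gives intercept and slope; cell summaries are averaged
across analyses and case-minus-control differences are tested by a
paired t-test across analyses *within* each stratum — pairing within
stratum matches reporting one p-value per stratum. For
interpretability, variables whose higher values are favourable (HDL,
physical activity, diet score) are sign-flipped before aggregation so
"higher = higher risk" holds everywhere.

Heritability is reported as
$h^2 = \sigma^2_{\alpha_0}/(\sigma^2_{\alpha_0} + \sigma^2_{\tau_0})$ —
intercept components only, i.e. at the covariate mean, assuming
environmental homogeneity — from both the null (GREML) and the full
(interaction) fit, with the change summarized as
$(h^2_{\text{MRNM}} - h^2_{\text{GREML}})/h^2_{\text{GREML}}$ and a
normal-theory 95% CI across a trait's analyses. A full variance
profile $v(c)$ is available as a diagnostic but never replaces the
headline ratio. With interaction variance present, the additive model
absorbs it into the residual, deflating $h^2$; the tests verify this
still-missing-heritability mechanism in simulation.

## Multiple testing and meta-analysis

A trait × covariate grid applies Bonferroni at
$\alpha/(\text{traits} \times \text{covariates})$ to the meta-analysed
p-value of each test type — the grid-level correction, applied
identically to all five test families (whether the correction should
instead be per family is not decidable from first principles; the
output table carries raw meta p-values and the threshold so either
call can be made). Per-split p-values are combined with Fisher's
method ($-2\sum\log p \sim \chi^2_{2k}$); splits with non-converged
fits are dropped from the combination and counted in
`n_splits_used`. Point estimates are pooled by fixed-effect
inverse-variance weighting. Legitimacy at the grid level uses the
pooled slope-variance estimates.

## Known limitations

* No bivariate (trait + covariate) model: genotype–covariate
  correlation is neither simulated nor corrected for.
* Dense linear algebra: memory and time are $O(n^2)$–$O(n^3)$ per
  split; large cohorts must be split (as the pipeline does).
* Unconstrained estimates near the feasibility floor are reported with
  a `boundary` flag; their AI standard errors are approximate.
* The liability-threshold case generator uses the generative risk
  score, not an external disease model; case/control contrasts in the
  tests validate internal consistency, not clinical calibration.
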