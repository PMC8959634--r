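#' Simulate biallelic SNP genotypes
#'
#' Draws an n x m dosage matrix of unlinked biallelic SNPs.  Each SNP j has
#' a minor allele frequency p_j drawn uniformly from `maf_range` and
#' dosages binomial(2, p_j), the Hardy-Weinberg genotype distribution.
#' There is no linkage disequilibrium and no genotype-covariate
#' correlation; this emulates the pruned, common-variant panel used for
#' GRM construction at desk scale.
#'
#' @param n number of individuals (>= 2).
#' @param m number of SNPs (>= 1).
#' @param maf_range length-2 numeric in (0, 0.5]; a single value may be
#'   given for a fixed frequency.  The degenerate range c(0, 0) is
#'   rejected (it would make every SNP monomorphic).
#' @param seed integer seed; mandatory for reproducibility.
#' @return a `genotype_matrix`: list with `dosages` (n x m integer matrix,
#'   entries 0/1/2 or NA), `sample_ids`, `snp_ids`, and `maf` (the
#'   generating frequencies).
#' @examples
#' g <- simulate_genotypes(100, 50, maf_range = c(0.05, 0.5), seed = 1)
#' range(g$dosages)
#' @export
simulate_genotypes <- function(n, m, maf_range = c(0.01, 0.5), seed) {
  stopifnot(n >= 2, m >= 1)
  if (length(maf_range) == 1L) maf_range <- rep(maf_range, 2L)
  stopifnot(length(maf_range) == 2L, maf_range[1] <= maf_range[2],
            maf_range[2] <= 0.5)
  if (maf_range[2] <= 0)
    stop("degenerate maf_range: frequencies must be in (0, 0.5]")
  if (missing(seed)) stop("'seed' is required")
  set.seed(seed)
  p <- runif(m, maf_range[1], maf_range[2])
  dos <- matrix(rbinom(n * m, 2L, rep(p, each = n)), nrow = n, ncol = m)
  genotype_matrix(dos,
                  sample_ids = sprintf("id%0*d", nchar(n), seq_len(n)),
                  snp_ids = sprintf("snp%0*d", nchar(m), seq_len(m)),
                  maf = p)
}

#' Construct a genotype matrix object
#'
#' @param dosages n x m matrix of allele dosages in \{0, 1, 2, NA\}.
#' @param sample_ids,snp_ids unique identifiers (defaults generated).
#' @param maf optional generating allele frequencies (simulation truth).
#' @return a `genotype_matrix` object.
#' @export
genotype_matrix <- function(dosages, sample_ids = NULL, snp_ids = NULL,
                            maf = NULL) {
  dosages <- as.matrix(dosages)
  ok <- dosages %in% c(0, 1, 2) | is.na(dosages)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  if (is.null(sample_ids))
    sample_ids <- if (!is.null(rownames(dosages))) rownames(dosages)
                  else paste0("id", seq_len(nrow(dosages)))
  if (is.null(snp_ids))
    snp_ids <- if (!is.null(colnames(dosages))) colnames(dosages)
               else paste0("snp", seq_len(ncol(dosages)))
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  stopifnot(length(sample_ids) == nrow(dosages),
            length(snp_ids) == ncol(dosages))
  rownames(dosages) <- sample_ids
  colnames(dosages) <- snp_ids
  structure(list(dosages = dosages, sample_ids = sample_ids,
                 snp_ids = snp_ids, maf = maf),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (%d missing calls)\n",
              nrow(x$dosages), ncol(x$dosages), sum(is.na(x$dosages))))
  invisible(x)
}

#' Simulate an environmental (lifestyle) covariate
#'
#' Continuous covariates are normal; ordinal covariates (mimicking coded
#' exposures such as alcohol intake frequency or smoking status) are
#' drawn from discrete levels mapped to numeric codes.  Downstream models
#' standardize the covariate either way, so ordinal codes are treated
#' exactly like continuous values after centering and scaling.
#'
#' @param n number of individuals.
#' @param dist `"normal"` or `"ordinal"`.
#' @param mean,sd parameters of the normal distribution.
#' @param levels numeric codes of the ordinal levels.
#' @param probs level probabilities (default equiprobable).
#' @param seed integer seed.
#' @return numeric vector of length n.
#' @export
simulate_covariate <- function(n, dist = c("normal", "ordinal"),
                               mean = 0, sd = 1,
                               levels = 0:2, probs = NULL, seed) {
  stopifnot(n >= 1)
  dist <- match.arg(dist)
  if (missing(seed)) stop("'seed' is required")
  set.seed(seed)
  switch(dist,
         normal = rnorm(n, mean, sd),
         ordinal = {
           if (is.null(probs)) probs <- rep(1 / length(levels), length(levels))
           stopifnot(length(probs) == length(levels), all(probs >= 0))
           sample(levels, n, replace = TRUE, prob = probs)
         })
}

#' Simulate a phenotype with reaction norm structure
#'
#' Generates `y_i = sum_j w_ij (a_j + b_j c_i) + X beta + e0_i + e1_i c_i`
#' where `w_ij` are column-standardized dosages, the per-SNP effect pairs
#' `(a_j, b_j)` are jointly normal with covariance block
#' `[[sigma2_a0, sigma_a01], [sigma_a01, sigma2_a1]] / m` (so the total
#' genetic variance is controlled by the components regardless of SNP
#' count, matching the GRM standardization), and the per-individual
#' residual pairs `(e0_i, e1_i)` carry the residual (tau) block.  The
#' genetic slope term is the genome-wide GxE effect; the residual slope is
#' the RxE effect.
#'
#' @param genotypes a `genotype_matrix` (no missing dosages).
#' @param covariate numeric covariate vector, standardized internally for
#'   the interaction terms (sample mean 0, SD 1).
#' @param vc generative truth, a [variance_components()] vector.
#' @param fixed_effects optional named list/vector: coefficients applied
#'   to the standardized covariate (name `"covariate"`) and/or an
#'   intercept (name `"intercept"`).
#' @param seed integer seed.
#' @return list with `y` (phenotype vector) and `truth`, a data frame of
#'   per-individual generative values: genetic intercept `g0`, genetic
#'   slope `g1`, residual intercept `e0`, residual slope `e1`, and the
#'   standardized covariate `c`.
#' @examples
#' g <- simulate_genotypes(200, 100, seed = 1)
#' cv <- simulate_covariate(200, seed = 2)
#' vc <- variance_components(sigma2_a0 = 0.4, sigma2_a1 = 0.2,
#'                           sigma2_t0 = 0.3, sigma2_t1 = 0.1)
#' sim <- simulate_phenotype(g, cv, vc, seed = 3)
#' var(sim$y)
#' @export
simulate_phenotype <- function(genotypes, covariate, vc,
                               fixed_effects = NULL, seed) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  vc <- as_vc(vc)
  variance_components(vc[1], vc[2], vc[3], vc[4], vc[5], vc[6])  # PSD check
  dos <- genotypes$dosages
  n <- nrow(dos); m <- ncol(dos)
  if (length(covariate) != n)
    stop("covariate length does not match the number of individuals")
  if (anyNA(dos)) stop("missing dosages: QC/impute before simulating")
  if (missing(seed)) stop("'seed' is required")
  cs <- if (sd(covariate) > 0) as.numeric(scale(covariate)) else covariate

  W <- standardize_dosages(dos)
  set.seed(seed)
  ab <- rmvnorm2(m, matrix(vc[c(1, 2, 2, 3)] / m, 2))
  ee <- rmvnorm2(n, matrix(vc[c(4, 5, 5, 6)], 2))
  g0 <- as.numeric(W %*% ab[, 1])
  g1 <- as.numeric(W %*% ab[, 2])
  y <- g0 + g1 * cs + ee[, 1] + ee[, 2] * cs
  if (!is.null(fixed_effects)) {
    fe <- unlist(fixed_effects)
    if (!is.null(fe["intercept"]) && !is.na(fe["intercept"]))
      y <- y + fe[["intercept"]]
    if (!is.null(fe["covariate"]) && !is.na(fe["covariate"]))
      y <- y + fe[["covariate"]] * cs
    unknown <- setdiff(names(fe), c("intercept", "covariate"))
    if (length(unknown)) stop("unknown fixed effect: ", unknown[1])
  }
  list(y = as.numeric(y),
       truth = data.frame(id = genotypes$sample_ids, g0 = g0, g1 = g1,
                          e0 = ee[, 1], e1 = ee[, 2], c = cs,
                          stringsAsFactors = FALSE))
}

# bivariate normal draws for a 2x2 covariance (handles singular blocks)
rmvnorm2 <- function(n, S) {
  ev <- eigen(S, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2)
  matrix(rnorm(2 * n), n, 2) %*% t(L)
}

# center by 2*phat, scale by sqrt(2*phat*(1-phat)); mean-impute missing
standardize_dosages <- function(dos) {
  p <- colMeans(dos, na.rm = TRUE) / 2
  if (any(p <= 0 | p >= 1))
    stop("monomorphic SNP: zero variance after standardization; run filter_snps first")
  W <- sweep(dos, 2, 2 * p)
  W[is.na(W)] <- 0  # missing -> imputed at the mean, i.e. 0 after centering
  sweep(W, 2, sqrt(2 * p * (1 - p)), "/")
}

#' Simulate prospective case status under a liability threshold
#'
#' Individual liability is the standardized generative risk (genetic
#' intercept + genetic and residual slopes times the covariate, the
#' quantities later estimated by BLUP) scaled to explain `h2_liability` of
#' the liability variance, plus independent normal noise.  Individuals
#' above the empirical (1 - prevalence) liability quantile are incident
#' cases, so the realized case fraction equals the prevalence up to
#' rounding.
#'
#' @param truth truth record from [simulate_phenotype()].
#' @param prevalence case proportion in (0, 1).
#' @param h2_liability proportion of liability variance explained by the
#'   risk score (default 0.5).
#' @param seed integer seed.
#' @return integer vector of 0/1 status, 1 = incident case.
#' @export
simulate_case_status <- function(truth, prevalence, h2_liability = 0.5, seed) {
  stopifnot(prevalence > 0, prevalence < 1,
            h2_liability >= 0, h2_liability <= 1)
  if (missing(seed)) stop("'seed' is required")
  n <- nrow(truth)
  risk <- truth$g0 + (truth$g1 + truth$e1) * truth$c
  vr <- var(risk)
  scaled <- if (vr > 0) sqrt(h2_liability / vr) * risk else rep(0, n)
  set.seed(seed)
  liab <- scaled + sqrt(max(1 - h2_liability, 0)) * rnorm(n)
  k <- round(n * prevalence)
  status <- integer(n)
  status[order(liab, decreasing = TRUE)[seq_len(k)]] <- 1L
  status
}

#' Simulate a complete reaction norm dataset
#'
#' Convenience bundle: genotypes, covariate, phenotype with truth record,
#' and (optionally) prospective case status, from one seed.  Sub-seeds are
#' derived deterministically so stages stay reproducible yet independent.
#'
#' @param n,m sample and SNP counts.
#' @param vc generative [variance_components()].
#' @param maf_range minor allele frequency range.
#' @param covariate_dist `"normal"` or `"ordinal"`.
#' @param fixed_effects passed to [simulate_phenotype()].
#' @param prevalence if non-`NULL`, also draw case status.
#' @param h2_liability liability variance explained by the risk score.
#' @param seed integer seed (< 2^31 after internal offsets).
#' @return list with `genotypes`, `covariate`, `y`, `truth`, and `status`
#'   (NULL when no prevalence given).
#' @export
simulate_rnm_data <- function(n, m, vc, maf_range = c(0.01, 0.5),
                              covariate_dist = "normal",
                              fixed_effects = NULL, prevalence = NULL,
                              h2_liability = 0.5, seed) {
  if (missing(seed)) stop("'seed' is required")
  s <- as.integer(seed %% 536870909L)  # keep derived seeds well under 2^31
  g <- simulate_genotypes(n, m, maf_range, seed = s)
  cv <- simulate_covariate(n, dist = covariate_dist, seed = s + 1L)
  sim <- simulate_phenotype(g, cv, vc, fixed_effects, seed = s + 2L)
  status <- if (!is.null(prevalence))
    simulate_case_status(sim$truth, prevalence, h2_liability, seed = s + 3L)
  list(genotypes = g, covariate = cv, y = sim$y, truth = sim$truth,
       status = status)
}
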