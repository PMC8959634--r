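#' SNP-level quality control
#'
#' Applies, in order: duplicate-id removal, call-rate, minor allele
#' frequency, and Hardy-Weinberg equilibrium filters.  HWE is a 1-df
#' chi-squared goodness-of-fit test of the three observed genotype counts
#' against Hardy-Weinberg expectations at the sample allele frequency,
#' appropriate for the large-sample regime.
#'
#' @param g a `genotype_matrix`.
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param hwe_p_min minimum HWE p-value (default 1e-4).
#' @param call_rate_min minimum per-SNP call rate (default 0.95).
#' @return list with `genotypes` (surviving SNPs) and `report`, the
#'   per-rule exclusion counts.
#' @examples
#' g <- simulate_genotypes(200, 50, seed = 1)
#' qc <- filter_snps(g)
#' qc$report
#' @export
filter_snps <- function(g, maf_min = 0.01, hwe_p_min = 1e-4,
                        call_rate_min = 0.95) {
  stopifnot(inherits(g, "genotype_matrix"),
            maf_min >= 0, maf_min <= 1, hwe_p_min >= 0, hwe_p_min <= 1,
            call_rate_min >= 0, call_rate_min <= 1)
  dos <- g$dosages
  report <- c(duplicate = 0L, call_rate = 0L, maf = 0L, hwe = 0L)

  dup <- duplicated(g$snp_ids)
  report["duplicate"] <- sum(dup)
  keep <- !dup

  cr <- colMeans(!is.na(dos))
  bad <- keep & cr < call_rate_min
  report["call_rate"] <- sum(bad)
  keep <- keep & !bad

  p <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  bad <- keep & !(maf >= maf_min & maf > 0)
  report["maf"] <- sum(bad)
  keep <- keep & !bad

  hp <- apply(dos[, keep, drop = FALSE], 2, hwe_pvalue)
  bad_h <- hp < hwe_p_min
  report["hwe"] <- sum(bad_h)
  keep[keep] <- !bad_h

  if (!any(keep)) {
    rule <- names(report)[which.max(report)]
    stop("no SNPs survive QC (largest exclusion: ", rule, ")")
  }
  out <- genotype_matrix(dos[, keep, drop = FALSE],
                         sample_ids = g$sample_ids,
                         snp_ids = g$snp_ids[keep],
                         maf = g$maf[keep])
  list(genotypes = out, report = report)
}

# 1-df chi-squared goodness of fit of genotype counts to HWE proportions
hwe_pvalue <- function(dosage) {
  dosage <- dosage[!is.na(dosage)]
  n <- length(dosage)
  if (n == 0) return(1)
  obs <- c(sum(dosage == 0), sum(dosage == 1), sum(dosage == 2))
  p <- (2 * obs[3] + obs[2]) / (2 * n)
  q <- 1 - p
  exp <- n * c(q^2, 2 * p * q, p^2)
  if (any(exp == 0)) return(1)  # monomorphic: HWE undefined, caught by MAF
  chi2 <- sum((obs - exp)^2 / exp)
  pchisq(chi2, df = 1, lower.tail = FALSE)
}

#' Compute the genomic relationship matrix
#'
#' K = W W' / m, with W the column-standardized dosage matrix: each SNP
#' centered by twice its sample allele frequency and scaled by
#' sqrt(2 p (1 - p)).  Missing dosages are mean-imputed (zero after
#' centering) before standardization.  K is the covariance kernel of the
#' genetic intercept and slope effects in the reaction norm model.
#'
#' @param g a `genotype_matrix`; monomorphic SNPs must have been removed.
#' @return a `grm` object: list with `K` (n x n symmetric), `sample_ids`,
#'   `n_snps`.
#' @examples
#' g <- genotype_matrix(matrix(c(0, 2), 2, 1))
#' compute_grm(g)$K   # [[2, -2], [-2, 2]]
#' @export
compute_grm <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  W <- standardize_dosages(g$dosages)
  K <- tcrossprod(W) / ncol(W)
  grm(K, g$sample_ids, n_snps = ncol(W))
}

#' Construct a GRM object
#' @param K n x n symmetric relationship matrix.
#' @param sample_ids sample identifiers.
#' @param n_snps number of SNPs used.
#' @return a `grm` object.
#' @export
grm <- function(K, sample_ids = NULL, n_snps = NA_integer_) {
  K <- as.matrix(K)
  stopifnot(nrow(K) == ncol(K))
  if (max(abs(K - t(K))) > 1e-8) stop("K is not symmetric")
  K <- (K + t(K)) / 2
  if (is.null(sample_ids))
    sample_ids <- if (!is.null(rownames(K))) rownames(K)
                  else paste0("id", seq_len(nrow(K)))
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  dimnames(K) <- list(sample_ids, sample_ids)
  structure(list(K = K, sample_ids = sample_ids, n_snps = n_snps),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d samples, %s SNPs, mean diagonal %.3f\n",
              nrow(x$K), format(x$n_snps), mean(diag(x$K))))
  invisible(x)
}

#' Prune related individuals
#'
#' Greedily scans off-diagonal relationships above `threshold` in
#' descending order; from each flagged pair one member is removed at
#' random (seeded), iterating until no remaining pair exceeds the
#' threshold.
#'
#' @param k a `grm`.
#' @param threshold relatedness cutoff (default 0.05).
#' @param seed integer seed for the random within-pair choice.
#' @return character vector of kept sample ids.
#' @export
prune_related <- function(k, threshold = 0.05, seed = 1L) {
  stopifnot(inherits(k, "grm"))
  K <- k$K
  set.seed(seed)
  keep <- rep(TRUE, nrow(K))
  repeat {
    Ksub <- K
    Ksub[!keep, ] <- -Inf; Ksub[, !keep] <- -Inf
    diag(Ksub) <- -Inf
    mx <- max(Ksub)
    if (mx <= threshold) break
    ij <- which(Ksub == mx, arr.ind = TRUE)[1, ]
    drop <- ij[[sample.int(2L, 1L)]]
    keep[drop] <- FALSE
  }
  k$sample_ids[keep]
}

#' Remove principal-component population outliers
#'
#' Principal components are taken from the eigendecomposition of the GRM;
#' samples farther than `n_sd` standard deviations from the mean on PC1
#' or PC2 are removed (single pass).
#'
#' @param k a `grm` with at least 3 samples.
#' @param n_sd outlier cutoff in SD units (default 6).
#' @return character vector of kept sample ids.
#' @export
pc_outlier_removal <- function(k, n_sd = 6) {
  stopifnot(inherits(k, "grm"))
  n <- nrow(k$K)
  if (n < 3) stop("need at least 3 samples for PC outlier screening")
  ev <- eigen(k$K, symmetric = TRUE)
  pcs <- ev$vectors[, 1:2, drop = FALSE] %*%
    diag(sqrt(pmax(ev$values[1:2], 0)), 2)
  out <- rep(FALSE, n)
  for (j in 1:2) {
    z <- (pcs[, j] - mean(pcs[, j]))
    s <- sd(pcs[, j])
    if (s > 0) out <- out | abs(z) > n_sd * s
  }
  k$sample_ids[!out]
}

#' Split samples into near-equal groups
#'
#' Random, seed-deterministic partition into `n_groups` disjoint and
#' exhaustive groups whose sizes differ by at most one, mirroring the
#' division of a large cohort into computationally tractable subsets.
#'
#' @param sample_ids ids to split.
#' @param n_groups number of groups (1 <= n_groups <= n).
#' @param seed integer seed.
#' @return integer vector of group labels (1..n_groups) named by id.
#' @export
split_samples <- function(sample_ids, n_groups, seed = 1L) {
  n <- length(sample_ids)
  stopifnot(n_groups >= 1)
  if (n_groups > n) stop("more groups than samples")
  set.seed(seed)
  lab <- sample(rep_len(seq_len(n_groups), n))
  names(lab) <- sample_ids
  lab
}
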