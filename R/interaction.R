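#' Likelihood-ratio test between nested reaction norm models
#'
#' chi2 = max(0, 2 (logL_full - logL_reduced)), df = difference in free
#' parameter counts, p from the upper chi-squared tail.  A materially
#' negative statistic (logL inversion beyond numerical noise) indicates a
#' convergence failure and is rejected.
#'
#' @param fit_full,fit_reduced converged `rnm` fits on the same data,
#'   with the reduced model nested in the full one.
#' @return list with `chi2`, `df`, `p`.
#' @examples
#' # ΔlogL = 2 on 2 df: chi2 = 4, p = exp(-2)
#' pchisq(4, 2, lower.tail = FALSE)
#' @export
lrt <- function(fit_full, fit_reduced) {
  stopifnot(inherits(fit_full, "rnm"), inherits(fit_reduced, "rnm"))
  if (!fit_full$converged || !fit_reduced$converged)
    stop("both fits must have converged")
  if (!all(fit_reduced$free %in% fit_full$free))
    stop("models are not nested")
  df <- length(fit_full$free) - length(fit_reduced$free)
  if (df < 1) stop("models are not nested (no extra free parameters)")
  stat <- 2 * (fit_full$logLik - fit_reduced$logLik)
  if (stat < -1e-4)
    stop("negative likelihood-ratio statistic (", format(stat),
         "): convergence failure")
  chi2 <- max(0, stat)
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE))
}

#' The five interaction tests from the four nested model fits
#'
#' Given fits of the null, GxE-only, RxE-only and full models on the same
#' data, produces: OVERALL (full vs null, both interactions jointly);
#' GXE_UNADJ (GxE-only vs null) and RXE_UNADJ (RxE-only vs null), each
#' uncorrected for collinearity with the other component; and the
#' orthogonal tests GXE_ORTHOGONAL (full vs RxE-only) and RXE_ORTHOGONAL
#' (full vs GxE-only), in which each interaction is tested on top of the
#' other and is therefore corrected for their collinearity.  The
#' legitimacy flag (nonnegative summed slope variances of the full fit)
#' accompanies every row.
#'
#' @param fit_null,fit_gxe,fit_rxe,fit_full `rnm` fits of the four specs
#'   on identical data.
#' @return data frame with one row per test: `test`, `chi2`, `df`, `p`,
#'   `legitimate`, `available` (FALSE when a needed fit did not
#'   converge).
#' @export
interaction_tests <- function(fit_null, fit_gxe, fit_rxe, fit_full) {
  fits <- list(null = fit_null, gxe = fit_gxe, rxe = fit_rxe, full = fit_full)
  stopifnot(vapply(fits, inherits, TRUE, "rnm"),
            vapply(fits, function(f) f$n, 0) == fits$null$n)
  models <- vapply(fits, `[[`, "", "model")
  if (!identical(unname(models), c("null", "gxe", "rxe", "full")))
    stop("fits must be the null, gxe, rxe and full models, in that order")
  ok <- vapply(fits, `[[`, TRUE, "converged")
  legit <- if (ok[["full"]]) legitimacy_check(fit_full) else NA

  pairs <- list(OVERALL        = c("full", "null"),
                GXE_UNADJ      = c("gxe",  "null"),
                RXE_UNADJ      = c("rxe",  "null"),
                GXE_ORTHOGONAL = c("full", "rxe"),
                RXE_ORTHOGONAL = c("full", "gxe"))
  rows <- lapply(names(pairs), function(nm) {
    pr <- pairs[[nm]]
    if (ok[[pr[1]]] && ok[[pr[2]]]) {
      r <- lrt(fits[[pr[1]]], fits[[pr[2]]])
      data.frame(test = nm, chi2 = r$chi2, df = r$df, p = r$p,
                 legitimate = legit, available = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(test = nm, chi2 = NA_real_, df = NA_integer_, p = NA_real_,
                 legitimate = legit, available = FALSE,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Legitimacy of an interaction fit
#'
#' A full-model fit is inside the legitimate parameter space when the sum
#' of the estimated GxE and RxE slope variances is nonnegative
#' (boundary inclusive).  Unconstrained REML can push individual slope
#' variances slightly negative; a fit failing this rule is excluded from
#' the significant set regardless of its p-value.
#'
#' @param fit_full an `rnm` fit of the full model (or any fit carrying
#'   both slope variances).
#' @return logical flag.
#' @export
legitimacy_check <- function(fit_full) {
  vc <- if (inherits(fit_full, "rnm")) fit_full$vc else as_vc(fit_full)
  unname(vc[["sigma2_a1"]] + vc[["sigma2_t1"]] >= 0)
}

#' Fisher's method for combining p-values
#'
#' X = -2 sum(log p_i) referred to chi-squared with 2k degrees of
#' freedom.  Zero p-values are clipped to the smallest positive
#' representable double with a warning.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return combined p-value.
#' @examples
#' fisher_meta(c(0.5, 0.5))  # 0.5966
#' @export
fisher_meta <- function(p) {
  stopifnot(length(p) >= 1, all(p >= 0), all(p <= 1))
  if (any(p == 0)) {
    warning("p-value of 0 clipped to .Machine$double.xmin")
    p[p == 0] <- .Machine$double.xmin
  }
  X <- -2 * sum(log(p))
  pchisq(X, df = 2 * length(p), lower.tail = FALSE)
}

#' Fixed-effect inverse-variance meta-analysis of estimates
#'
#' pooled = sum(e_i / se_i^2) / sum(1 / se_i^2);
#' pooled se = sqrt(1 / sum(1 / se_i^2)).
#'
#' @param estimates numeric vector of per-group estimates.
#' @param ses matching standard errors (> 0).
#' @return list with `estimate` and `se`.
#' @export
meta_estimates <- function(estimates, ses) {
  stopifnot(length(estimates) == length(ses), all(ses > 0))
  w <- 1 / ses^2
  list(estimate = sum(w * estimates) / sum(w), se = sqrt(1 / sum(w)))
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate in (0, 1).
#' @param n_tests number of tests (>= 1).
#' @return per-test threshold alpha / n_tests.
#' @examples
#' bonferroni_threshold(0.05, 96)  # 5.21e-04
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  alpha / n_tests
}

#' Interaction testing over a trait-by-covariate grid
#'
#' For every trait x covariate cell: the trait is adjusted for the cell's
#' covariate (plus any shared adjustment columns), prepared
#' (outlier removal + inverse normal transform), the four nested models
#' are fitted within each sample split, the five tests are computed per
#' split, per-test p-values are combined across splits by Fisher's
#' method, pooled slope-variance estimates decide legitimacy, and
#' significance is called at the Bonferroni threshold
#' alpha / (n_traits * n_covariates) on the meta-analyzed p-value.
#'
#' @param traits named list (or data frame) of trait vectors.
#' @param covariates named list (or data frame) of covariate vectors.
#' @param K a `grm` covering all samples.
#' @param splits integer group labels from [split_samples()] (default:
#'   one group).
#' @param adjust data frame of shared adjustment columns (optional).
#' @param alpha family-wise error rate (default 0.05).
#' @param control passed to [rnm()].
#' @return data frame with one row per cell per test: trait, covariate,
#'   test, per-split combined `meta_p` (equal to the single-split p when
#'   only one split), pooled slope variances, `legitimate`,
#'   `significant`, and the Bonferroni `threshold`.
#' @export
interaction_grid <- function(traits, covariates, K, splits = NULL,
                             adjust = NULL, alpha = 0.05,
                             control = rnm_control()) {
  traits <- as.data.frame(traits)
  covariates <- as.data.frame(covariates)
  stopifnot(inherits(K, "grm"))
  n <- nrow(K$K)
  stopifnot(nrow(traits) == n, nrow(covariates) == n)
  if (is.null(splits)) splits <- setNames(rep(1L, n), K$sample_ids)
  n_cells <- ncol(traits) * ncol(covariates)
  thr <- bonferroni_threshold(alpha, n_cells)

  out <- list()
  for (tr in names(traits)) for (cv in names(covariates)) {
    cell <- tryCatch(
      grid_cell(traits[[tr]], covariates[[cv]], K, splits, adjust, control),
      error = function(e) {
        warning(sprintf("cell %s x %s failed: %s", tr, cv, conditionMessage(e)))
        NULL
      })
    if (is.null(cell)) {
      cell <- data.frame(test = c("OVERALL", "GXE_UNADJ", "RXE_UNADJ",
                                  "GXE_ORTHOGONAL", "RXE_ORTHOGONAL"),
                         meta_p = NA_real_, df = NA_integer_,
                         sigma2_a1 = NA_real_, sigma2_t1 = NA_real_,
                         legitimate = NA, n_splits_used = 0L,
                         stringsAsFactors = FALSE)
    }
    cell$trait <- tr
    cell$covariate <- cv
    out[[paste(tr, cv)]] <- cell
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  res$threshold <- thr
  res$significant <- !is.na(res$meta_p) & res$meta_p < thr &
    !is.na(res$legitimate) & res$legitimate
  res[, c("trait", "covariate", "test", "meta_p", "df", "sigma2_a1",
          "sigma2_t1", "legitimate", "n_splits_used", "threshold",
          "significant")]
}

# one trait x covariate cell: per-split fits + five tests + Fisher meta
grid_cell <- function(y, cov_raw, K, splits, adjust, control,
                      keep_fits = FALSE) {
  adj_cols <- data.frame(covariate = cov_raw)
  if (!is.null(adjust)) adj_cols <- cbind(adj_cols, adjust)
  split_p <- list()
  details <- list()
  a1s <- a1ses <- t1s <- t1ses <- numeric(0)
  for (g in sort(unique(splits))) {
    sel <- which(splits == g)
    prep <- prepare_phenotype(y[sel], adj_cols[sel, , drop = FALSE])
    idx <- sel[prep$index]
    Ksub <- grm(K$K[idx, idx, drop = FALSE], K$sample_ids[idx], K$n_snps)
    cs <- standardize_covariate(cov_raw[idx])
    fits <- rnm_nested(prep$values, Ksub, cs, control = control)
    if (!all(vapply(fits, `[[`, TRUE, "converged"))) next
    tst <- interaction_tests(fits$null, fits$gxe, fits$rxe, fits$full)
    split_p[[as.character(g)]] <- tst
    if (keep_fits)
      details[[as.character(g)]] <- list(fits = fits, idx = idx, c_std = cs)
    full <- fits$full
    a1s <- c(a1s, full$vc[["sigma2_a1"]]); a1ses <- c(a1ses, full$se[["sigma2_a1"]])
    t1s <- c(t1s, full$vc[["sigma2_t1"]]); t1ses <- c(t1ses, full$se[["sigma2_t1"]])
  }
  if (!length(split_p)) stop("no split converged")
  tests <- split_p[[1]]$test
  meta_p <- vapply(tests, function(tt) {
    ps <- vapply(split_p, function(s) s$p[s$test == tt], 0)
    fisher_meta(ps)
  }, 0)
  a1_pool <- meta_estimates(a1s, pmax(a1ses, 1e-12))
  t1_pool <- meta_estimates(t1s, pmax(t1ses, 1e-12))
  tab <- data.frame(test = tests, meta_p = unname(meta_p),
                    df = split_p[[1]]$df,
                    sigma2_a1 = a1_pool$estimate, sigma2_t1 = t1_pool$estimate,
                    legitimate = a1_pool$estimate + t1_pool$estimate >= 0,
                    n_splits_used = length(split_p),
                    stringsAsFactors = FALSE)
  if (keep_fits) attr(tab, "details") <- details
  tab
}
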