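#' Adjust a phenotype for fixed-effect covariates
#'
#' Ordinary least squares residuals of the trait on the named adjustment
#' columns (always including an intercept).  The interaction covariate
#' itself must be among the adjustment columns when preparing a trait for
#' an interaction analysis, so that mean effects of the covariate cannot
#' masquerade as variance heterogeneity.  Rows with missing design values
#' are dropped and recorded.  Collinear columns are dropped with a
#' warning (pivoted QR).
#'
#' @param y numeric trait vector.
#' @param covariates data frame of candidate adjustment columns.
#' @param adjust_for character vector of column names to adjust for
#'   (default: all columns of `covariates`).
#' @return an `adjusted_phenotype`: list with `values` (residuals),
#'   `index` (row indices kept), and `provenance`.
#' @examples
#' d <- data.frame(sex = rep(0:1, 50))
#' y <- 2 * d$sex + rnorm(100)
#' a <- adjust_phenotype(y, d)
#' abs(cor(a$values, d$sex[a$index]))   # ~ 0
#' @export
adjust_phenotype <- function(y, covariates, adjust_for = names(covariates)) {
  covariates <- as.data.frame(covariates)
  stopifnot(length(y) == nrow(covariates))
  missing_cols <- setdiff(adjust_for, names(covariates))
  if (length(missing_cols))
    stop("adjustment column not found: ", paste(missing_cols, collapse = ", "))
  X <- cbind(`(Intercept)` = 1,
             as.matrix(covariates[, adjust_for, drop = FALSE]))
  ok <- !is.na(y) & complete.cases(X)
  Xo <- X[ok, , drop = FALSE]
  qrX <- qr(Xo)
  if (qrX$rank < ncol(Xo)) {
    dropped <- colnames(Xo)[qrX$pivot[(qrX$rank + 1):ncol(Xo)]]
    warning("dropping collinear adjustment column(s): ",
            paste(dropped, collapse = ", "))
  }
  res <- qr.resid(qrX, y[ok])
  structure(list(values = as.numeric(res), index = which(ok),
                 provenance = list(list(step = "adjust",
                                        columns = adjust_for,
                                        n_dropped = sum(!ok)))),
            class = "adjusted_phenotype")
}

#' Remove phenotype outliers
#'
#' Excludes values more than `k_sd` standard deviations from the mean in
#' either direction.  Mean and SD are computed once on the input; the
#' rule is not iterated.  With zero SD nothing is removed.
#'
#' @param values numeric vector.
#' @param k_sd cutoff in SD units (default 3).
#' @return list with `values` (kept), `kept` (logical mask on the input).
#' @export
remove_outliers <- function(values, k_sd = 3) {
  stopifnot(k_sd >= 0)
  m <- mean(values); s <- sd(values)
  kept <- if (is.na(s) || s == 0) rep(TRUE, length(values))
          else abs(values - m) <= k_sd * s
  list(values = values[kept], kept = kept)
}

#' Rank-based inverse normal transformation
#'
#' Maps the value of rank r among n to `qnorm((r - offset)/(n - 2*offset + 1))`
#' with the Blom offset 3/8 by default, i.e. `(r - 3/8)/(n + 1/4)`.  Ties
#' share the average rank; the transform is monotone, so any monotone
#' re-expression of the input yields the same output.
#'
#' @param values numeric vector, length >= 2.
#' @param offset rank offset (default 3/8, Blom).
#' @return transformed numeric vector.
#' @examples
#' inverse_normal_transform(c(3.2, -1, 7))  # 0, -0.8694, 0.8694
#' @export
inverse_normal_transform <- function(values, offset = 3 / 8) {
  n <- length(values)
  if (n < 2) stop("need at least 2 values")
  r <- rank(values, ties.method = "average")
  qnorm((r - offset) / (n - 2 * offset + 1))
}

#' Standardize a covariate
#'
#' Centers and scales to sample mean 0 and SD 1 (n - 1 denominator), the
#' scale on which reaction norm slopes are defined.
#'
#' @param values numeric vector with positive SD.
#' @return numeric vector, mean 0 and SD 1.
#' @export
standardize_covariate <- function(values) {
  s <- sd(values)
  if (is.na(s) || s == 0) stop("constant covariate cannot be standardized")
  (values - mean(values)) / s
}

#' Full phenotype preparation pipeline
#'
#' Applies, in the fixed order required to avoid spurious interaction
#' signals: fixed-effect adjustment, +/- `k_sd` SD outlier removal, and
#' rank-based inverse normal transformation.  The provenance list records
#' each step and its parameters.
#'
#' @inheritParams adjust_phenotype
#' @inheritParams remove_outliers
#' @param int_offset offset for [inverse_normal_transform()].
#' @return an `adjusted_phenotype` with INT-scale `values`, `index` (rows
#'   of the original data retained), and full `provenance`.
#' @export
prepare_phenotype <- function(y, covariates, adjust_for = names(covariates),
                              k_sd = 3, int_offset = 3 / 8) {
  a <- adjust_phenotype(y, covariates, adjust_for)
  o <- remove_outliers(a$values, k_sd)
  v <- inverse_normal_transform(o$values, int_offset)
  structure(list(values = v, index = a$index[o$kept],
                 provenance = c(a$provenance,
                                list(list(step = "remove_outliers", k_sd = k_sd,
                                          n_removed = sum(!o$kept)),
                                     list(step = "inverse_normal_transform",
                                          offset = int_offset)))),
            class = "adjusted_phenotype")
}

#' @export
print.adjusted_phenotype <- function(x, ...) {
  steps <- vapply(x$provenance, `[[`, "", "step")
  cat(sprintf("adjusted_phenotype: %d values; steps: %s\n",
              length(x$values), paste(steps, collapse = " -> ")))
  invisible(x)
}
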