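#' Reaction norm variance components
#'
#' Constructs and validates the six (co)variance parameters of the full
#' reaction norm model: the genetic intercept variance `sigma2_a0`, the
#' genetic intercept-slope covariance `sigma_a01`, the genetic slope (GxE)
#' variance `sigma2_a1`, and the residual counterparts `sigma2_t0`,
#' `sigma_t01`, `sigma2_t1` (the RxE variance).
#'
#' Each intercept-slope pair forms a 2x2 covariance block
#' `[[s2_0, s_01], [s_01, s2_1]]`.  For a generative truth
#' (e.g. [simulate_phenotype()]) both blocks must be positive
#' semidefinite; REML estimates, which are unconstrained by default, may
#' violate this and are stored without the check.
#'
#' @param sigma2_a0,sigma_a01,sigma2_a1 genetic intercept variance,
#'   intercept-slope covariance, and slope (GxE) variance.
#' @param sigma2_t0,sigma_t01,sigma2_t1 residual intercept variance,
#'   intercept-slope covariance, and slope (RxE) variance.
#' @param check if `TRUE`, require nonnegative variances and positive
#'   semidefinite blocks.
#' @return a named numeric vector of length 6 with class `"variance_components"`.
#' @examples
#' variance_components(sigma2_a0 = 0.4, sigma2_a1 = 0.2,
#'                     sigma2_t0 = 0.3, sigma2_t1 = 0.1)
#' @export
variance_components <- function(sigma2_a0 = 0, sigma_a01 = 0, sigma2_a1 = 0,
                                sigma2_t0 = 0, sigma_t01 = 0, sigma2_t1 = 0,
                                check = TRUE) {
  vc <- c(sigma2_a0 = sigma2_a0, sigma_a01 = sigma_a01, sigma2_a1 = sigma2_a1,
          sigma2_t0 = sigma2_t0, sigma_t01 = sigma_t01, sigma2_t1 = sigma2_t1)
  stopifnot(is.numeric(vc), length(vc) == 6L, all(is.finite(vc)))
  if (check) {
    if (any(vc[c(1L, 3L, 4L, 6L)] < 0))
      stop("variances must be nonnegative")
    if (sigma_a01^2 > sigma2_a0 * sigma2_a1 + 1e-12)
      stop("genetic intercept-slope block is not positive semidefinite")
    if (sigma_t01^2 > sigma2_t0 * sigma2_t1 + 1e-12)
      stop("residual intercept-slope block is not positive semidefinite")
  }
  class(vc) <- "variance_components"
  vc
}

vc_names <- c("sigma2_a0", "sigma_a01", "sigma2_a1",
              "sigma2_t0", "sigma_t01", "sigma2_t1")

as_vc <- function(x) {
  if (inherits(x, "variance_components")) return(x)
  stopifnot(is.numeric(x))
  if (!is.null(names(x)) && all(vc_names %in% names(x))) {
    x <- x[vc_names]
  } else if (length(x) == 6L) {
    names(x) <- vc_names
  } else stop("cannot interpret 'vc': need the 6 named reaction norm components")
  class(x) <- "variance_components"
  x
}

#' @export
print.variance_components <- function(x, digits = 4, ...) {
  cat("Reaction norm variance components:\n")
  m <- matrix(unclass(x), nrow = 2, byrow = TRUE,
              dimnames = list(c("genetic (alpha)", "residual (tau)"),
                              c("var(intercept)", "cov(int,slope)", "var(slope)")))
  print(round(m, digits), ...)
  invisible(x)
}
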