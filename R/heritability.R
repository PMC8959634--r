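#' SNP heritability from intercept variance components
#'
#' `h2 = s2_a0 / (s2_a0 + s2_t0)`: the genetic intercept variance as a
#' proportion of intercept (environment-at-the-mean) variance.  Slope
#' components are deliberately excluded — the definition assumes
#' environmental homogeneity of the sample, so the additive and the
#' interaction model are compared on the same scale.
#'
#' @param x an `rnm` fit or a [variance_components()] vector.
#' @return heritability in \[0, 1\] for legitimate estimates (returned raw
#'   otherwise).
#' @examples
#' heritability(variance_components(sigma2_a0 = 0.5, sigma2_t0 = 0.5))
#' @export
heritability <- function(x) {
  vc <- if (inherits(x, "rnm")) x$vc else as_vc(x)
  denom <- vc[["sigma2_a0"]] + vc[["sigma2_t0"]]
  if (denom <= 0) stop("zero intercept variance: heritability undefined")
  unname(vc[["sigma2_a0"]] / denom)
}

#' Compare heritability between the additive and interaction fits
#'
#' The additive (null/GREML) model absorbs any real interaction variance
#' into the residual, deflating heritability ("still-missing"
#' heritability); the full reaction norm fit frees the slope components,
#' so its intercept heritability is expected to be larger on data with
#' genuine interactions.  The change is summarized as the ratio
#' `(h2_mrnm - h2_greml) / h2_greml`.
#'
#' @param null_fit `rnm` fit of the null model.
#' @param full_fit `rnm` fit of the full (interaction) model on the same
#'   data.
#' @param trait optional trait label.
#' @return data frame (one row) with `trait`, `h2_greml`, `h2_mrnm`,
#'   `ratio_change`, and `legitimate` (the full fit's nonnegativity
#'   flag).
#' @export
compare_heritability <- function(null_fit, full_fit, trait = NA_character_) {
  stopifnot(inherits(null_fit, "rnm"), inherits(full_fit, "rnm"),
            null_fit$model == "null", full_fit$model == "full",
            null_fit$n == full_fit$n)
  if (!null_fit$converged || !full_fit$converged)
    stop("both fits must have converged")
  h2g <- heritability(null_fit)
  h2m <- heritability(full_fit)
  data.frame(trait = trait, h2_greml = h2g, h2_mrnm = h2m,
             ratio_change = (h2m - h2g) / h2g,
             legitimate = legitimacy_check(full_fit),
             stringsAsFactors = FALSE)
}

#' Mean heritability-change ratio with 95% confidence interval
#'
#' Averages `ratio_change` over the analyses of each trait and attaches
#' the normal-theory 95% interval (mean +/- 1.96 SE); the `significant`
#' flag marks traits whose interval excludes zero.  Traits with a single
#' analysis get a point estimate without an interval.
#'
#' @param records row-bound [compare_heritability()] outputs with a
#'   `trait` column.
#' @return data frame per trait: `mean_ratio`, `se`, `ci_lower`,
#'   `ci_upper`, `n_analyses`, `significant`.
#' @export
ratio_ci <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("trait", "ratio_change") %in% names(records)))
  out <- lapply(split(records, records$trait), function(d) {
    r <- d$ratio_change
    n <- length(r)
    if (n >= 2) {
      se <- sd(r) / sqrt(n)
      lo <- mean(r) - 1.96 * se; hi <- mean(r) + 1.96 * se
      data.frame(trait = d$trait[1], mean_ratio = mean(r), se = se,
                 ci_lower = lo, ci_upper = hi, n_analyses = n,
                 significant = lo > 0 | hi < 0, stringsAsFactors = FALSE)
    } else {
      data.frame(trait = d$trait[1], mean_ratio = r, se = NA_real_,
                 ci_lower = NA_real_, ci_upper = NA_real_, n_analyses = 1L,
                 significant = NA, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}
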