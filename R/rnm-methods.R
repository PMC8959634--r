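#' @export
print.rnm <- function(x, digits = 4, ...) {
  cat(sprintf("Reaction norm model (%s), n = %d\n", x$model, x$n))
  cat(sprintf("REML logL = %.4f (%d iterations, %sconverged)\n",
              x$logLik, x$n_iter, if (x$converged) "" else "NOT "))
  est <- cbind(estimate = unclass(x$vc), se = x$se)
  print(round(est, digits))
  invisible(x)
}

#' Summarize a fitted reaction norm model
#'
#' @param object an `rnm` fit.
#' @param ... unused.
#' @return a `summary.rnm`: the estimate/SE table restricted to free
#'   parameters, intercept-component heritability, and diagnostics.
#' @export
summary.rnm <- function(object, ...) {
  tab <- cbind(estimate = unclass(object$vc)[object$free],
               se = object$se[object$free])
  structure(list(model = object$model, n = object$n, table = tab,
                 h2 = heritability(object), logLik = object$logLik,
                 beta = object$beta, n_iter = object$n_iter,
                 converged = object$converged),
            class = "summary.rnm")
}

#' @export
print.summary.rnm <- function(x, digits = 4, ...) {
  cat(sprintf("Reaction norm model (%s), n = %d\n", x$model, x$n))
  print(round(x$table, digits))
  cat(sprintf("intercept h2 = %.4f; REML logL = %.4f; intercept = %.4f\n",
              x$h2, x$logLik, x$beta))
  cat(sprintf("%d iterations, %sconverged\n", x$n_iter,
              if (x$converged) "" else "NOT "))
  invisible(x)
}

#' @export
coef.rnm <- function(object, ...) unclass(object$vc)

#' @export
vcov.rnm <- function(object, ...) object$vcov_vc

#' @export
logLik.rnm <- function(object, ...) {
  structure(object$logLik, df = length(object$free), nobs = object$n,
            class = "logLik")
}

#' Predicted phenotype (risk) from a reaction norm fit
#'
#' The expected phenotype of individual i at covariate value c is
#' `yhat_i = a0hat_i + a1hat_i c + t1hat_i c`: the BLUP genetic intercept
#' plus the genetic (GxE) and residual (RxE) slopes times the covariate.
#'
#' @param object an `rnm` fit.
#' @param c_new covariate values at which to predict (default: the
#'   fitted covariate).
#' @param ... unused.
#' @return numeric vector of predicted phenotypes.
#' @export
predict.rnm <- function(object, c_new = object$c_std, ...) {
  stopifnot(length(c_new) == object$n)
  predict_risk(object$blups, c_new)
}

#' @export
fitted.rnm <- function(object, ...) {
  b <- object$blups
  object$beta + b$a0 + b$a1 * object$c_std
}

#' @export
residuals.rnm <- function(object, ...) object$y - fitted(object)

#' Extract BLUPs of the random reaction norm effects
#'
#' @param object an `rnm` fit.
#' @param ... unused.
#' @return data frame with per-individual genetic intercept `a0`, genetic
#'   slope `a1`, residual intercept `e0`, and residual slope `t1`.
#' @export
ranef <- function(object, ...) UseMethod("ranef")

#' @rdname ranef
#' @export
ranef.rnm <- function(object, ...) object$blups

#' Simulate phenotypes from a fitted reaction norm model
#'
#' Draws `y* ~ N(intercept, V(theta_hat))` with V rebuilt from the
#' estimated components; the GRM is needed and is not stored in the fit.
#'
#' @param object an `rnm` fit.
#' @param nsim number of replicate phenotype vectors.
#' @param seed integer seed.
#' @param K the GRM (`grm` object or matrix) used for the fit.
#' @param ... unused.
#' @return n x nsim matrix of simulated phenotypes.
#' @export
simulate.rnm <- function(object, nsim = 1, seed = NULL, K, ...) {
  if (missing(K)) stop("the GRM 'K' must be supplied")
  if (!is.null(seed)) set.seed(seed)
  V <- build_covariance(K, object$c_std, object$vc)
  ch <- chol(V + diag(1e-10, object$n))
  Z <- matrix(rnorm(object$n * nsim), object$n, nsim)
  object$beta + crossprod(ch, Z)
}

#' Plot predicted risk trajectories by interaction stratum
#'
#' Scatter of the Eq.-style predicted phenotype against the covariate,
#' highlighting the bottom, middle and top 20% strata of the estimated
#' interaction effect (a1hat + t1hat), with per-stratum regression lines.
#'
#' @param x an `rnm` fit.
#' @param ... passed to [plot()].
#' @return invisibly, the stratum labels.
#' @export
plot.rnm <- function(x, ...) {
  yhat <- predict(x)
  eff <- x$blups$a1 + x$blups$t1
  groups <- stratify_by_effect(eff, ids = x$blups$id)
  cols <- c(BOTTOM20 = "#4575b4", MIDDLE20 = "grey50", TOP20 = "#d73027")
  col <- ifelse(is.na(groups), "grey85", cols[groups])
  plot(x$c_std, yhat, col = col, pch = 16, cex = 0.5,
       xlab = "standardized covariate", ylab = "predicted phenotype", ...)
  for (gname in names(cols)) {
    sel <- !is.na(groups) & groups == gname
    if (sum(sel) > 2)
      abline(lm(yhat[sel] ~ x$c_std[sel]), col = cols[gname], lwd = 2)
  }
  legend("topleft", legend = names(cols), col = cols, lwd = 2, bty = "n")
  invisible(groups)
}
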