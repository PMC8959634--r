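#' Predicted phenotype from BLUPs
#'
#' `yhat_i = a0hat_i + a1hat_i c_i + t1hat_i c_i`: the estimated additive
#' genetic effect plus the estimated GxE and RxE interaction effects
#' scaled by the standardized covariate.
#'
#' @param blups data frame with columns `a0`, `a1`, `t1` (as produced by
#'   [ranef()] on a full-model fit).
#' @param c_std standardized covariate vector of matching length.
#' @return numeric vector of predicted phenotypes.
#' @export
predict_risk <- function(blups, c_std) {
  stopifnot(all(c("a0", "a1", "t1") %in% names(blups)))
  if (nrow(blups) != length(c_std))
    stop("BLUPs and covariate lengths differ")
  blups$a0 + (blups$a1 + blups$t1) * c_std
}

#' Stratify individuals by estimated interaction effect
#'
#' Labels the lowest `fraction` of individuals BOTTOM20, the highest
#' TOP20, and the `fraction`-sized band centered on the median MIDDLE20;
#' everyone else is unlabeled (NA).  Ties are broken by a stable sort on
#' individual id so the grouping is deterministic.
#'
#' @param effects per-individual interaction effect: `a1 + t1` for the
#'   combined stratification, or `a1` / `t1` alone for the GxE-only and
#'   RxE-only variants.
#' @param fraction group size as a proportion (default 0.2).
#' @param ids individual identifiers used for tie-breaking (default
#'   index order).
#' @return character vector of labels (`"BOTTOM20"`, `"MIDDLE20"`,
#'   `"TOP20"`, or NA), in input order.
#' @export
stratify_by_effect <- function(effects, fraction = 0.2, ids = NULL) {
  n <- length(effects)
  if (n < 5) stop("need at least 5 individuals to form 20% strata")
  stopifnot(fraction > 0, fraction <= 1 / 3)
  if (is.null(ids)) ids <- seq_len(n)
  ord <- order(effects, ids)          # stable: ties resolved by id
  k <- floor(fraction * n)
  lab <- rep(NA_character_, n)
  lab[ord[seq_len(k)]] <- "BOTTOM20"
  lab[ord[seq(n - k + 1, n)]] <- "TOP20"
  mid_start <- floor((n - k) / 2) + 1
  lab[ord[seq(mid_start, mid_start + k - 1)]] <- "MIDDLE20"
  lab
}

#' Orient trait/covariate signs toward a common risk direction
#'
#' For interpretability across analyses, variables whose larger values
#' are *favorable* for metabolic health (HDL cholesterol, physical
#' activity measures, healthy diet score) are negated so that "higher =
#' higher risk" holds for every trait and covariate; all others (glucose,
#' HbA1c, TC, LDL, CRP, sodium, potassium, BMI, WHR, blood pressures,
#' age, alcohol, smoking) are left unchanged.  Applying the orientation
#' twice restores the input.
#'
#' @param name trait or covariate name (matched case-insensitively
#'   against the configured vocabulary).
#' @param values numeric values to orient.
#' @param flip_set names to negate; defaults to the favorable-direction
#'   set.
#' @return oriented values.
#' @export
orient_signs <- function(name, values,
                         flip_set = c("HDL", "PA:summed", "PA:walk",
                                      "PA:moderate", "PA:vigorous",
                                      "physical_activity", "Diet", "diet")) {
  known <- c(flip_set,
             c("glucose", "HbA1c", "TC", "LDL", "CRP", "sodium", "potassium",
               "BMI", "WHR", "systolic", "diastolic", "Age", "ALC", "SMK"))
  if (!tolower(name) %in% tolower(known)) {
    warning("unknown variable '", name, "': values left unchanged")
    return(values)
  }
  if (tolower(name) %in% tolower(flip_set)) -values else values
}

#' Per-group regression lines of predicted phenotype on covariate
#'
#' For each stratum x case/control cell, the OLS intercept and slope of
#' the predicted phenotype on the standardized covariate.
#'
#' @param yhat predicted phenotypes ([predict_risk()]).
#' @param c_std standardized covariate.
#' @param groups stratum labels ([stratify_by_effect()]).
#' @param status 0/1 incident (prospective) case status; the module does
#'   not derive diagnosis from phenotypes.
#' @return data frame with `group`, `status` (`"case"`/`"control"`),
#'   `intercept`, `slope`, `n`; cells with fewer than 2 individuals are
#'   returned with NA coefficients.
#' @export
trajectory_lines <- function(yhat, c_std, groups, status) {
  stopifnot(length(yhat) == length(c_std), length(groups) == length(yhat),
            length(status) == length(yhat), all(status %in% c(0, 1)))
  cells <- expand.grid(group = c("BOTTOM20", "MIDDLE20", "TOP20"),
                       status = c("control", "case"),
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- !is.na(groups) & groups == cells$group[i] &
      status == (cells$status[i] == "case")
    if (sum(sel) >= 2 && sd(c_std[sel]) > 0) {
      fit <- lm.fit(cbind(1, c_std[sel]), yhat[sel])
      data.frame(group = cells$group[i], status = cells$status[i],
                 intercept = fit$coefficients[1], slope = fit$coefficients[2],
                 n = sum(sel), stringsAsFactors = FALSE)
    } else {
      data.frame(group = cells$group[i], status = cells$status[i],
                 intercept = NA_real_, slope = NA_real_, n = sum(sel),
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Aggregate trajectory summaries across analyses
#'
#' Averages per-cell intercepts and slopes over analyses
#' (trait-covariate pairs) and tests the case-minus-control difference
#' within each stratum by a paired t-test across analyses, separately for
#' intercepts and slopes.
#'
#' @param summaries list of [trajectory_lines()] data frames, one per
#'   analysis (>= 2).
#' @return list with `means` (per group x status: mean and SE of
#'   intercept and slope over analyses) and `paired_tests` (per group:
#'   mean paired difference, t, df, two-sided p for intercept and slope;
#'   NA when the paired differences have zero variance).
#' @export
aggregate_trajectories <- function(summaries) {
  stopifnot(length(summaries) >= 2)
  all_s <- do.call(rbind, c(summaries, make.row.names = FALSE))
  all_s$analysis <- rep(seq_along(summaries),
                        vapply(summaries, nrow, 0L))
  agg <- function(v) c(mean = mean(v, na.rm = TRUE),
                       se = sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))))
  means <- do.call(rbind, lapply(split(all_s, all_s[c("status", "group")]),
    function(d) data.frame(group = d$group[1], status = d$status[1],
                           intercept_mean = agg(d$intercept)[1],
                           intercept_se = agg(d$intercept)[2],
                           slope_mean = agg(d$slope)[1],
                           slope_se = agg(d$slope)[2],
                           n_analyses = sum(!is.na(d$intercept)),
                           stringsAsFactors = FALSE)))
  rownames(means) <- NULL

  paired <- lapply(c("BOTTOM20", "MIDDLE20", "TOP20"), function(gname) {
    d <- all_s[all_s$group == gname, ]
    wide <- merge(d[d$status == "case", c("analysis", "intercept", "slope")],
                  d[d$status == "control", c("analysis", "intercept", "slope")],
                  by = "analysis", suffixes = c("_case", "_control"))
    wide <- wide[complete.cases(wide), ]
    test_one <- function(diffs) {
      if (length(diffs) < 2 || sd(diffs) == 0)
        return(c(mean_diff = mean(diffs), t = NA, df = NA, p = NA))
      tt <- t.test(diffs)
      c(mean_diff = unname(tt$estimate), t = unname(tt$statistic),
        df = unname(tt$parameter), p = tt$p.value)
    }
    ti <- test_one(wide$intercept_case - wide$intercept_control)
    ts <- test_one(wide$slope_case - wide$slope_control)
    data.frame(group = gname, n_pairs = nrow(wide),
               intercept_diff = ti[1], intercept_t = ti[2],
               intercept_p = ti[4],
               slope_diff = ts[1], slope_t = ts[2], slope_p = ts[4],
               stringsAsFactors = FALSE)
  })
  paired <- do.call(rbind, c(paired, make.row.names = FALSE))
  list(means = means, paired_tests = paired)
}
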