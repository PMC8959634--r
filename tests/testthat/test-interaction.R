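# minimal stand-in rnm objects for the pure-arithmetic LRT checks
fake_fit <- function(logl, model, converged = TRUE) {
  structure(list(logLik = logl, model = model,
                 free = rnm_free_params(model), converged = converged,
                 n = 100L,
                 vc = structure(setNames(rep(0.1, 6),
                   c("sigma2_a0", "sigma_a01", "sigma2_a1",
                     "sigma2_t0", "sigma_t01", "sigma2_t1")),
                   class = "variance_components")),
            class = "rnm")
}

test_that("LRT follows the chi-squared closed forms", {
  r0 <- lrt(fake_fit(-100, "full"), fake_fit(-100, "null"))
  expect_equal(r0$chi2, 0)
  expect_equal(r0$p, 1)

  r1 <- lrt(fake_fit(-98, "full"), fake_fit(-100, "rxe"))
  expect_equal(r1$chi2, 4)
  expect_equal(r1$df, 2)
  expect_equal(r1$p, exp(-2), tolerance = 1e-12)   # chi2_2 survival e^(-x/2)

  r2 <- lrt(fake_fit(-100 + 1e-9, "full"), fake_fit(-100, "null"))
  expect_gte(r2$chi2, 0)
  expect_equal(r2$p, 1, tolerance = 1e-6)

  expect_error(lrt(fake_fit(-100, "gxe"), fake_fit(-99, "rxe")), "nested")
  expect_error(lrt(fake_fit(-101, "full"), fake_fit(-100, "null")),
               "convergence failure")
  expect_error(lrt(fake_fit(-98, "full", converged = FALSE),
                   fake_fit(-100, "null")), "converged")
})

test_that("five tests map onto the four model comparisons", {
  tst <- interaction_tests(fake_fit(-110, "null"), fake_fit(-106, "gxe"),
                           fake_fit(-104, "rxe"), fake_fit(-100, "full"))
  expect_equal(nrow(tst), 5)
  expect_setequal(tst$test, c("OVERALL", "GXE_UNADJ", "RXE_UNADJ",
                              "GXE_ORTHOGONAL", "RXE_ORTHOGONAL"))
  expect_equal(tst$chi2[tst$test == "OVERALL"], 20)        # full vs null
  expect_equal(tst$df[tst$test == "OVERALL"], 4)
  expect_equal(tst$chi2[tst$test == "GXE_UNADJ"], 8)       # gxe vs null
  expect_equal(tst$chi2[tst$test == "RXE_UNADJ"], 12)      # rxe vs null
  expect_equal(tst$chi2[tst$test == "GXE_ORTHOGONAL"], 8)  # full vs rxe
  expect_equal(tst$chi2[tst$test == "RXE_ORTHOGONAL"], 12) # full vs gxe
  expect_true(all(tst$df[tst$test != "OVERALL"] == 2))

  # a non-converged fit disables only the tests that need it
  tst2 <- interaction_tests(fake_fit(-110, "null"),
                            fake_fit(-106, "gxe", converged = FALSE),
                            fake_fit(-104, "rxe"), fake_fit(-100, "full"))
  expect_false(tst2$available[tst2$test == "GXE_UNADJ"])
  expect_false(tst2$available[tst2$test == "RXE_ORTHOGONAL"])
  expect_true(all(tst2$available[tst2$test %in%
    c("OVERALL", "RXE_UNADJ", "GXE_ORTHOGONAL")]))
})

test_that("legitimacy rule is the boundary-inclusive nonnegative sum", {
  mk <- function(a1, t1) variance_components(
    sigma2_a0 = 0.1, sigma2_a1 = a1, sigma2_t0 = 0.1, sigma2_t1 = t1,
    check = FALSE)
  expect_true(legitimacy_check(mk(0.02, 0.01)))
  expect_false(legitimacy_check(mk(-0.03, 0.01)))
  expect_true(legitimacy_check(mk(-0.01, 0.01)))   # sum exactly 0
})

test_that("Fisher combination matches its closed forms", {
  expect_equal(fisher_meta(1), 1)
  # X = -2 ln(0.25) = 2.7726, df 4: p = e^(-X/2) (1 + X/2)
  expect_equal(round(fisher_meta(c(0.5, 0.5)), 4), 0.5966)
  X <- -2 * log(0.25)
  expect_equal(fisher_meta(c(0.5, 0.5)), exp(-X / 2) * (1 + X / 2),
               tolerance = 1e-12)
  expect_lte(fisher_meta(rep(1e-6, 4)), 1e-6)      # monotone in tiny p
  expect_warning(p0 <- fisher_meta(c(0, 0.5)), "clipped")
  expect_lt(p0, 1e-10)
})

test_that("inverse-variance meta-analysis pools as expected", {
  m1 <- meta_estimates(c(2, 2), c(0.5, 0.5))
  expect_equal(m1$estimate, 2)
  expect_equal(m1$se, 0.5 / sqrt(2))
  expect_equal(meta_estimates(c(1, 3), c(1, 1))$estimate, 2)
  expect_equal(meta_estimates(c(0, 4), c(1, 2))$estimate, 0.8)
  m2 <- meta_estimates(5, 1.5)
  expect_equal(m2$estimate, 5)
  expect_equal(m2$se, 1.5)
})

test_that("Bonferroni threshold reproduces the 96-test correction", {
  expect_equal(signif(bonferroni_threshold(0.05, 96), 3), 5.21e-4)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 10), 0.005)
})

test_that("orthogonal chi2 never exceeds the overall chi2", {
  ff <- fit_four(300, 250,
                 variance_components(sigma2_a0 = 0.4, sigma2_a1 = 0.2,
                                     sigma2_t0 = 0.3, sigma2_t1 = 0.1),
                 seed = 61)
  tst <- interaction_tests(ff$fits$null, ff$fits$gxe, ff$fits$rxe,
                           ff$fits$full)
  ov <- tst$chi2[tst$test == "OVERALL"]
  expect_gte(ov + 1e-6, tst$chi2[tst$test == "GXE_ORTHOGONAL"])
  expect_gte(ov + 1e-6, tst$chi2[tst$test == "RXE_ORTHOGONAL"])
})

test_that("collinear GxE and RxE signals separate only in orthogonal tests", {
  # both slope variances load on the same c^2 channel: the unadjusted GxE
  # test absorbs the RxE signal while the orthogonal test does not
  ff <- fit_four(500, 300,
                 variance_components(sigma2_a0 = 0.3, sigma2_a1 = 0.2,
                                     sigma2_t0 = 0.3, sigma2_t1 = 0.2),
                 seed = 62)
  tst <- interaction_tests(ff$fits$null, ff$fits$gxe, ff$fits$rxe,
                           ff$fits$full)
  expect_gt(tst$chi2[tst$test == "GXE_UNADJ"],
            tst$chi2[tst$test == "GXE_ORTHOGONAL"])
})

test_that("grid testing flags the planted cell and applies Bonferroni", {
  set.seed(63)
  n <- 400
  g <- simulate_genotypes(n, 300, seed = 63)
  K <- compute_grm(g)
  c1 <- simulate_covariate(n, seed = 64)
  c2 <- simulate_covariate(n, seed = 65)
  planted <- simulate_phenotype(g, c1,
    variance_components(sigma2_a0 = 0.25, sigma2_a1 = 0.45,
                        sigma2_t0 = 0.3), seed = 66)
  nullish <- simulate_phenotype(g, c1,
    variance_components(sigma2_a0 = 0.5, sigma2_t0 = 0.5), seed = 67)
  res <- interaction_grid(
    traits = data.frame(planted = planted$y, nullish = nullish$y),
    covariates = data.frame(c1 = c1, c2 = c2), K = K)
  expect_equal(nrow(res), 2 * 2 * 5)
  expect_equal(unique(res$threshold), 0.05 / 4)
  p_gxe <- res[res$test == "GXE_ORTHOGONAL", ]
  planted_p <- p_gxe$meta_p[p_gxe$trait == "planted" & p_gxe$covariate == "c1"]
  other_p <- p_gxe$meta_p[!(p_gxe$trait == "planted" & p_gxe$covariate == "c1")]
  expect_lt(planted_p, 0.05 / 4)
  expect_gt(min(other_p), planted_p)

  # 1x1 grid: the threshold is alpha itself
  res1 <- interaction_grid(traits = data.frame(y = nullish$y),
                           covariates = data.frame(c1 = c1), K = K)
  expect_equal(unique(res1$threshold), 0.05)
})
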