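test_that("simulated genotypes match their generating frequencies", {
  n <- 1000; m <- 200
  g <- simulate_genotypes(n, m, maf_range = c(0.5, 0.5), seed = 101)
  phat <- colMeans(g$dosages) / 2
  se <- sqrt(0.5 * 0.5 / (2 * n))
  expect_gte(mean(abs(phat - 0.5) <= 3 * se), 0.95)

  g2 <- simulate_genotypes(2, 1, maf_range = c(0.01, 0.01), seed = 1)
  expect_true(all(g2$dosages %in% 0:2))

  expect_identical(simulate_genotypes(50, 20, seed = 7)$dosages,
                   simulate_genotypes(50, 20, seed = 7)$dosages)
  expect_error(simulate_genotypes(10, 5, maf_range = c(0, 0), seed = 1),
               "degenerate")
})

test_that("simulated covariates have the requested distribution", {
  x <- simulate_covariate(1e4, seed = 5)
  expect_lt(abs(mean(x)), 0.05)
  expect_true(sd(x) > 0.95 && sd(x) < 1.05)

  n <- 9000
  o <- simulate_covariate(n, dist = "ordinal", levels = 1:3, seed = 6)
  counts <- table(o)
  se <- sqrt(n * (1 / 3) * (2 / 3))
  expect_true(all(abs(counts - n / 3) <= 3 * se))

  expect_length(simulate_covariate(1, seed = 2), 1)
  expect_error(simulate_covariate(10, dist = "gamma", seed = 1))
})

test_that("phenotype generator obeys its variance decomposition", {
  # no-interaction truth: Var(y) = 0.5 + 0.5 and GREML recovers h2 = 0.5
  vc <- variance_components(sigma2_a0 = 0.5, sigma2_t0 = 0.5)
  sim <- simulate_rnm_data(2000, 1000, vc, seed = 31)
  expect_lt(abs(var(sim$y) - 1.0), 0.1)
  K <- compute_grm(sim$genotypes)
  fit <- rnm(sim$y, K, standardize_covariate(sim$covariate), model = "null")
  expect_true(fit$converged)
  expect_lt(abs(heritability(fit) - 0.5), 0.1)

  # degenerate noise: y is exactly the fixed effect
  g <- simulate_genotypes(200, 50, seed = 8)
  cv <- simulate_covariate(200, seed = 9)
  sim0 <- simulate_phenotype(g, cv, variance_components(),
                             fixed_effects = c(covariate = 1.5), seed = 10)
  expect_equal(sim0$y, 1.5 * standardize_covariate(cv), tolerance = 1e-12)

  # a genetic slope inflates variance with |c|: squared centered y
  # regressed on c^2 has positive slope
  vc1 <- variance_components(sigma2_a0 = 0.2, sigma2_a1 = 0.5,
                             sigma2_t0 = 0.2)
  sim1 <- simulate_rnm_data(1e4, 50, vc1, seed = 32)
  cs <- sim1$truth$c
  z2 <- (sim1$y - mean(sim1$y))^2
  expect_gt(coef(lm(z2 ~ I(cs^2)))[2], 0)
})

test_that("phenotype variance profile follows the reaction norm formula", {
  vc <- variance_components(sigma2_a0 = 0.3, sigma_a01 = 0.1,
                            sigma2_a1 = 0.3, sigma2_t0 = 0.2,
                            sigma_t01 = 0.05, sigma2_t1 = 0.2)
  # enough SNPs that between-individual genetic correlation (~1/sqrt(m))
  # does not inflate the sampling noise of the per-bin variances
  sim <- simulate_rnm_data(2e4, 200, vc, seed = 33)
  cs <- sim$truth$c
  bins <- cut(cs, quantile(cs, seq(0, 1, 0.1)), include.lowest = TRUE)
  emp <- tapply(sim$y, bins, var)
  v <- unclass(vc)
  vprofile <- v[1] + 2 * v[2] * cs + v[3] * cs^2 +
    v[4] + 2 * v[5] * cs + v[6] * cs^2
  theo <- tapply(vprofile, bins, mean)   # bin-averaged variance profile
  expect_lt(max(abs(emp - theo) / theo), 0.15)
})

test_that("liability-threshold case status behaves as designed", {
  vc <- variance_components(sigma2_a0 = 0.5, sigma2_t0 = 0.5)
  sim <- simulate_rnm_data(1e4, 40, vc, seed = 51)
  status <- simulate_case_status(sim$truth, prevalence = 0.05, seed = 52)
  expect_lte(abs(sum(status) - 500), 1)

  # zero genetic signal: cases and controls share the same genetic mean
  status0 <- simulate_case_status(sim$truth, prevalence = 0.2,
                                  h2_liability = 0, seed = 53)
  g <- sim$truth$g0
  d <- abs(mean(g[status0 == 1]) - mean(g[status0 == 0]))
  se <- sd(g) * sqrt(1 / sum(status0 == 1) + 1 / sum(status0 == 0))
  expect_lt(d, 3 * se)

  # strong signal: true risk higher in cases
  vc2 <- variance_components(sigma2_a0 = 0.6, sigma2_a1 = 0.2,
                             sigma2_t0 = 0.2)
  sim2 <- simulate_rnm_data(5000, 60, vc2, seed = 54)
  st <- simulate_case_status(sim2$truth, prevalence = 0.1,
                             h2_liability = 0.8, seed = 55)
  risk <- sim2$truth$g0 + (sim2$truth$g1 + sim2$truth$e1) * sim2$truth$c
  tt <- t.test(risk[st == 1], risk[st == 0], alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})

test_that("generator config is validated", {
  expect_error(variance_components(sigma2_a0 = -0.1), "nonnegative")
  expect_error(variance_components(sigma2_a0 = 0.1, sigma_a01 = 0.5,
                                   sigma2_a1 = 0.1),
               "positive semidefinite")
  g <- simulate_genotypes(20, 5, seed = 1)
  expect_error(simulate_phenotype(g, rnorm(10), variance_components(
    sigma2_a0 = 1, sigma2_t0 = 1), seed = 1), "length")
})
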