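test_that("risk prediction is the BLUP linear combination", {
  b <- data.frame(a0 = 0.5, a1 = 0.2, t1 = 0.1)
  expect_equal(predict_risk(b, 1), 0.8)
  expect_equal(predict_risk(b, 0), 0.5)          # at the covariate mean

  b2 <- data.frame(a0 = rnorm(20), a1 = 0, t1 = 0)
  cs <- rnorm(20)
  expect_equal(predict_risk(b2, cs), b2$a0)      # no interaction, no slope
  expect_error(predict_risk(b2, rnorm(5)), "lengths differ")
})

test_that("stratification picks the bottom, middle and top 20%", {
  lab <- stratify_by_effect(1:10)
  expect_identical(which(lab == "BOTTOM20"), 1:2)
  expect_identical(which(lab == "TOP20"), 9:10)
  expect_identical(which(lab == "MIDDLE20"), 5:6)

  # all-tied effects: stable id tie-break still yields size-2 groups
  lab2 <- stratify_by_effect(rep(1, 10), ids = 1:10)
  expect_equal(unname(table(lab2)), c(2L, 2L, 2L), ignore_attr = TRUE)

  lab3 <- stratify_by_effect(rnorm(1000))
  expect_equal(sum(lab3 == "BOTTOM20", na.rm = TRUE), 200)
  expect_equal(sum(lab3 == "MIDDLE20", na.rm = TRUE), 200)
  expect_equal(sum(lab3 == "TOP20", na.rm = TRUE), 200)
  expect_error(stratify_by_effect(1:4), "at least 5")
})

test_that("sign orientation flips only the favorable-direction variables", {
  v <- c(1.2, -0.3)
  expect_equal(orient_signs("HDL", v), -v)
  expect_equal(orient_signs("glucose", v), v)
  expect_equal(orient_signs("PA:walk", v), -v)
  expect_equal(orient_signs("HDL", orient_signs("HDL", v)), v)  # involution
  expect_warning(out <- orient_signs("mystery", v), "unknown")
  expect_equal(out, v)
})

test_that("group regression lines match the closed-form OLS", {
  set.seed(71)
  n <- 120
  cs <- rnorm(n)
  groups <- stratify_by_effect(rnorm(n))
  status <- rbinom(n, 1, 0.5)

  yhat <- 2 + 3 * cs                       # exact line everywhere
  tl <- trajectory_lines(yhat, cs, groups, status)
  filled <- !is.na(tl$intercept)
  expect_true(any(filled))
  expect_equal(tl$intercept[filled], rep(2, sum(filled)), tolerance = 1e-10)
  expect_equal(tl$slope[filled], rep(3, sum(filled)), tolerance = 1e-10)

  yc <- rep(1.5, n)                        # constant: slope 0
  tl2 <- trajectory_lines(yc, cs, groups, status)
  expect_equal(tl2$slope[!is.na(tl2$slope)],
               rep(0, sum(!is.na(tl2$slope))), tolerance = 1e-12)

  # cell-level OLS equals cov/var closed form
  yr <- rnorm(n)
  tl3 <- trajectory_lines(yr, cs, groups, status)
  sel <- !is.na(groups) & groups == "TOP20" & status == 1
  if (sum(sel) >= 2) {
    beta <- cov(yr[sel], cs[sel]) / var(cs[sel])
    alpha <- mean(yr[sel]) - beta * mean(cs[sel])
    row <- tl3[tl3$group == "TOP20" & tl3$status == "case", ]
    expect_equal(row$slope, beta, tolerance = 1e-10)
    expect_equal(row$intercept, alpha, tolerance = 1e-10)
  }
})

test_that("aggregation performs the paired t-test across analyses", {
  mk <- function(int_case, int_ctrl) {
    d <- expand.grid(group = c("BOTTOM20", "MIDDLE20", "TOP20"),
                     status = c("control", "case"),
                     stringsAsFactors = FALSE)
    d$intercept <- ifelse(d$status == "case", int_case, int_ctrl)
    d$slope <- 1
    d$n <- 10L
    d
  }
  # paired intercept differences (1, 2, 3): t = 2 / (1/sqrt(3)) = 3.464
  s <- list(mk(1, 0), mk(2, 0), mk(3, 0))
  agg <- aggregate_trajectories(s)
  row <- agg$paired_tests[agg$paired_tests$group == "TOP20", ]
  expect_equal(row$intercept_t, 2 / (1 / sqrt(3)), tolerance = 1e-6)
  expect_equal(row$intercept_p,
               2 * pt(-2 / (1 / sqrt(3)), df = 2), tolerance = 1e-6)
  expect_equal(round(row$intercept_p, 4), 0.0742)
  # identical slopes in every analysis: zero-variance path, p undefined
  expect_true(is.na(row$slope_p))

  # identical case/control summaries: difference 0, undefined test
  s2 <- list(mk(1, 1), mk(1, 1))
  agg2 <- aggregate_trajectories(s2)
  expect_true(all(is.na(agg2$paired_tests$intercept_p)))
  expect_equal(agg2$paired_tests$intercept_diff, rep(0, 3))
})

test_that("stratification variants coincide when a component is absent", {
  set.seed(72)
  a1 <- rnorm(100)
  t1 <- rep(0, 100)
  expect_identical(stratify_by_effect(a1 + t1, ids = 1:100),
                   stratify_by_effect(a1, ids = 1:100))
})

test_that("TOP20 stratum has steeper predicted slopes than BOTTOM20", {
  # by construction: predicted slope = a1 + t1, the stratifying quantity
  sim <- simulate_rnm_data(3000, 40,
    variance_components(sigma2_a0 = 0.3, sigma2_a1 = 0.3,
                        sigma2_t0 = 0.2, sigma2_t1 = 0.1), seed = 73)
  eff <- sim$truth$g1 + sim$truth$e1
  yhat <- sim$truth$g0 + eff * sim$truth$c
  groups <- stratify_by_effect(eff)
  tl <- trajectory_lines(yhat, sim$truth$c, groups, rep(0, 3000))
  ctrl <- tl[tl$status == "control", ]
  expect_gt(ctrl$slope[ctrl$group == "TOP20"],
            ctrl$slope[ctrl$group == "BOTTOM20"])
})
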