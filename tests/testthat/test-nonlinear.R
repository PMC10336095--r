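test_that("fractional-polynomial basis transforms follow the standard conventions", {
  x <- c(1, exp(1), exp(2))
  expect_equal(fp_transform(x, 1), x)                     # p = 1 is the identity
  expect_equal(fp_transform(x, 0), c(0, 1, 2))            # p = 0 is natural log
  expect_equal(fp_transform(x, -2), x^-2)

  rep2 <- fp_transform(exp(1), c(2, 2))                   # repeated power
  expect_equal(unname(rep2[1, ]), c(exp(2), exp(2)))      # (x^2, x^2 log x) at x = e

  pair <- fp_transform(x, c(0, 0.5))
  expect_equal(unname(pair[, 1]), log(x))
  expect_equal(unname(pair[, 2]), sqrt(x))

  expect_error(fp_transform(c(1, -1), 2), class = "mrwell_domain_error")
})

test_that("the degree-2 search space has exactly 36 combinations", {
  pairs <- fp2_power_pairs()
  expect_equal(nrow(pairs), 36)
  expect_equal(sum(pairs$p1 == pairs$p2), 8)              # repeated powers
  expect_equal(sum(pairs$p1 < pairs$p2), choose(8, 2))    # distinct pairs
  expect_true(all(pairs$p1 %in% fp_powers & pairs$p2 %in% fp_powers))
})

test_that("quadratic fits recover curvature and stay calibrated under the null", {
  set.seed(5)
  n <- 2000
  x <- rnorm(n, 25, 3)
  y <- -(x - 25)^2 / 10 + rnorm(n)
  fit <- fit_quadratic(x, y)
  expect_lt(fit$beta_quadratic, 0)
  expect_lt(abs(fit$beta_quadratic - (-0.1)), 3 * fit$se_quadratic)

  # null calibration: rejection rate of the quadratic term near 5%
  set.seed(6)
  rej <- vapply(1:200, function(i) {
    x <- rnorm(400, 25, 3)
    y <- 0.1 * x + rnorm(400)
    fit_quadratic(x, y)$p_quadratic < 0.05
  }, logical(1))
  ci <- binom.test(sum(rej), 200, 0.05)$conf.int
  expect_true(ci[1] <= 0.05 && 0.05 <= ci[2])
})

test_that("the degree-2 polynomial at powers (1, 2) is exactly a quadratic regression", {
  set.seed(7)
  x <- rnorm(1500, 25, 3)
  y <- 0.2 * x - 0.03 * (x - 25)^2 + rnorm(1500)
  quad <- fit_quadratic(x, y)
  pre <- x / mean(x)
  fp12 <- mrwell:::.fp_fit(pre, y, c(1, 2), NULL, mean(x))
  expect_equal(fp12$aic, quad$aic, tolerance = 1e-8)
  expect_equal(fp12$fitted, quad$fitted, tolerance = 1e-8)
})

test_that("degree-1 search finds the generative power and matches linear regression at p = 1", {
  set.seed(8)
  n <- 5000
  x <- exp(rnorm(n, 0, 0.4)) * 10          # positive, skewed exposure
  y <- log(x) + rnorm(n, 0, 0.1)
  best <- fp1_search(x, y)
  expect_equal(best$powers, 0)             # log truth selected
  expect_equal(nrow(best$aic_table), 8)    # exhaustive search

  y2 <- 0.3 * x + rnorm(n)
  best2 <- fp1_search(x, y2)
  expect_equal(best2$powers, 1)
  lin <- fit_linear(x, y2)
  expect_equal(best2$aic, lin$aic, tolerance = 1e-8)
})

test_that("degree-2 search is exhaustive and identifies quadratic truth", {
  set.seed(9)
  n <- 4000
  x <- rnorm(n, 25, 3)
  y <- 0.1 * x - 0.05 * (x - 25)^2 + rnorm(n, 0, 0.5)
  best <- fp2_search(x, y)
  expect_equal(nrow(best$aic_table), 36)
  expect_equal(sort(best$powers), c(1, 2))
  quad <- fit_quadratic(x, y)
  expect_equal(best$aic, quad$aic, tolerance = 1e-8)
  expect_false(best$collapsible)
})

test_that("AIC selection prefers the true model class and honours its tie rules", {
  set.seed(10)
  # replicate majority: linear truth favours the linear model
  wins <- vapply(1:40, function(i) {
    x <- rnorm(800, 25, 3)
    y <- 0.2 * x + rnorm(800)
    lin <- fit_linear(x, y)
    quad <- fit_quadratic(x, y)
    sel <- select_by_aic(list(lin, quad))
    sel$best$k == lin$k
  }, logical(1))
  expect_gt(mean(wins), 0.5)

  # quadratic truth: quadratic wins
  x <- rnorm(3000, 25, 3)
  yq <- 0.1 * x - 0.08 * (x - 25)^2 + rnorm(3000)
  sel <- select_by_aic(list(fit_linear(x, yq), fit_quadratic(x, yq)))
  expect_equal(sel$best$k, 3)

  # exact tie: fewer parameters win
  m_small <- list(aic = 100, k = 2, n = 50)
  m_big <- list(aic = 100, k = 4, n = 50)
  expect_equal(select_by_aic(list(m_big, m_small))$best$k, 2)

  expect_error(select_by_aic(list(list(aic = 1, k = 2, n = 50),
                                  list(aic = 1, k = 2, n = 60))),
               class = "mrwell_comparability_error")
})

test_that("the control function matches TSLS in the linear just-identified case", {
  co <- quick_cohort(n = 4000, m = 10, seed = 15, beta_linear = 0.3,
                     confounder_strength_x = 1, confounder_strength_y = 1,
                     noise_sd_x = 1, noise_sd_y = 1, beta_g = 0.12,
                     exposure_mean = 20)
  ph <- co$phenotypes
  gr <- true_grs(co)
  iv <- tsls_fit(gr, ph$bmi, ph$wellbeing_latent)
  cf <- control_function(gr, ph$bmi, ph$wellbeing_latent, degree = 1,
                         se_method = "naive")
  expect_equal(cf$beta, iv$beta, tolerance = 1e-8)
})

test_that("the control function recovers quadratic causal truth under confounding", {
  co <- quick_cohort(n = 20000, m = 20, seed = 25, beta_linear = 0.3,
                     beta_quadratic = -0.05,
                     confounder_strength_x = 1, confounder_strength_y = 1,
                     noise_sd_x = 1, noise_sd_y = 1, beta_g = 0.1,
                     exposure_mean = 20)
  ph <- co$phenotypes
  cf <- control_function(true_grs(co), ph$bmi, ph$wellbeing_latent,
                         se_method = "naive")
  expect_lt(abs(cf$beta - 0.3), 3.5 * cf$se)
  expect_lt(abs(cf$beta_quadratic - (-0.05)), 3.5 * cf$se_quadratic)
  expect_gt(cf$rho / cf$se_rho, 3)        # confounding picked up by the residual
})

test_that("without confounding the residual-control coefficient vanishes", {
  co <- quick_cohort(n = 10000, m = 10, seed = 35, beta_linear = 0.2,
                     confounder_strength_x = 0, confounder_strength_y = 0,
                     noise_sd_x = 1, noise_sd_y = 1, beta_g = 0.12,
                     exposure_mean = 20)
  ph <- co$phenotypes
  cf <- control_function(true_grs(co), ph$bmi, ph$wellbeing_latent,
                         se_method = "naive")
  expect_lt(abs(cf$rho), 3.5 * cf$se_rho)
})

test_that("bootstrap control-function SEs are stable in replicate count", {
  co <- quick_cohort(n = 4000, m = 10, seed = 45, beta_linear = 0.3,
                     beta_quadratic = -0.05,
                     confounder_strength_x = 1, confounder_strength_y = 1,
                     noise_sd_x = 1, noise_sd_y = 1, beta_g = 0.15,
                     exposure_mean = 20)
  ph <- co$phenotypes
  gr <- true_grs(co)
  cf1 <- control_function(gr, ph$bmi, ph$wellbeing_latent, n_boot = 200, seed = 1)
  cf2 <- control_function(gr, ph$bmi, ph$wellbeing_latent, n_boot = 400, seed = 2)
  expect_lt(abs(cf1$se_quadratic - cf2$se_quadratic) / cf2$se_quadratic, 0.25)
  # bootstrap and naive SEs agree in order of magnitude here
  cfn <- control_function(gr, ph$bmi, ph$wellbeing_latent, se_method = "naive")
  expect_lt(abs(cf2$se_quadratic - cfn$se_quadratic) / cfn$se_quadratic, 0.5)
})

test_that("cross-cohort comparison of quadratic terms is antisymmetric", {
  cf_a <- structure(list(beta_quadratic = -0.05, se_quadratic = 0.01), class = "cf_result")
  cf_b <- structure(list(beta_quadratic = 0.02, se_quadratic = 0.015), class = "cf_result")
  d1 <- compare_nonlinear(cf_a, cf_b)
  d2 <- compare_nonlinear(cf_b, cf_a)
  expect_equal(d1$z, -d2$z)
  expect_equal(d1$p, d2$p)
  expect_equal(compare_nonlinear(cf_a, cf_a)$p, 1)
})
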