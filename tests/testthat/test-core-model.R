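# The pooled logistic estimator and the slope-to-effect conversion.

test_that("symmetric frequencies force a zero slope and intercept", {
  fit <- fit_binomial_logit(c(1, 1), c(2, 2), c(-1, 1))
  expect_lt(abs(fit$slope_b), 1e-8)
  expect_lt(abs(fit$intercept_g), 1e-8)
  expect_true(fit$converged)
  expect_gt(fit$pvalue, 0)
  expect_lte(fit$pvalue, 1)
})

test_that("noise-free counts invert the logistic curve", {
  x <- c(-2, -1, 0, 1, 2)
  tot <- rep(1e6, 5)
  s <- plogis(0.3 + 0.8 * x) * tot
  fit <- fit_binomial_logit(s, tot, x)
  expect_equal(fit$intercept_g, 0.3, tolerance = 1e-3)
  expect_equal(fit$slope_b, 0.8, tolerance = 1e-3)
})

test_that("fit agrees with a Newton-Raphson likelihood oracle on small instances", {
  cases <- list(
    list(s = c(1, 3, 2, 5), t = c(6, 6, 6, 6), x = c(-1, 0, 1, 2)),
    list(s = c(0, 2, 4, 4, 5), t = c(5, 5, 5, 5, 6), x = c(-2, -1, 0, 1, 2)),
    list(s = c(2.5, 3.5, 1.0, 4.0), t = c(7, 7, 7, 7),
         x = c(0.3, -0.2, -1.1, 0.9))            # fractional counts
  )
  for (cs in cases) {
    fit <- fit_binomial_logit(cs$s, cs$t, cs$x)
    beta <- nr_logit_oracle(cs$s, cs$t, cs$x)
    expect_equal(fit$intercept_g, beta[1], tolerance = 1e-8)
    expect_equal(fit$slope_b, beta[2], tolerance = 1e-8)
  }
  # with a covariate
  set.seed(3)
  cv <- c(1, 0, 1, 0, 1, 0)
  s <- c(1, 2, 3, 2, 4, 1); t <- rep(5, 6); x <- c(-2, -1, 0, 1, 2, 3)
  fit <- fit_binomial_logit(s, t, x, covariates = cbind(cv))
  beta <- nr_logit_oracle(s, t, x, covariates = cbind(cv))
  expect_equal(unname(fit$coefficients), beta, tolerance = 1e-8)
})

test_that("degenerate inputs raise, separation is flagged not raised", {
  expect_error(fit_binomial_logit(c(0, 0), c(2, 2), c(-1, 1)),
               "unidentifiable")
  expect_error(fit_binomial_logit(c(2, 2), c(2, 2), c(-1, 1)),
               "unidentifiable")
  expect_error(fit_binomial_logit(c(1, 1), c(2, 2), c(1, 1)), "constant")
  expect_error(fit_binomial_logit(c(1), c(2), c(1)), "at least two")
  expect_error(
    fit_binomial_logit(c(1, 2, 1), c(3, 3, 3), c(-1, 0, 1),
                       covariates = cbind(a = c(1, 1, 1))),  # aliases intercept
    "rank deficient")
  # perfect separation: low-x pools fixed for one allele, high-x the other
  fit <- fit_binomial_logit(c(0, 0, 5, 5), rep(5, 4), 1:4)
  expect_false(fit$converged)
})

test_that("Wald and likelihood-ratio tests broadly agree away from boundaries", {
  set.seed(9)
  x <- seq(-2, 2, length.out = 12)
  s <- rbinom(12, 40, plogis(0.2 + 0.5 * x))
  fw <- fit_binomial_logit(s, rep(40, 12), x, test = "wald")
  fl <- fit_binomial_logit(s, rep(40, 12), x, test = "lrt")
  expect_equal(fw$slope_b, fl$slope_b, tolerance = 1e-10)
  expect_equal(log(fw$pvalue), log(fl$pvalue), tolerance = 0.2)
})

test_that("alpha_from_b matches its closed-form examples and symmetry", {
  expect_identical(alpha_from_b(0, 0.5, 1), 0)
  expect_equal(alpha_from_b(1, 0.5, 1.125), 0.5, tolerance = 1e-12)
  expect_equal(alpha_from_b(-1, 0.5, 1.125), -0.5, tolerance = 1e-12)
  expect_error(alpha_from_b(1, 0, 1), "strictly inside")
  expect_error(alpha_from_b(1, 1, 1), "strictly inside")
  expect_error(alpha_from_b(1, 0.5, 0), "positive")
})

test_that("alpha_from_b inverts the forward map exactly over a grid", {
  set.seed(17)
  for (i in 1:200) {
    alpha <- runif(1, -2, 2)
    p <- runif(1, 0.01, 0.99)
    sigma_e2 <- runif(1, 0.2, 3)
    b <- 2 * alpha / sigma_e2
    sigma2 <- sigma_e2 + 2 * p * (1 - p) * alpha^2
    expect_equal(alpha_from_b(b, p, sigma2), alpha, tolerance = 1e-12)
  }
})

test_that("alpha_from_b is continuous at b = 0", {
  for (eps in 10^-(4:9)) {
    a <- alpha_from_b(eps, 0.3, 1.7)
    expect_lt(abs(a - eps * 1.7 / 2), eps^2 * 10)
  }
  # sign always follows b
  expect_gt(alpha_from_b(0.5, 0.2, 2), 0)
  expect_lt(alpha_from_b(-0.5, 0.2, 2), 0)
})

test_that("mlp_from_pvalue is exact at its anchor points", {
  expect_identical(mlp_from_pvalue(1e-5), 5)
  expect_identical(mlp_from_pvalue(1), 0)
  expect_equal(mlp_from_pvalue(0.05), 1.30103, tolerance = 1e-5)
  expect_error(mlp_from_pvalue(0), "in \\(0, 1\\]")
  expect_error(mlp_from_pvalue(1.5), "in \\(0, 1\\]")
})

test_that("pooled estimator recovers a known per-allele effect", {
  set.seed(21)
  n <- 3000
  dosage <- rbinom(n, 2, 0.5)
  y <- 0.3 * dosage + rnorm(n)
  ch <- snp_cohort(matrix(dosage, ncol = 1), y)
  ps <- make_pools(ch, 64, within_group = FALSE)
  est <- estimate_pooled_snp_effect(ps, 1, sigma2 = var(y))
  expect_true(est$converged)
  # 3 x the LS standard error at this design: sqrt(1/(2 p (1-p) n)) ~ 0.026
  expect_lt(abs(est$alpha - 0.3), 0.08)
  expect_equal(sign(est$alpha), sign(est$slope_b))
  expect_gte(est$mlp, 0)
})

test_that("degenerate pool sets raise or flag as specified", {
  ps <- pool_set(sizes = c(10, 10), mean_phenotype = c(1, 1),
                 freq = matrix(0.5, 2, 1))
  expect_error(estimate_pooled_snp_effect(ps, 1, sigma2 = 1), "constant")
  fixed <- pool_set(sizes = c(10, 10), mean_phenotype = c(0, 1),
                    freq = matrix(1, 2, 1))
  est <- estimate_pooled_snp_effect(fixed, 1, sigma2 = 1)
  expect_false(est$converged)
  expect_true(is.na(est$alpha))
  expect_error(estimate_pooled_snp_effect(ps, 1), "sigma2")
})

test_that("singleton pools reproduce the individual logistic analysis bit for bit", {
  ch <- random_cohort(n = 150, m = 3, seed = 5, alpha = 0.4)
  s2 <- var(ch$phenotypes)
  for (j in 1:3) {
    a <- estimate_pooled_snp_effect(singleton_pools(ch), j, sigma2 = s2)
    b <- estimate_individual_lr(ch, j, sigma2 = s2)
    expect_identical(a$alpha, b$alpha)
    expect_identical(a$slope_b, b$slope_b)
    expect_identical(a$mlp, b$mlp)
    expect_identical(a$method, "individual_lr")
  }
})

test_that("fitted slope increases with the true effect on noise-free counts", {
  x <- seq(-1.5, 1.5, length.out = 8)
  slopes <- sapply(c(0.1, 0.2, 0.3, 0.4), function(alpha) {
    b_true <- 2 * alpha / 1
    s <- plogis(b_true * x) * 100
    fit_binomial_logit(s, rep(100, 8), x)$slope_b
  })
  expect_true(all(diff(slopes) > 0))
})

test_that("individual vs haploid count scales agree on alpha, differ on information", {
  ch <- random_cohort(n = 400, m = 1, seed = 8, alpha = 0.35)
  ps <- make_pools(ch, 16, within_group = FALSE)
  s2 <- var(ch$phenotypes)
  hap <- estimate_pooled_snp_effect(ps, 1, sigma2 = s2)
  ind <- estimate_pooled_snp_effect(ps, 1, sigma2 = s2,
                                    count_scale = "individuals")
  expect_equal(hap$alpha, ind$alpha, tolerance = 1e-10)
  expect_equal(hap$se_b * sqrt(2), ind$se_b, tolerance = 1e-6)
  expect_gt(hap$mlp, ind$mlp)
})
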