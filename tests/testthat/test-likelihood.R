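# Constant-SD toy model used throughout: means are exponential in rho,
# SDs constant, correlations fixed.
default_toy <- function(corr = diag(3), sds = c(0.2, 0.03, 0.1)) {
  toy_model(
    mean_curves = list(g_max = c(a = 1.34, b = 4.52, c = 1.10),
                       F_max = c(a = 0.18, b = 9.16, c = 0.09),
                       J_min = c(a = -2.04, b = 0.74, c = 2.06)),
    sd_curves = list(g_max = c(a = 0, b = 0, c = sds[1]),
                     F_max = c(a = 0, b = 0, c = sds[2]),
                     J_min = c(a = 0, b = 0, c = sds[3])),
    corr = corr)
}

test_that("univariate log-likelihood matches the Gaussian density", {
  m <- default_toy()
  mu0 <- 1.34 + 1.10
  # zero residual
  expect_equal(log_likelihood_single(mu0, 0, m, "g_max"),
               -0.5 * log(2 * pi * 0.2^2))
  # unit residual with sigma = 1
  m1 <- default_toy(sds = c(1, 1, 1))
  expect_equal(log_likelihood_single(mu0 + 1, 0, m1, "g"),
               -0.5 * (log(2 * pi) + 1))
  expect_equal(-0.5 * (log(2 * pi) + 1), -1.418939, tolerance = 1e-6)
  # oracle: dnorm at random (x, rho)
  set.seed(17)
  for (k in 1:20) {
    x <- runif(1, 0.5, 3); rho <- runif(1, 0, 0.5)
    mu <- 1.34 * exp(-4.52 * rho) + 1.10
    expect_equal(log_likelihood_single(x, rho, m, "g_max"),
                 dnorm(x, mu, 0.2, log = TRUE), tolerance = 1e-12)
  }
  expect_error(log_likelihood_single(1, 0.7, m, "g_max"), "\\[0, 0.5\\]")
  m_bad <- default_toy(sds = c(-1, 1, 1))
  expect_error(log_likelihood_single(1, 0.1, m_bad, "g_max"),
               "SD non-positive")
})

test_that("multivariate log-likelihood factorises, reduces and matches oracles", {
  x <- list(g_max = 1.9, F_max = 0.12, J_min = 0.35)
  rho <- c(0, 0.17, 0.42)

  # diagonal covariance: sum of univariate terms
  m <- default_toy()
  ll3 <- log_likelihood_multi(x, rho, m, "gFJ")
  ll_sum <- log_likelihood_single(x$g_max, rho, m, "g_max") +
    log_likelihood_single(x$F_max, rho, m, "F_max") +
    log_likelihood_single(x$J_min, rho, m, "J_min")
  expect_equal(ll3, ll_sum, tolerance = 1e-12)

  # k = 1 reduction
  expect_equal(log_likelihood_multi(x, rho, m, "g"),
               log_likelihood_single(x$g_max, rho, m, "g_max"))

  # correlated case against a direct solve()/cofactor oracle
  C <- matrix(c(1, 0.5, -0.3, 0.5, 1, 0.2, -0.3, 0.2, 1), 3, 3)
  mc <- default_toy(corr = C)
  for (r in rho) {
    mu <- c(1.34 * exp(-4.52 * r) + 1.10,
            0.18 * exp(-9.16 * r) + 0.09,
            -2.04 * exp(-0.74 * r) + 2.06)
    S <- diag(c(0.2, 0.03, 0.1)) %*% C %*% diag(c(0.2, 0.03, 0.1))
    xv <- c(x$g_max, x$F_max, x$J_min)
    ll_oracle <- -0.5 * (log(oracle_det(S)) +
                         drop(t(xv - mu) %*% solve(S) %*% (xv - mu)) +
                         3 * log(2 * pi))
    expect_equal(log_likelihood_multi(x, r, mc, "gFJ"), ll_oracle,
                 tolerance = 1e-10)
  }

  # x = mu gives -0.5 (ln|Sigma| + k ln 2pi)
  r0 <- 0.3
  x_mu <- list(g_max = 1.34 * exp(-4.52 * r0) + 1.10,
               F_max = 0.18 * exp(-9.16 * r0) + 0.09,
               J_min = -2.04 * exp(-0.74 * r0) + 2.06)
  S <- diag(c(0.2, 0.03, 0.1)) %*% C %*% diag(c(0.2, 0.03, 0.1))
  expect_equal(log_likelihood_multi(x_mu, r0, mc, "gFJ"),
               -0.5 * (log(oracle_det(S)) + 3 * log(2 * pi)),
               tolerance = 1e-10)

  # pairwise subset uses the right 2x2 restriction
  S2 <- S[c(1, 3), c(1, 3)]
  xv2 <- c(x$g_max, x$J_min)
  mu2 <- c(1.34 * exp(-4.52 * r0) + 1.10, -2.04 * exp(-0.74 * r0) + 2.06)
  expect_equal(log_likelihood_multi(x, r0, mc, "gJ"),
               -0.5 * (log(oracle_det(S2)) +
                       drop(t(xv2 - mu2) %*% solve(S2) %*% (xv2 - mu2)) +
                       2 * log(2 * pi)),
               tolerance = 1e-10)

  expect_error(log_likelihood_multi(x, r0, mc, "gX"), "subset")
})

test_that("rho estimation maximises the profile and truncates at bounds", {
  m <- default_toy()  # constant SDs: argmax sits at the generating mean
  x <- list(g_max = 1.34 * exp(-4.52 * 0.3) + 1.10,
            F_max = 0.18 * exp(-9.16 * 0.3) + 0.09,
            J_min = -2.04 * exp(-0.74 * 0.3) + 2.06)
  est <- estimate_rho(x, m, "gFJ")
  expect_equal(est$eta, 0.3, tolerance = est$rho_step + 1e-12)
  expect_lte(est$ci_lower, est$eta)
  expect_gte(est$ci_upper, est$eta)
  # profile is maximal at eta
  expect_equal(max(est$profile$log_lik), est$log_lik_max)

  # far-above-mean g_max pins eta at the lower boundary
  est0 <- estimate_rho(list(g_max = 5), m, "g")
  expect_equal(est0$eta, 0)
  expect_equal(est0$ci_lower, 0)

  # flat likelihood: ties resolve to the smallest rho
  m_flat <- toy_model(
    mean_curves = list(g_max = c(a = 0, b = 0, c = 1),
                       F_max = c(a = 0, b = 0, c = 1),
                       J_min = c(a = 0, b = 0, c = 1)),
    sd_curves = list(g_max = c(a = 0, b = 0, c = 1),
                     F_max = c(a = 0, b = 0, c = 1),
                     J_min = c(a = 0, b = 0, c = 1)))
  expect_equal(estimate_rho(list(g_max = 1), m_flat, "g")$eta, 0)
})

test_that("profile CI width matches the closed-form normal-model interval", {
  # linear mean mu(rho) = rho, constant sigma: CI half-width 1.96 sigma.
  # a*exp(-b*rho)+c ~ c - a*b*rho for small b; use a = -1/b, c = 1/b
  b <- 1e-6
  m_lin <- toy_model(
    mean_curves = list(g_max = c(a = -1 / b, b = b, c = 1 / b),
                       F_max = c(a = 0, b = 0, c = 1),
                       J_min = c(a = 0, b = 0, c = 1)),
    sd_curves = list(g_max = c(a = 0, b = 0, c = 0.05),
                     F_max = c(a = 0, b = 0, c = 1),
                     J_min = c(a = 0, b = 0, c = 1)))
  est <- estimate_rho(list(g_max = 0.25), m_lin, "g", rho_step = 0.001)
  expect_equal(est$eta, 0.25, tolerance = 0.002)
  # grid discretisation can move each CI endpoint by up to two steps
  expect_lt(abs((est$ci_upper - est$ci_lower) - 2 * 1.96 * 0.05), 0.0045)
})

test_that("single-statistic estimates are monotone in the observation", {
  m <- default_toy()
  # decreasing mean curve: larger g_max -> smaller eta
  etas <- vapply(seq(1.1, 2.6, by = 0.05), function(g)
    estimate_rho(list(g_max = g), m, "g")$eta, numeric(1))
  expect_true(all(diff(etas) <= 0))
  # increasing mean curve: larger J_min -> larger eta
  etas_j <- vapply(seq(0.05, 0.9, by = 0.05), function(j)
    estimate_rho(list(J_min = j), m, "J")$eta, numeric(1))
  expect_true(all(diff(etas_j) >= 0))
})

test_that("batch prediction produces one consistent row per pattern-subset", {
  m <- default_toy()
  set.seed(21)
  feats <- data.frame(pattern_id = sprintf("p%02d", 1:10),
                      rho = runif(10, 0, 0.5))
  feats$g_max <- 1.34 * exp(-4.52 * feats$rho) + 1.10 + rnorm(10, 0, 0.1)
  feats$F_max <- 0.18 * exp(-9.16 * feats$rho) + 0.09 + rnorm(10, 0, 0.02)
  feats$J_min <- -2.04 * exp(-0.74 * feats$rho) + 2.06 + rnorm(10, 0, 0.05)
  pred <- predict_batch(feats, m)
  expect_equal(nrow(pred), 70L)
  expect_true(all(pred$ci_lower <= pred$eta & pred$eta <= pred$ci_upper))
  expect_true(all(pred$eta >= 0 & pred$eta <= 0.5))
  expect_setequal(unique(pred$subset), all_subsets())
})
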