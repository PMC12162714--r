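# the factorized prior, including the penalized random-effect variance prior

test_that("penalized variance prior = Gamma factors + degeneracy penalty", {
  x <- c(1, 1)
  # lambda = 0: exactly the sum of Gamma log densities
  expect_equal(log_prior_sigma_g(x, alpha_b = 1.5, lambda = 0),
               sum(dgamma(x, 1.5, rate = 1.5, log = TRUE)))
  # penalty at (1, 1) with lambda = 1 is -1/sqrt(2)
  expect_equal(log_prior_sigma_g(x, 1.5, 1) - log_prior_sigma_g(x, 1.5, 0),
               -1 / sqrt(2), tolerance = 1e-12)
  expect_equal(-1 / sqrt(2), -0.7071, tolerance = 1e-4)
  # the penalty vanishes far from the origin
  big <- c(500, 500)
  expect_lt(abs(log_prior_sigma_g(big, 1.5, 1) -
                log_prior_sigma_g(big, 1.5, 0)), 0.05)
  expect_error(log_prior_sigma_g(c(1, -1)), "positive")
})

test_that("penalized prior is proper and penalization only removes mass", {
  # 2-d numeric integral over (0, 20]^2 of the unnormalized density is finite
  # and smaller than the lambda = 0 normalizer (the Gamma product, ~1)
  f <- function(x, y, lambda) {
    exp(dgamma(x, 1.5, rate = 1.5, log = TRUE) +
          dgamma(y, 1.5, rate = 1.5, log = TRUE) - lambda / sqrt(x + y))
  }
  int2 <- function(lambda) {
    stats::integrate(function(x) vapply(x, function(xx)
      stats::integrate(function(y) f(xx, y, lambda), 1e-8, 20,
                       rel.tol = 1e-8)$value, numeric(1)),
      1e-8, 20, rel.tol = 1e-8)$value
  }
  z0 <- int2(0)          # Gamma-product mass on the box (close to 1)
  z1 <- int2(1)
  expect_lt(z1, z0)
  expect_gt(z1, 0.3 * z0)         # penalty removes mass but keeps propriety
  expect_equal(z0, prod(rep(pgamma(20, 1.5, rate = 1.5), 2)), tolerance = 0.02)
})

test_that("prior mode lies on the equal-diagonal line and is stationary", {
  # lambda = 0: the Gamma mode (alpha_b - 1) / alpha_b
  expect_equal(prior_mode_sigma(alpha_b = 1.5, lambda = 0, r = 2),
               rep(1 / 3, 2), tolerance = 1e-5)
  m <- prior_mode_sigma(alpha_b = 1.5, lambda = 1, r = 2)
  expect_lt(diff(range(m)), 1e-6)
  expect_gt(m[1], 1 / 3)   # penalty pushes the mode away from the origin
  # grid-search oracle along the equal-diagonal line
  grid <- seq(0.05, 3, by = 1e-4)
  vals <- vapply(grid, function(s) log_prior_sigma_g(c(s, s), 1.5, 1),
                 numeric(1))
  expect_equal(m[1], grid[which.max(vals)], tolerance = 2e-4)
  # first-order stationarity
  g <- numDeriv::grad(function(x) log_prior_sigma_g(x, 1.5, 1), m)
  expect_lt(max(abs(g)), 1e-6)
  expect_error(prior_mode_sigma(alpha_b = 0.9), "exceed 1")
})

test_that("joint structural prior adds the configured marginal densities", {
  spec <- scenario_spec(G = 2, membership_model = 2)
  cfg <- jlcm_priors()
  cp <- demo_params()
  draw <- list(classes = list(cp, cp), psi0 = 0.3,
               psi = matrix(c(0.1, -0.2), 1), b = array(0, c(1, 2, 2)))
  lp <- log_prior_theta(draw, cfg, spec)
  manual <- 2 * (sum(dnorm(cp$beta, 0, 5, log = TRUE)) +
                 log(2) + dnorm(cp$sigma2, 0, 0.5, log = TRUE) +
                 dgamma(cp$phi0, 2, rate = 0.5, log = TRUE) +
                 dnorm(cp$phi1, 0, 5, log = TRUE) +
                 dnorm(cp$gamma, 0, 5, log = TRUE) +
                 dnorm(cp$alpha, 0, 5, log = TRUE) +
                 log_prior_sigma_g(cp$Sigma_diag, 1.5, 1)) +
    sum(dnorm(c(0.3, 0.1, -0.2), 0, 1, log = TRUE))
  expect_equal(lp, manual, tolerance = 1e-12)
  # half-Normal(0, 0.5^2) at sigma2 = 0.5 is log 2 + log N(0.5; 0, 0.5^2)
  cp2 <- cp; cp2$sigma2 <- 0.5
  d1 <- list(classes = list(cp2), psi0 = numeric(0), psi = matrix(0, 0, 0),
             b = array(0, c(1, 2, 1)))
  d1b <- d1; d1b$classes <- list(cp)
  spec1 <- scenario_spec(G = 1, membership_model = 1)
  diffv <- log_prior_theta(d1, cfg, spec1) - log_prior_theta(d1b, cfg, spec1)
  expect_equal(diffv, (log(2) + dnorm(0.5, 0, 0.5, log = TRUE)) -
                 (log(2) + dnorm(cp$sigma2, 0, 0.5, log = TRUE)),
               tolerance = 1e-12)
  # Weibull-shape prior at the benchmark value 1.4 matches the reference pdf
  expect_equal(dgamma(1.4, shape = 2, rate = 0.5, log = TRUE),
               log(0.5^2 * 1.4 * exp(-0.5 * 1.4) / gamma(2)), tolerance = 1e-12)
})

test_that("priors factorize across classes", {
  spec <- scenario_spec(G = 2, membership_model = 2)
  cfg <- jlcm_priors()
  base <- list(classes = list(demo_params(), demo_params()), psi0 = 0,
               psi = matrix(0, 1, 2), b = array(0, c(1, 2, 2)))
  bump1 <- base; bump1$classes[[1]]$beta[1] <- 3
  delta_a <- log_prior_theta(bump1, cfg, spec) - log_prior_theta(base, cfg, spec)
  # change class 2 values; the class-1 perturbation effect must not move
  base2 <- base; base2$classes[[2]]$phi1 <- 2; base2$classes[[2]]$alpha <- -1
  bump2 <- base2; bump2$classes[[1]]$beta[1] <- 3
  delta_b <- log_prior_theta(bump2, cfg, spec) - log_prior_theta(base2, cfg, spec)
  expect_equal(delta_a, delta_b, tolerance = 1e-12)
})

test_that("G = 1 uses the inverse-Gamma variance prior", {
  cfg <- jlcm_priors()
  spec1 <- scenario_spec(G = 1, membership_model = 1)
  cp <- demo_params()
  d1 <- list(classes = list(cp), psi0 = numeric(0), psi = matrix(0, 0, 0),
             b = array(0, c(1, 2, 1)))
  lp <- log_prior_theta(d1, cfg, spec1)
  ig <- function(x, a, s) a * log(s) - lgamma(a) - (a + 1) * log(x) - s / x
  manual <- sum(dnorm(cp$beta, 0, 5, log = TRUE)) +
    log(2) + dnorm(cp$sigma2, 0, 0.5, log = TRUE) +
    dgamma(cp$phi0, 2, rate = 0.5, log = TRUE) +
    dnorm(cp$phi1, 0, 5, log = TRUE) + dnorm(cp$gamma, 0, 5, log = TRUE) +
    dnorm(cp$alpha, 0, 5, log = TRUE) +
    sum(ig(cp$Sigma_diag, 0.01, 0.01))
  expect_equal(lp, manual, tolerance = 1e-12)
})

test_that("residual-variance elicitation recovers the generating noise level", {
  sim <- tiny_sim(n = 150, seed = 23, scenario = "setting2_scenario1")
  est <- elicit_sigma_scale(sim$data, scenario_spec(G = 2, membership_model = 1))
  expect_gt(est, 0.4761 * 0.6)
  expect_lt(est, 0.4761 * 1.6)
})
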