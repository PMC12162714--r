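# log-density building blocks of the joint model

test_that("membership probabilities follow the softmax with reference class G", {
  expect_equal(membership_probs(c(0, 0), NULL, NULL, G = 3), rep(1 / 3, 3))
  expect_equal(membership_probs(numeric(0), NULL, NULL, G = 1), 1)
  # scenario-3 coefficients at (male = 1, age = 45): eta = 2 + 4 - 4.5 = 1.5
  p <- membership_probs(2, matrix(c(4, -0.1), 1), c(1, 45), G = 2)
  expect_equal(p[1], stats::plogis(1.5), tolerance = 1e-12)
  expect_equal(p[1], 0.8176, tolerance = 1e-4)
})

test_that("membership probabilities are a proper simplex for extreme inputs", {
  set.seed(1)
  for (rep in 1:25) {
    G <- sample(2:5, 1)
    p <- sample(0:3, 1)
    psi0 <- rnorm(G - 1, 0, 100)         # deliberately overflow-prone
    psi <- matrix(rnorm((G - 1) * p, 0, 50), G - 1, p)
    W <- rnorm(p)
    pr <- membership_probs(psi0, if (p > 0) psi else NULL,
                           if (p > 0) W else NULL, G)
    expect_true(all(pr >= 0))
    expect_lt(abs(sum(pr) - 1), 1e-12)
  }
})

test_that("membership dimension mismatches are rejected with a clear error", {
  expect_error(membership_probs(c(1, 2), NULL, NULL, G = 2), "psi0")
  expect_error(membership_probs(1, matrix(1:2, 1), c(1, 2, 3), G = 2), "psi")
})

test_that("linear predictor and its declared slope behave linearly", {
  beta <- c(8.03, -0.16, -5.86)
  expect_equal(linear_predictor(beta, c(0, 0), c(1, 0, 1), c(1, 0)), 2.17)
  # adding b = (1, 0) shifts mu by exactly 1 at any t
  des <- linear_design(male = 1)
  for (t in c(0, 1.3, 7, 14)) {
    m0 <- linear_predictor(beta, c(0, 0), des$fx(t)[1, ], des$fz(t)[1, ])
    m1 <- linear_predictor(beta, c(1, 0), des$fx(t)[1, ], des$fz(t)[1, ])
    expect_equal(m1 - m0, 1)
    # slope of an intercept-slope design is beta_1 + b_1 at all t
    s <- linear_predictor_slope(beta, c(1, 0.5), des$fxs(t)[1, ], des$fzs(t)[1, ])
    expect_equal(s, beta[2] + 0.5)
  }
  expect_error(linear_predictor(beta, c(0, 0), c(1, 0), c(1, 0)),
               "inconsistent")
  expect_error(linear_predictor_slope(beta, c(0, 0), NULL, NULL),
               "declared")
})

test_that("Gaussian longitudinal log-likelihood matches a direct density product", {
  cp <- demo_params()
  # one observation at its mean with unit variance
  cp1 <- class_params(beta = 0, sigma2 = 1, Sigma_diag = 1, phi0 = 1, phi1 = 0)
  expect_equal(longitudinal_loglik(0, matrix(1), matrix(0), cp1, 0),
               -0.5 * log(2 * pi))
  # n_i = 5 block against the brute-force product of normal densities
  set.seed(7)
  tt <- c(0, 1, 3, 5, 8)
  X <- cbind(1, tt, 1); Z <- cbind(1, tt)
  b <- c(0.4, -0.1)
  y <- rnorm(5, 2, 3)
  mu <- drop(X %*% cp$beta + Z %*% b)
  oracle <- log(prod(dnorm(y, mu, sqrt(cp$sigma2))))
  expect_equal(longitudinal_loglik(y, X, Z, cp, b), oracle, tolerance = 1e-12)
  # additivity across observations
  one_by_one <- sum(vapply(1:5, function(j)
    longitudinal_loglik(y[j], X[j, , drop = FALSE], Z[j, , drop = FALSE],
                        cp, b), numeric(1)))
  expect_equal(longitudinal_loglik(y, X, Z, cp, b), one_by_one)
  expect_error(longitudinal_loglik(c(1, NA), X[1:2, ], Z[1:2, ], cp, b),
               "non-finite")
})

test_that("hazard combines Weibull baseline, risk covariates and association", {
  des <- linear_design(male = 1)
  cp_exp <- class_params(beta = c(0, 0, 0), sigma2 = 1, Sigma_diag = c(1, 1),
                         phi0 = 1, phi1 = -1.2, alpha = 0, gamma = numeric(0))
  # phi0 = 1, alpha = 0 -> constant hazard exp(phi1)
  expect_equal(hazard(c(0.5, 3, 10), cp_exp, c(0, 0), numeric(0), des),
               rep(exp(-1.2), 3))
  # association "none": hazard free of the random effects
  cp <- demo_params()
  h1 <- hazard(2, cp, c(5, 5), -0.02 * 0 + 50, des, association = "none")
  h2 <- hazard(2, cp, c(-5, -5), 50, des, association = "none")
  expect_equal(h1, h2)
  # log-hazard difference between alpha = 0.38 and alpha = 0 is 0.38 mu(t)
  cp0 <- demo_params(alpha = 0)
  t <- 4.5
  mu <- linear_predictor(cp$beta, c(0.3, 0.1), des$fx(t)[1, ], des$fz(t)[1, ])
  expect_equal(log(hazard(t, cp, c(0.3, 0.1), 50, des)) -
                 log(hazard(t, cp0, c(0.3, 0.1), 50, des)),
               0.38 * mu, tolerance = 1e-12)
  expect_error(hazard(0, cp, c(0, 0), 50, des), "t <= 0")
})

test_that("Gauss-Legendre cumulative hazard matches closed forms and adaptive quadrature", {
  des <- linear_design(male = 0)
  # alpha = 0: closed form exp(phi1) T^phi0
  for (phi0 in c(1, 1.5, 2.2, 3)) {
    for (Tt in c(0.1, 1, 5, 17.5)) {
      cp <- class_params(beta = c(0, 0, 0), sigma2 = 1, Sigma_diag = c(1, 1),
                         phi0 = phi0, phi1 = -2, alpha = 0)
      H <- cumulative_hazard(Tt, cp, c(0, 0), numeric(0), des)
      expect_equal(H, exp(-2) * Tt^phi0, tolerance = 1e-4)
    }
  }
  expect_equal(cumulative_hazard(0, demo_params(), c(0, 0), 50, des), 0)
  # alpha != 0 with a linear mean: adaptive-quadrature oracle
  cp <- demo_params()
  b <- c(0.5, -0.2)
  oracle <- stats::integrate(function(s) hazard(s, cp, b, 50, des),
                             0, 6, rel.tol = 1e-10)$value
  H <- cumulative_hazard(6, cp, b, 50, des)
  expect_equal(H, oracle, tolerance = 1e-4)
  # the rule converges: a higher configurable order reaches 1e-6
  H30 <- cumulative_hazard(6, cp, b, 50, des, n_quad = 30)
  expect_equal(H30, oracle, tolerance = 1e-6)
  # nondecreasing in T
  Ts <- seq(0, 12, length.out = 25)
  Hs <- vapply(Ts, function(Tt) cumulative_hazard(Tt, cp, b, 50, des),
               numeric(1))
  expect_true(all(diff(Hs) >= 0))
  expect_equal(Hs[1], 0)
})

test_that("survival log-likelihood is delta log h(T) - H(T)", {
  des <- linear_design(male = 1)
  cp <- demo_params()
  b <- c(0.2, 0.05); Wt <- 47
  H <- cumulative_hazard(3.5, cp, b, Wt, des)
  expect_equal(survival_loglik(3.5, 0, cp, b, Wt, des), -H)
  expect_equal(survival_loglik(3.5, 1, cp, b, Wt, des),
               log(hazard(3.5, cp, b, Wt, des)) - H)
  # numerically integrated oracle on a random configuration
  set.seed(11)
  cp2 <- class_params(beta = rnorm(3), sigma2 = 0.5, Sigma_diag = c(0.5, 0.1),
                      phi0 = runif(1, 0.8, 2.5), phi1 = rnorm(1, -2),
                      gamma = rnorm(1, 0, 0.1), alpha = rnorm(1, 0, 0.3))
  b2 <- rnorm(2, 0, 0.5)
  Hor <- stats::integrate(function(s) hazard(s, cp2, b2, 50, des), 0, 2.7,
                          rel.tol = 1e-10)$value
  expect_equal(survival_loglik(2.7, 1, cp2, b2, 50, des),
               log(hazard(2.7, cp2, b2, 50, des)) - Hor, tolerance = 1e-6)
  expect_error(survival_loglik(0, 1, cp, b, Wt, des), "time 0")
})

test_that("class-marginalized subject likelihood reduces and mixes correctly", {
  sim <- tiny_sim(n = 15, seed = 5, scenario = "setting2_scenario1")
  # G = 1: marginal equals the single-class complete-data log-likelihood
  spec1 <- scenario_spec(G = 1, membership_model = 1)
  d1 <- list(classes = list(demo_params()), psi0 = numeric(0),
             psi = matrix(0, 0, 0),
             b = array(rnorm(15 * 2, 0, 0.2), c(15, 2, 1)))
  for (i in c(1, 7, 15)) {
    lw <- bjlcm:::subject_class_logliks(i, d1, sim$data, spec1)
    expect_length(lw, 1)
    expect_equal(subject_marginal_loglik(i, d1, sim$data, spec1), lw[1])
  }
  # duplicating a class at half weight leaves the marginal unchanged
  spec2 <- scenario_spec(G = 2, membership_model = 1)
  d2 <- list(classes = list(demo_params(), demo_params()), psi0 = 0,
             psi = matrix(0, 1, 0),
             b = array(rep(d1$b, 2), c(15, 2, 2)))
  for (i in c(2, 9)) {
    expect_equal(subject_marginal_loglik(i, d2, sim$data, spec2),
                 subject_marginal_loglik(i, d1, sim$data, spec1),
                 tolerance = 1e-12)
  }
})

test_that("marginal likelihood equals the naive mixture sum when it is safe", {
  # moderate magnitudes: direct sum of exponentials cannot underflow
  sim <- tiny_sim(n = 10, seed = 9, scenario = "setting2_scenario1")
  spec3 <- jlcm_spec(G = 3, fixed = y ~ time + male, random = ~ time,
                     survival = ~ age, association = "current_value")
  set.seed(2)
  classes <- replicate(3, {
    cp <- demo_params()
    cp$beta <- cp$beta + rnorm(3, 0, 0.5)
    cp
  }, simplify = FALSE)
  d3 <- list(classes = classes, psi0 = rnorm(2, 0, 0.3),
             psi = matrix(0, 2, 0),
             b = array(rnorm(10 * 2 * 3, 0, 0.2), c(10, 2, 3)))
  for (i in c(1, 4, 10)) {
    lw <- bjlcm:::subject_class_logliks(i, d3, sim$data, spec3)
    scale <- max(lw)
    naive <- scale + log(sum(exp(lw - scale)))
    expect_equal(subject_marginal_loglik(i, d3, sim$data, spec3), naive,
                 tolerance = 1e-12)
  }
})

test_that("joint log posterior: R and compiled paths agree, order-invariant", {
  sim <- tiny_sim(n = 12, seed = 13)
  spec <- scenario_spec(G = 2, membership_model = 2)
  priors <- jlcm_priors()
  md <- bjlcm:::prepare_model_data(sim$data, spec, priors, "non_centered")
  dd <- bjlcm:::md_dims(md)
  set.seed(4)
  par <- rnorm(dd$n_par, 0, 0.3)
  cpp <- bjlcm:::jlcm_lp_grad_cpp(par, md, FALSE)
  draw <- bjlcm:::unpack_draw(par, md)
  expect_equal(joint_logpost(draw, sim$data, spec, priors), cpp$lp_joint,
               tolerance = 1e-9)
  # permuting subjects (by relabelling ids) leaves the log posterior unchanged
  perm <- sample(nrow(sim$data$surv))
  id_map <- stats::setNames(perm, sim$data$surv$id)
  long2 <- sim$data$long; long2$id <- id_map[as.character(long2$id)]
  surv2 <- sim$data$surv; surv2$id <- id_map[as.character(surv2$id)]
  data2 <- jlcm_data(long2, surv2)
  inv <- match(seq_along(perm), perm)   # new position -> old subject
  draw2 <- draw
  draw2$b <- draw$b[inv, , , drop = FALSE]
  expect_equal(joint_logpost(draw2, data2, spec, priors),
               joint_logpost(draw, sim$data, spec, priors), tolerance = 1e-9)
  # centered and non-centered parameterizations give the same natural joint
  mdc <- bjlcm:::prepare_model_data(sim$data, spec, priors, "centered")
  parc <- bjlcm:::pack_draw(draw, mdc)
  cppc <- bjlcm:::jlcm_lp_grad_cpp(parc, mdc, FALSE)
  expect_equal(cppc$lp_joint, cpp$lp_joint, tolerance = 1e-9)
})

test_that("per-class compiled log weights match the R reference", {
  sim <- tiny_sim(n = 8, seed = 17)
  spec <- scenario_spec(G = 2, membership_model = 2)
  md <- bjlcm:::prepare_model_data(sim$data, spec, jlcm_priors())
  dd <- bjlcm:::md_dims(md)
  set.seed(5)
  par <- rnorm(dd$n_par, 0, 0.3)
  draw <- bjlcm:::unpack_draw(par, md)
  lw <- bjlcm:::jlcm_class_logweights_cpp(par, md)
  for (i in seq_len(8)) {
    expect_equal(lw[i, ],
                 bjlcm:::subject_class_logliks_md(i, draw, md, spec),
                 tolerance = 1e-9)
  }
})

test_that("current-slope association uses the declared derivative designs", {
  sim <- tiny_sim(n = 10, seed = 19, scenario = "setting2_scenario1")
  spec_s <- jlcm_spec(G = 2, fixed = y ~ time + male, random = ~ time,
                      survival = ~ age, association = "current_slope",
                      fixed_slope = ~ 0 + I(0 * time) + I(1 + 0 * time) +
                        I(0 * male),
                      random_slope = ~ 0 + I(0 * time) + I(1 + 0 * time))
  priors <- jlcm_priors()
  md <- bjlcm:::prepare_model_data(sim$data, spec_s, priors)
  dd <- bjlcm:::md_dims(md)
  set.seed(21)
  par <- rnorm(dd$n_par, 0, 0.3)
  cpp <- bjlcm:::jlcm_lp_grad_cpp(par, md, TRUE)
  # compiled path agrees with the R reference under the slope association
  draw <- bjlcm:::unpack_draw(par, md)
  expect_equal(joint_logpost(draw, sim$data, spec_s, priors), cpp$lp_joint,
               tolerance = 1e-9)
  # and its gradient with numerical differentiation
  f <- function(p) bjlcm:::jlcm_lp_grad_cpp(p, md, FALSE)$lp
  nd <- numDeriv::grad(f, par)
  expect_lt(sqrt(sum((cpp$grad - nd)^2)) / sqrt(sum(nd^2)), 1e-6)
  # the hazard now responds to the slope, not the level, of the mean
  des <- linear_design(male = 1)
  cp <- demo_params()
  h_flat <- hazard(3, cp, c(5, 0), 50, des, association = "current_slope")
  h_flat2 <- hazard(3, cp, c(-5, 0), 50, des, association = "current_slope")
  expect_equal(h_flat, h_flat2)   # intercept shift is invisible
  h_up <- hazard(3, cp, c(0, 1), 50, des, association = "current_slope")
  expect_equal(log(h_up) - log(h_flat), cp$alpha * 1 - cp$alpha * 0 +
                 cp$alpha * 5 * 0, tolerance = 1e-12)
  # requesting the slope without declared derivatives fails at spec time
  expect_error(jlcm_spec(G = 2, fixed = y ~ time, random = ~ time,
                         association = "current_slope"),
               "declared")
})
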