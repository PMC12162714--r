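# generators for the heterogeneous-population study designs

test_that("baseline covariates follow their laws and are reproducible", {
  n <- 1e5
  cov <- simulate_covariates(n, seed = 1)
  expect_lt(abs(mean(cov$male) - 0.5), 3 * sqrt(0.25 / n))
  expect_lt(abs(mean(cov$age) - 45), 3 * 15.70 / sqrt(n))
  expect_lt(abs(sd(cov$age) - 15.70), 3 * 15.70 / sqrt(2 * n))
  expect_lt(abs(mean(cov$xtilde)), 3 / sqrt(n))
  expect_identical(cov, simulate_covariates(n, seed = 1))
})

test_that("class assignment follows the softmax scenarios", {
  des1 <- sim_design(n = 500, membership = list(type = "fixed_proportions",
                                                proportions = c(1, 0)))
  cov <- simulate_covariates(500, seed = 2)
  expect_true(all(assign_classes(des1, cov, seed = 3) == 1L))
  # scenario 2: P(class 1) = E[logistic(-0.4 + x)], x ~ N(0, 1)
  p1 <- stats::integrate(function(x) plogis(-0.4 + x) * dnorm(x),
                         -10, 10, rel.tol = 1e-10)$value
  expect_gt(p1, 0.40); expect_lt(p1, 0.43)   # the averaging pulls toward 1/2
  n <- 1e5
  des2 <- sim_design("setting2_scenario2", n = n)
  cov2 <- simulate_covariates(n, seed = 4)
  lab2 <- assign_classes(des2, cov2, seed = 5)
  expect_lt(abs(mean(lab2 == 1L) - p1), 3 * sqrt(p1 * (1 - p1) / n))
  # scenario 3 depends on male and age but not on xtilde
  des3 <- sim_design("setting2_scenario3", n = 2e4)
  cov3 <- simulate_covariates(2e4, seed = 6)
  lab3 <- assign_classes(des3, cov3, seed = 7)
  fit <- glm(I(lab3 == 1L) ~ male + age + xtilde, binomial(), data = cov3)
  zs <- summary(fit)$coefficients[, "z value"]
  expect_gt(abs(zs["male"]), 5)
  expect_gt(abs(zs["age"]), 5)
  expect_lt(abs(zs["xtilde"]), 3)
})

test_that("longitudinal trajectories decompose into trend, effects and noise", {
  cov <- simulate_covariates(400, seed = 8)
  truths <- table2_truths()
  # noise off: exact linear trajectories
  t0 <- lapply(truths, function(cp) {
    cp$sigma2 <- 1e-24; cp$Sigma_diag <- c(1e-24, 1e-24); cp
  })
  lab <- rep(1:2, 200)
  lng0 <- simulate_longitudinal(lab, cov, t0, visit_times = 0:5, seed = 9)
  for (i in c(1, 2)) {
    cp <- truths[[lab[i]]]
    rows <- lng0$long[lng0$long$id == cov$id[i], ]
    expect_equal(rows$y,
                 cp$beta[1] + cp$beta[2] * rows$time + cp$beta[3] * cov$male[i],
                 tolerance = 1e-8)
  }
  # variance of y at t = 0 in class 1 is Sigma_11 + sigma2
  n <- 1e4
  cov2 <- simulate_covariates(n, seed = 10)
  lab2 <- rep(1L, n)
  lng <- simulate_longitudinal(lab2, cov2, truths, visit_times = 0, seed = 11)
  v <- var(lng$long$y - truths[[1]]$beta[3] * cov2$male)
  v_true <- 0.87 + 0.4761
  expect_lt(abs(v - v_true), 3 * v_true * sqrt(2 / n))
  # class-wise regression recovers the fixed effects
  lng2 <- simulate_longitudinal(lab2, cov2, truths, visit_times = 0:6,
                                seed = 12)
  df <- merge(lng2$long, cov2, by = "id")
  fit <- lm(y ~ time + male, df)
  se <- summary(fit)$coefficients[, 2]
  # per-subject random effects induce correlation; OLS SEs understate, allow 6x
  expect_lt(max(abs(coef(fit) - truths[[1]]$beta) / (6 * se + 0.02)), 3)
})

test_that("event times invert the cumulative hazard", {
  truths0 <- lapply(table2_truths(), function(cp) { cp$alpha <- 0; cp })
  n <- 5000
  cov <- simulate_covariates(n, seed = 13)
  lab <- rep(1L, n)
  b <- matrix(0, n, 2)
  ev <- simulate_event_times(lab, cov, b, truths0, censor_bound = 17.5,
                             seed = 14)
  # alpha = 0: compare with the closed-form Weibull PH inverse-CDF sampler
  cp <- truths0[[1]]
  set.seed(15)
  u <- runif(n)
  closed <- (-log(u) / exp(cp$phi1 + cp$gamma[1] * cov$age))^(1 / cp$phi0)
  ks <- suppressWarnings(stats::ks.test(ev$T_star[is.finite(ev$T_star)],
                                        closed[is.finite(closed)]))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(ev$surv$time <= 17.5))
  # exponential case: doubling exp(phi1) halves the median latent time
  # (a rate giving event times well inside the root-finding horizon)
  cp_exp <- cp; cp_exp$phi0 <- 1; cp_exp$phi1 <- -2
  cp_exp2 <- cp_exp; cp_exp2$phi1 <- cp_exp$phi1 + log(2)
  e1 <- simulate_event_times(lab, cov, b, list(cp_exp), 17.5, seed = 16)
  e2 <- simulate_event_times(lab, cov, b, list(cp_exp2), 17.5, seed = 16)
  m1 <- median(e1$T_star[is.finite(e1$T_star)])
  m2 <- median(e2$T_star[is.finite(e2$T_star)])
  expect_equal(m1 / m2, 2, tolerance = 0.15)
})

test_that("assembled datasets are reproducible with sane censoring", {
  des <- sim_design("setting2_scenario3", n = 400, seed = 17)
  a <- simulate_dataset(des)
  b <- simulate_dataset(des)
  expect_identical(a$data$long, b$data$long)
  expect_identical(a$data$surv, b$data$surv)
  cens <- 1 - mean(a$data$surv$event)
  expect_gt(cens, 0.2); expect_lt(cens, 0.8)
  # scenario 1 proportions: binomial around n/2
  des1 <- sim_design("setting2_scenario1", n = 900, seed = 18)
  s1 <- simulate_dataset(des1)
  n1 <- sum(s1$truth$labels == 1L)
  expect_lt(abs(n1 - 450), 3 * sqrt(900 * 0.25))
  # visits never exceed the observed time
  Tmap <- setNames(a$data$surv$time, a$data$surv$id)
  expect_true(all(a$data$long$time <= Tmap[as.character(a$data$long$id)] + 1e-9))
})

test_that("datasets round-trip through the CSV interface exactly", {
  sim <- tiny_sim(n = 25, seed = 19)
  lf <- tempfile(fileext = ".csv"); sf <- tempfile(fileext = ".csv")
  write_joint_dataset(sim$data, lf, sf)
  back <- read_joint_dataset(lf, sf)
  expect_equal(back$long$y, sim$data$long$y)
  expect_equal(back$surv, sim$data$surv, tolerance = 1e-12)
  unlink(c(lf, sf))
})
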