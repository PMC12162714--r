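# pointwise likelihood, WAIC/PSIS-LOO, z-score comparison, forward selection

test_that("pointwise log-likelihood matches the subject marginal per draw", {
  sim <- tiny_sim(n = 10, seed = 79)
  spec <- scenario_spec(G = 2, membership_model = 2)
  cfg <- jlcm_chains(M = 1, iter = 120, warmup = 60, thin = 1, base_seed = 23,
                     rhat_threshold = Inf)
  ch <- quiet_chain(cfg, spec, jlcm_priors(), sim$data, 1)
  ll <- pointwise_loglik(ch)
  expect_equal(dim(ll), c(10, 60))
  for (s in c(1, 30)) {
    draw <- bjlcm:::chain_draw(ch, s)
    for (i in c(2, 10)) {
      expect_equal(ll[i, s],
                   subject_marginal_loglik(i, draw, sim$data, spec),
                   tolerance = 1e-10)
    }
  }
  # column sums recompute the total marginal log-likelihood per draw
  tot <- vapply(1:60, function(s) {
    draw <- bjlcm:::chain_draw(ch, s)
    sum(vapply(1:10, function(i)
      subject_marginal_loglik(i, draw, sim$data, spec), numeric(1)))
  }, numeric(1))
  expect_equal(colSums(ll), tot, tolerance = 1e-8)
})

test_that("constant likelihood matrices give degenerate WAIC = LOOIC", {
  m <- matrix(-1.7, nrow = 12, ncol = 50)
  w <- compute_waic(m)
  l <- compute_looic(m)
  expect_equal(w$elpd, 12 * -1.7)
  expect_equal(w$p_eff, 0)
  expect_equal(w$ic, -2 * 12 * -1.7)
  expect_equal(l$ic, w$ic)
  expect_equal(l$se, 0)
})

test_that("p_WAIC is nonnegative on random matrices", {
  set.seed(10)
  for (k in 1:5) {
    m <- matrix(rnorm(40 * 30, -2, abs(rnorm(1))), 40, 30)
    expect_gte(compute_waic(m)$p_eff, 0)
  }
})

test_that("WAIC and PSIS-LOO agree on a well-specified iid model", {
  set.seed(11)
  n <- 600; S <- 500
  y <- rnorm(n, 0.3, 1)
  # posterior of the mean under a flat-ish prior
  th <- rnorm(S, mean(y), 1 / sqrt(n))
  ll <- vapply(th, function(t) dnorm(y, t, 1, log = TRUE), numeric(n))
  w <- compute_waic(ll); l <- compute_looic(ll)
  expect_lt(abs(w$elpd - l$elpd), 2 * sqrt(w$se^2 + l$se^2) / 10 + 0.5)
  expect_lt(max(l$pareto_k), 0.7)
})

test_that("PSIS-LOO matches exact leave-one-out refits on a conjugate model", {
  set.seed(12)
  n <- 8; S <- 4000
  y <- rnorm(n, 1, 1); tau2 <- 4
  v <- 1 / (n + 1 / tau2); m <- v * sum(y)
  th <- rnorm(S, m, sqrt(v))
  ll <- vapply(th, function(t) dnorm(y, t, 1, log = TRUE), numeric(n))
  loo <- compute_looic(ll)
  exact <- vapply(seq_len(n), function(i) {
    vi <- 1 / ((n - 1) + 1 / tau2); mi <- vi * sum(y[-i])
    dnorm(y[i], mi, sqrt(vi + 1), log = TRUE)
  }, numeric(1))
  expect_lt(abs(loo$elpd - sum(exact)), 2 * loo$se)
  expect_lt(abs(loo$elpd - sum(exact)), 0.2)
})

test_that("model comparison z-scores follow the documented conventions", {
  pw <- rnorm(50, -2, 0.5)
  a <- bjlcm:::new_ic_result("looic", pw, se = sqrt(50) * sd(pw), p_eff = 1)
  same <- compare_models(a, a)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 0.5)
  # one-tailed p at the 0.1% critical value
  expect_lt(abs(stats::pnorm(3.09, lower.tail = FALSE) - 0.001), 1e-5)
  # improvement (lower deviance IC for b) gives z > 0
  b <- bjlcm:::new_ic_result("looic", pw + 0.3, se = sqrt(50) * sd(pw),
                             p_eff = 1)
  cmp <- compare_models(a, b)
  expect_gt(cmp$z, 0)
  expect_lt(cmp$delta_ic, 0)
  bad <- bjlcm:::new_ic_result("looic", rnorm(10), se = 1, p_eff = 1)
  expect_error(compare_models(a, bad), "length")
})

# engineered pointwise vectors with a target z-score for the difference
mk_candidate <- function(G, g_eff, base, z = NULL, n = 499, seed = 1) {
  set.seed(seed)
  if (is.null(z)) pw <- base else {
    d <- rnorm(n, 0, 0.4)
    d <- d - mean(d) + z * sd(d) / sqrt(n)  # sum difference = z * SE exactly
    pw <- base + d
  }
  list(G = G, ic = bjlcm:::new_ic_result("looic", pw,
                                         se = sqrt(n) * sd(pw), p_eff = 1),
       g_eff = g_eff, pw = pw)
}

test_that("forward selection is parsimonious and respects both conditions", {
  base <- rnorm(499, -40, 3)
  # all candidates indistinguishable -> stay at G = 1
  cands <- list(mk_candidate(1, 1, base),
                mk_candidate(2, 2, base, z = 0.3, seed = 2),
                mk_candidate(3, 3, base, z = 0.1, seed = 3))
  sel <- forward_select(cands, alpha = 0.001)
  expect_equal(sel$G, 1)
  expect_true(all(!sel$trail$adopted))
  # significantly better IC but no extra effective class -> rejected
  c2 <- list(mk_candidate(1, 1, base),
             mk_candidate(2, 1, base, z = 8, seed = 4))
  expect_equal(forward_select(c2, alpha = 0.001)$G, 1)
  expect_false(forward_select(c2, alpha = 0.001)$trail$adopted[1])
})

test_that("forward selection reproduces the cohort-style G choice", {
  # strong 1->2 improvement, borderline 2->3 adoption, 4 adds no signal
  base <- rnorm(499, -41, 2.5)
  c1 <- mk_candidate(1, 1, base, seed = 5)
  c2 <- mk_candidate(2, 2, c1$pw, z = 12, seed = 6)
  c3 <- mk_candidate(3, 3, c2$pw, z = 3.19, seed = 7)
  c4 <- mk_candidate(4, 3, c3$pw, z = 0.63, seed = 8)
  sel <- forward_select(list(c1, c2, c3, c4), alpha = 0.001)
  expect_equal(sel$G, 3)
  expect_equal(sel$trail$adopted, c(TRUE, TRUE, FALSE))
  # invariant to the order in which candidates are supplied
  sel2 <- forward_select(list(c4, c2, c1, c3), alpha = 0.001)
  expect_equal(sel2$G, 3)
  expect_equal(sel2$trail, sel$trail)
  expect_error(forward_select(list(c1, c3)), "consecutive")
})
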