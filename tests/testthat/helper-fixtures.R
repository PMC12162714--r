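# shared fixtures: all built in code at test time

# design-of-time functions for one subject of the benchmark design:
# fixed (1, t, male), random (1, t), with declared time derivatives
linear_design <- function(male = 1) {
  list(fx = function(t) cbind(1, t, rep(male, length(t))),
       fz = function(t) cbind(1, t),
       fxs = function(t) cbind(0, rep(1, length(t)), 0),
       fzs = function(t) cbind(0, rep(1, length(t))))
}

demo_params <- function(alpha = 0.38) {
  class_params(beta = c(8.03, -0.16, -5.86), sigma2 = 0.4761,
               Sigma_diag = c(0.87, 0.02), phi0 = 1.8, phi1 = -4.85,
               gamma = -0.02, alpha = alpha)
}

tiny_sim <- function(n = 20, seed = 3, scenario = "setting2_scenario3") {
  simulate_dataset(sim_design(scenario, n = n, seed = seed))
}

# a natural-scale draw with all random effects zero (or supplied)
make_draw <- function(classes, n, psi0 = numeric(length(classes) - 1),
                      psi = NULL, b = NULL) {
  G <- length(classes)
  r <- length(classes[[1]]$Sigma_diag)
  if (is.null(b)) b <- array(0, dim = c(n, r, G))
  if (is.null(psi)) psi <- matrix(0, max(G - 1, 0), 0)
  list(classes = classes, psi0 = psi0, psi = psi, b = b)
}

# draw from the generating truth of a simulated dataset (true b in the
# subject's own class slot, zeros elsewhere)
truth_draw <- function(sim, membership_psi = NULL) {
  n <- n_subjects(sim$data)
  G <- sim$design$G
  b <- array(0, dim = c(n, 2, G))
  for (i in seq_len(n)) b[i, , sim$truth$labels[i]] <- sim$truth$b[i, ]
  m <- sim$design$membership
  if (m$type == "softmax" && !is.null(membership_psi)) {
    psi0 <- m$psi0
    psi <- matrix(m$psi, nrow = G - 1, byrow = TRUE)
  } else {
    psi0 <- numeric(G - 1)
    psi <- matrix(0, G - 1, 0)
  }
  list(classes = sim$design$truths, psi0 = psi0, psi = psi, b = b)
}

quiet_chain <- function(...) suppressWarnings(run_chain(...))
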