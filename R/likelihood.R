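#' Class-specific parameter set
#'
#' Bundles the parameters of one latent class: the fixed effects and
#' residual variance of the linear mixed longitudinal submodel, the diagonal
#' random-effect variances, the Weibull baseline-hazard parameters, the risk
#' coefficients and the association strength.
#'
#' @param beta fixed-effect vector.
#' @param sigma2 residual variance (> 0).
#' @param Sigma_diag positive random-effect variances (diagonal of the
#'   class covariance matrix).
#' @param phi0 Weibull shape (> 0).
#' @param phi1 log-scale intercept of the baseline hazard.
#' @param gamma risk-coefficient vector (may be empty).
#' @param alpha association strength.
#' @return a list of class `class_params`.
#' @export
class_params <- function(beta, sigma2, Sigma_diag, phi0, phi1,
                         gamma = numeric(0), alpha = 0) {
  if (!is.finite(sigma2) || sigma2 <= 0) stop("`sigma2` must be > 0")
  if (any(!is.finite(Sigma_diag)) || any(Sigma_diag <= 0))
    stop("`Sigma_diag` entries must be > 0")
  if (!is.finite(phi0) || phi0 <= 0) stop("`phi0` must be > 0")
  structure(list(beta = as.numeric(beta), sigma2 = sigma2,
                 Sigma_diag = as.numeric(Sigma_diag), phi0 = phi0,
                 phi1 = phi1, gamma = as.numeric(gamma),
                 alpha = alpha),
            class = "class_params")
}

#' Softmax class membership probabilities
#'
#' Computes the membership probability vector of one subject under the
#' multinomial-logit membership submodel, with the last class as the
#' zero-coefficient reference. Evaluated with max-subtraction so that large
#' linear predictors cannot overflow.
#'
#' @param psi0 intercepts for classes `1..G-1`.
#' @param psi coefficient matrix `(G-1) x p` (or `NULL` when `p = 0`).
#' @param W subject covariate vector of length `p` (or `NULL`).
#' @param G number of classes.
#' @return probability vector of length `G` summing to one.
#' @export
membership_probs <- function(psi0, psi = NULL, W = NULL, G) {
  if (G == 1L) return(1)
  if (length(psi0) != G - 1L)
    stop("`psi0` must have length G - 1 = ", G - 1L)
  p <- if (is.null(W)) 0L else length(W)
  eta <- psi0
  if (p > 0L) {
    psi <- rbind(psi)
    if (ncol(psi) != p || nrow(psi) != G - 1L)
      stop("`psi` must be a (G-1) x length(W) matrix; got ",
           nrow(psi), " x ", ncol(psi), " for W of length ", p)
    eta <- psi0 + drop(psi %*% W)
  } else if (!is.null(psi) && length(psi)) {
    stop("`psi` coefficients supplied but membership covariates `W` are empty")
  }
  eta <- c(eta, 0)
  eta <- eta - max(eta)
  exp(eta) / sum(exp(eta))
}

#' Linear predictor of the longitudinal mean
#'
#' The subject- and class-specific mean `mu(t) = x(t)' beta + z(t)' b`.
#' `linear_predictor_slope` evaluates its time derivative from *declared*
#' derivative design rows.
#'
#' @param beta fixed-effect vector.
#' @param b random-effect vector.
#' @param x_row,z_row fixed/random design rows at the time of interest.
#' @return scalar mean (or slope) value.
#' @export
linear_predictor <- function(beta, b, x_row, z_row) {
  if (length(x_row) != length(beta) || length(z_row) != length(b))
    stop("design rows inconsistent with coefficient lengths")
  sum(x_row * beta) + sum(z_row * b)
}

#' @rdname linear_predictor
#' @param xs_row,zs_row declared time-derivative design rows.
#' @export
linear_predictor_slope <- function(beta, b, xs_row, zs_row) {
  if (is.null(xs_row) || is.null(zs_row))
    stop("slope requested for a design without a declared time derivative")
  linear_predictor(beta, b, xs_row, zs_row)
}

#' Gaussian longitudinal log-likelihood of one subject under one class
#'
#' @param y response vector.
#' @param X,Z fixed/random design matrices (one row per visit).
#' @param params a [class_params()] object.
#' @param b random-effect vector for this subject and class.
#' @return scalar log-likelihood.
#' @export
longitudinal_loglik <- function(y, X, Z, params, b) {
  if (any(!is.finite(y))) stop("non-finite longitudinal responses")
  mu <- drop(X %*% params$beta) + drop(Z %*% b)
  sum(stats::dnorm(y, mu, sqrt(params$sigma2), log = TRUE))
}

#' Class-specific hazard at time t
#'
#' Weibull baseline `phi0 * t^(phi0 - 1) * exp(phi1)` times
#' `exp(W' gamma + alpha * f(t))`, where `f` is the current value of the
#' longitudinal mean, its current slope, or absent.
#'
#' @param t evaluation time (> 0).
#' @param params a [class_params()] object.
#' @param b random-effect vector.
#' @param W_tilde exogenous risk covariates (may be empty).
#' @param design list of design functions of time as produced by the model
#'   specification: `fx(t)`, `fz(t)` and, for the slope association,
#'   `fxs(t)`, `fzs(t)`.
#' @param association `"current_value"`, `"current_slope"` or `"none"`.
#' @return hazard value(s), positive.
#' @export
hazard <- function(t, params, b, W_tilde = numeric(0), design,
                   association = "current_value") {
  if (any(t <= 0)) stop("hazard undefined at t <= 0")
  lh <- log(params$phi0) + (params$phi0 - 1) * log(t) + params$phi1 +
    sum(W_tilde * params$gamma)
  if (association == "current_value") {
    mu <- drop(design$fx(t) %*% params$beta) + drop(design$fz(t) %*% b)
    lh <- lh + params$alpha * mu
  } else if (association == "current_slope") {
    if (is.null(design$fxs) || is.null(design$fzs))
      stop("current_slope association requires declared slope designs")
    mus <- drop(design$fxs(t) %*% params$beta) + drop(design$fzs(t) %*% b)
    lh <- lh + params$alpha * mus
  }
  exp(lh)
}

#' Cumulative hazard by Gauss-Legendre quadrature
#'
#' Approximates `int_0^T h(s) ds` with an `n_quad`-point Gauss-Legendre rule
#' mapped onto `(0, T)`; the hazard is only evaluated at interior nodes, so
#' the integrable singularity of the Weibull baseline at 0 (when
#' `phi0 < 1`) is never touched.
#'
#' @inheritParams hazard
#' @param T upper limit (>= 0); returns 0 when `T = 0`.
#' @param n_quad quadrature order.
#' @return nonnegative scalar.
#' @export
cumulative_hazard <- function(T, params, b, W_tilde = numeric(0), design,
                              association = "current_value", n_quad = 15) {
  if (T < 0) stop("`T` must be >= 0")
  if (T == 0) return(0)
  gl <- gl_rule(n_quad)
  s <- T / 2 * (gl$x + 1)
  w <- T / 2 * gl$w
  sum(w * hazard(s, params, b, W_tilde, design, association))
}

#' Survival log-likelihood of one subject under one class
#'
#' `delta * log h(T) - H(T)`: the event/censoring contribution of the
#' Weibull proportional-hazards submodel.
#'
#' @inheritParams cumulative_hazard
#' @param Tobs observed time.
#' @param delta event indicator (0/1).
#' @return scalar log-likelihood.
#' @export
survival_loglik <- function(Tobs, delta, params, b, W_tilde = numeric(0),
                            design, association = "current_value",
                            n_quad = 15) {
  if (!delta %in% c(0, 1)) stop("`delta` must be 0 or 1")
  if (Tobs == 0 && delta == 1) stop("event at time 0 is not admissible")
  ll <- -cumulative_hazard(Tobs, params, b, W_tilde, design, association, n_quad)
  if (delta == 1)
    ll <- ll + log(hazard(Tobs, params, b, W_tilde, design, association))
  ll
}

# per-class complete-data log-likelihood pieces of subject i (internal;
# shared by the marginal likelihood, allocation weights and pointwise LOO)
subject_class_logliks <- function(i, draw, data, spec) {
  md <- attr(data, "mdata")
  if (is.null(md)) md <- prepare_model_data(data, spec)
  subject_class_logliks_md(i, draw, md, spec)
}

subject_class_logliks_md <- function(i, draw, md, spec) {
  G <- md$G
  rows <- md$sub_start[i] + seq_len(md$sub_len[i])
  pi_i <- membership_probs(draw$psi0,
                           if (md$pW > 0) draw$psi else NULL,
                           if (md$pW > 0) md$W[i, ] else NULL, G)
  out <- numeric(G)
  for (g in seq_len(G)) {
    cp <- draw$classes[[g]]
    b <- draw$b[i, , g]
    ll_long <- longitudinal_loglik(md$y[rows], md$X[rows, , drop = FALSE],
                                   md$Z[rows, , drop = FALSE], cp, b)
    ll_surv <- surv_loglik_md(i, cp, b, md)
    out[g] <- log(pi_i[g]) + ll_long + ll_surv
  }
  out
}

# survival log-likelihood straight off the precomputed quadrature designs
surv_loglik_md <- function(i, cp, b, md) {
  rows <- (i - 1L) * md$nq + seq_len(md$nq)
  lin <- cp$phi1 + if (md$q > 0) sum(md$Wt[i, ] * cp$gamma) else 0
  amu_q <- 0
  if (md$assoc == 1L) {
    amu_q <- cp$alpha * (drop(md$Xq[rows, , drop = FALSE] %*% cp$beta) +
                         drop(md$Zq[rows, , drop = FALSE] %*% b))
  } else if (md$assoc == 2L) {
    amu_q <- cp$alpha * (drop(md$Xqs[rows, , drop = FALSE] %*% cp$beta) +
                         drop(md$Zqs[rows, , drop = FALSE] %*% b))
  }
  H <- sum(md$wq[rows] * exp(log(cp$phi0) + (cp$phi0 - 1) * md$logsq[rows] +
                             lin + amu_q))
  ll <- -H
  if (md$delta[i] == 1L) {
    amu_T <- 0
    if (md$assoc == 1L) {
      amu_T <- cp$alpha * (sum(md$XT[i, ] * cp$beta) + sum(md$ZT[i, ] * b))
    } else if (md$assoc == 2L) {
      amu_T <- cp$alpha * (sum(md$XTs[i, ] * cp$beta) + sum(md$ZTs[i, ] * b))
    }
    ll <- ll + log(cp$phi0) + (cp$phi0 - 1) * md$logT[i] + lin + amu_T
  }
  ll
}

#' Class-marginalized log-likelihood of one subject
#'
#' `log sum_g pi_ig p(y_i | b_ig, g) p(T_i, Delta_i | b_ig, g)`, evaluated
#' by log-sum-exp.
#'
#' @param i subject index (position in the sorted dataset).
#' @param draw a parameter draw: list with `classes` (list of
#'   [class_params()]), `psi0`, `psi` and random-effect array
#'   `b` (`n x r x G`).
#' @param data a [jlcm_data()] object.
#' @param spec a [jlcm_spec()] object.
#' @return scalar log-likelihood.
#' @export
subject_marginal_loglik <- function(i, draw, data, spec) {
  lw <- subject_class_logliks(i, draw, data, spec)
  m <- max(lw)
  if (!is.finite(m)) stop("all mixture components underflowed for subject ", i)
  m + log(sum(exp(lw - m)))
}

#' Unnormalized joint log posterior (classes marginalized)
#'
#' The natural-scale log density targeted by the sampler: the sum over
#' subjects of the class-marginalized log-likelihood, the `N(0, Sigma_g)`
#' log-density of every random-effect vector, and the log prior of the
#' structural parameters.
#'
#' @inheritParams subject_marginal_loglik
#' @param priors a [jlcm_priors()] configuration.
#' @return scalar log density.
#' @export
joint_logpost <- function(draw, data, spec, priors = jlcm_priors()) {
  md <- attr(data, "mdata")
  if (is.null(md)) md <- prepare_model_data(data, spec, priors)
  n <- md$n
  ll <- sum(vapply(seq_len(n), function(i) {
    lw <- subject_class_logliks_md(i, draw, md, spec)
    m <- max(lw)
    m + log(sum(exp(lw - m)))
  }, numeric(1)))
  lb <- 0
  for (g in seq_len(md$G)) {
    Sg <- draw$classes[[g]]$Sigma_diag
    bg <- draw$b[, , g, drop = FALSE]
    lb <- lb + sum(stats::dnorm(sweep(matrix(bg, n, md$r), 2,
                                      sqrt(Sg), "/"), log = TRUE)) -
      n * sum(0.5 * log(Sg))
  }
  lt <- log_prior_theta(draw, priors, spec)
  total <- ll + lb + lt
  if (!is.finite(total))
    stop("non-finite joint log posterior (likelihood = ", signif(ll, 6),
         ", random effects = ", signif(lb, 6), ", prior = ", signif(lt, 6), ")")
  total
}
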