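#' Prior configuration
#'
#' Hyperparameters of the factorized joint prior. Defaults follow the
#' weakly-informative estimation settings used throughout the simulation
#' study: normal priors of scale 5 on fixed effects, risk coefficients, the
#' baseline log-scale intercept and the association strength; standard
#' normal priors on membership coefficients; `Gamma(2, 0.5)` on the Weibull
#' shape; half-Normal(0, 0.5^2) on residual variances; and, for `G > 1`,
#' the penalized `Gamma(alpha_b, alpha_b) x exp(-lambda / sqrt(sum))` joint
#' prior on each class's random-effect variances. When `G = 1` an
#' inverse-Gamma(0.01, 0.01) prior per variance is used instead, the common
#' weakly-informative choice for a standard joint model.
#'
#' `paquid_priors()` returns the more informative profile used for the
#' standardized cognitive-score case study (normal scale 2 for fixed
#' effects, 3 for the survival block, half-Normal scale 0.2).
#'
#' @param scale_beta normal scale for longitudinal fixed effects.
#' @param scale_surv normal scale for `gamma`, `phi1` and `alpha`.
#' @param scale_psi normal scale for membership coefficients.
#' @param shape_phi,rate_phi Gamma shape/rate for the Weibull shape `phi0`.
#' @param scale_sigma2 half-Normal scale for residual variances.
#' @param alpha_b shared shape = rate of the Gamma factors on random-effect
#'   variances.
#' @param lambda degeneracy-penalty strength (`>= 0`; 0 turns the penalty off).
#' @param ig_shape,ig_scale inverse-Gamma hyperparameters used when `G = 1`.
#' @return a list of class `jlcm_priors`.
#' @export
jlcm_priors <- function(scale_beta = 5, scale_surv = 5, scale_psi = 1,
                        shape_phi = 2, rate_phi = 0.5, scale_sigma2 = 0.5,
                        alpha_b = 1.5, lambda = 1,
                        ig_shape = 0.01, ig_scale = 0.01) {
  vals <- c(scale_beta, scale_surv, scale_psi, shape_phi, rate_phi,
            scale_sigma2, alpha_b, ig_shape, ig_scale)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all prior scales and shapes must be positive")
  if (lambda < 0) stop("`lambda` must be >= 0")
  structure(list(scale_beta = scale_beta, scale_surv = scale_surv,
                 scale_psi = scale_psi, shape_phi = shape_phi,
                 rate_phi = rate_phi, scale_sigma2 = scale_sigma2,
                 alpha_b = alpha_b, lambda = lambda,
                 ig_shape = ig_shape, ig_scale = ig_scale),
            class = "jlcm_priors")
}

#' @rdname jlcm_priors
#' @export
paquid_priors <- function() {
  jlcm_priors(scale_beta = 2, scale_surv = 3, scale_sigma2 = 0.2)
}

#' Penalized log prior for one class's random-effect variances
#'
#' `sum_k log Gamma(Sigma_kk | alpha_b, alpha_b) - lambda / sqrt(sum_k
#' Sigma_kk)`, up to the (omitted) normalizing constant of the penalty. The
#' Gamma factors anchor each variance in a plausible range; the penalty term
#' vanishes away from the origin and keeps the variances from jointly
#' collapsing, which in mixtures is associated with spurious tiny classes.
#'
#' @param Sigma_diag positive variance vector.
#' @param alpha_b Gamma shape = rate.
#' @param lambda penalty strength.
#' @return unnormalized log density.
#' @export
log_prior_sigma_g <- function(Sigma_diag, alpha_b = 1.5, lambda = 1) {
  if (any(!is.finite(Sigma_diag)) || any(Sigma_diag <= 0))
    stop("`Sigma_diag` entries must be positive")
  sum(stats::dgamma(Sigma_diag, shape = alpha_b, rate = alpha_b, log = TRUE)) -
    lambda / sqrt(sum(Sigma_diag))
}

#' Mode of the penalized random-effect variance prior
#'
#' Numerically maximizes the penalized prior. The maximizer lies on the
#' equal-diagonal line, so the returned vector has all entries equal.
#'
#' @param alpha_b Gamma shape = rate (> 1 so the Gamma factor has an
#'   interior mode).
#' @param lambda penalty strength.
#' @param r dimension.
#' @return `r`-vector, all entries equal within 1e-6.
#' @export
prior_mode_sigma <- function(alpha_b = 1.5, lambda = 1, r = 2) {
  if (alpha_b <= 1) stop("`alpha_b` must exceed 1 for an interior mode")
  neg <- function(lv) -log_prior_sigma_g(exp(lv), alpha_b, lambda) # no Jacobian: mode of the density itself
  opt <- stats::optim(rep(log((alpha_b - 1) / alpha_b), r), neg,
                      method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 500))
  if (opt$convergence != 0)
    stop("mode search did not converge (optim code ", opt$convergence, ")")
  x <- exp(opt$par)
  if (diff(range(x)) > 1e-6 * max(x))
    stop("mode search left the equal-diagonal line; spread = ",
         diff(range(x)))
  x
}

#' Joint log prior of all structural parameters
#'
#' Sum of the marginal log priors of every parameter in the draw under the
#' configured factorized prior; uses the penalized variance prior per class
#' when `G > 1` and the inverse-Gamma fallback when `G = 1`.
#'
#' @param draw a parameter draw (see [subject_marginal_loglik()]).
#' @param config a [jlcm_priors()] object.
#' @param spec a [jlcm_spec()] object (supplies `G` and the association type).
#' @return scalar log prior density (unnormalized in the `G > 1` variance
#'   factor).
#' @export
log_prior_theta <- function(draw, config, spec) {
  G <- spec$G
  lp <- 0
  for (g in seq_len(G)) {
    cp <- draw$classes[[g]]
    lp <- lp + sum(stats::dnorm(cp$beta, 0, config$scale_beta, log = TRUE))
    lp <- lp + log(2) + stats::dnorm(cp$sigma2, 0, config$scale_sigma2, log = TRUE)
    lp <- lp + stats::dgamma(cp$phi0, shape = config$shape_phi,
                             rate = config$rate_phi, log = TRUE)
    lp <- lp + stats::dnorm(cp$phi1, 0, config$scale_surv, log = TRUE)
    if (length(cp$gamma))
      lp <- lp + sum(stats::dnorm(cp$gamma, 0, config$scale_surv, log = TRUE))
    if (spec$association != "none")
      lp <- lp + stats::dnorm(cp$alpha, 0, config$scale_surv, log = TRUE)
    if (G > 1L) {
      lp <- lp + log_prior_sigma_g(cp$Sigma_diag, config$alpha_b, config$lambda)
    } else {
      lp <- lp + sum(config$ig_shape * log(config$ig_scale) -
                       lgamma(config$ig_shape) -
                       (config$ig_shape + 1) * log(cp$Sigma_diag) -
                       config$ig_scale / cp$Sigma_diag)
    }
  }
  if (G > 1L) {
    lp <- lp + sum(stats::dnorm(draw$psi0, 0, config$scale_psi, log = TRUE))
    if (length(draw$psi))
      lp <- lp + sum(stats::dnorm(draw$psi, 0, config$scale_psi, log = TRUE))
  }
  lp
}

#' Elicit the residual-variance prior scale from the data
#'
#' Fits a single-class linear mixed model to the longitudinal data alone
#' (the survival process has little bearing on the residual variance) and
#' returns its residual-variance estimate, to be used as the half-Normal
#' scale for `sigma2`.
#'
#' @param data a [jlcm_data()] object.
#' @param spec a [jlcm_spec()] object (designs are reused).
#' @return the residual-variance estimate (scalar).
#' @export
elicit_sigma_scale <- function(data, spec) {
  md <- prepare_model_data(data, spec_with_G(spec, 1L))
  # moment-based LMM fit: OLS residual variance after per-subject detrending
  fit <- stats::lm.fit(md$X, md$y)
  res <- fit$residuals
  # within-subject residual variance after removing subject random effects
  # by per-subject regression on Z
  pieces <- lapply(seq_len(md$n), function(i) {
    rows <- md$sub_start[i] + seq_len(md$sub_len[i])
    if (md$sub_len[i] <= md$r) return(NULL)
    zi <- md$Z[rows, , drop = FALSE]
    e <- stats::lm.fit(zi, res[rows])$residuals
    c(sum(e^2), length(e) - md$r)
  })
  pieces <- do.call(rbind, pieces)
  if (is.null(pieces) || sum(pieces[, 2]) < 10) return(stats::var(res))
  sum(pieces[, 1]) / sum(pieces[, 2])
}

spec_with_G <- function(spec, G) { spec$G <- as.integer(G); spec }
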