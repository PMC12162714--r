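#' Chain configuration
#'
#' Settings for the parallel-chain sampling scheme. Defaults are the
#' estimation settings used throughout the simulation study: 6 independently
#' initialized chains of 6000 iterations with the first half discarded and
#' the rest thinned by 3, a non-centered random-effect parameterization and
#' a target acceptance rate of 0.8.
#'
#' @param M number of chains.
#' @param iter iterations per chain (including warmup).
#' @param warmup warmup iterations (must be `< iter`).
#' @param thin post-warmup thinning interval.
#' @param base_seed integer seed from which per-chain seeds are derived.
#' @param parameterization `"non_centered"` (random effects sampled as
#'   standard normals scaled by the class SDs) or `"centered"`.
#' @param adapt_delta NUTS target acceptance statistic.
#' @param perturb_scale scale of the Gaussian perturbations applied to the
#'   heuristic initial values, so chains start in distinct neighbourhoods.
#' @param max_treedepth NUTS maximum doubling depth.
#' @param beta_trunc truncation fraction of the harmonic-mean evidence
#'   estimator.
#' @param rhat_threshold split-Rhat bound below which a chain is flagged
#'   convergent (default 1.01; short desk-scale chains may need a looser
#'   bound because split-Rhat itself is noisy at small effective sample
#'   sizes).
#' @return list of class `jlcm_chains`.
#' @export
jlcm_chains <- function(M = 6, iter = 6000, warmup = 3000, thin = 3,
                        base_seed = 1, parameterization = c("non_centered",
                                                            "centered"),
                        adapt_delta = 0.8, perturb_scale = 0.5,
                        max_treedepth = 10, beta_trunc = 0.8,
                        rhat_threshold = 1.01) {
  parameterization <- match.arg(parameterization)
  if (warmup >= iter) stop("`warmup` must be smaller than `iter`")
  if (thin < 1) stop("`thin` must be >= 1")
  if (M < 1) stop("`M` must be >= 1")
  structure(list(M = as.integer(M), iter = as.integer(iter),
                 warmup = as.integer(warmup), thin = as.integer(thin),
                 base_seed = as.integer(base_seed),
                 parameterization = parameterization,
                 adapt_delta = adapt_delta, perturb_scale = perturb_scale,
                 max_treedepth = as.integer(max_treedepth),
                 beta_trunc = beta_trunc,
                 rhat_threshold = rhat_threshold),
            class = "jlcm_chains")
}

chain_seed <- function(base_seed, chain_index) {
  as.integer((as.numeric(base_seed) * 7919 + chain_index * 104729) %% 2147483629)
}

#' Heuristic, randomly perturbed initial values
#'
#' Builds spread-out chain initializations: per-subject least-squares
#' trajectory coefficients are clustered into `G` groups with k-means;
#' class-wise regression and moment estimates give the longitudinal
#' parameters, and a class-wise Weibull fit (ignoring the association) gives
#' the survival parameters. Independent Gaussian perturbations scaled by
#' `perturb_scale` are then applied, and the remaining parameters
#' (membership coefficients, association strengths, random effects) are
#' drawn from independent Gaussians.
#'
#' @param data a [jlcm_data()] object.
#' @param spec a [jlcm_spec()] object.
#' @param seed integer seed; distinct seeds give distinct initial values.
#' @param perturb_scale nonnegative perturbation scale (0 = deterministic
#'   heuristic).
#' @return a natural-scale parameter draw (see [subject_marginal_loglik()]).
#' @export
initialize_params <- function(data, spec, seed = 1, perturb_scale = 0.5) {
  md <- prepare_model_data(data, spec)
  G <- spec$G; r <- md$r; p <- md$p; q <- md$q; n <- md$n
  set.seed(seed)

  # per-subject least-squares coefficients on the random-effect design
  coefs <- t(vapply(seq_len(n), function(i) {
    rows <- md$sub_start[i] + seq_len(md$sub_len[i])
    zi <- md$Z[rows, , drop = FALSE]
    yi <- md$y[rows]
    cf <- tryCatch(stats::lm.fit(zi, yi)$coefficients,
                   error = function(e) rep(NA_real_, r))
    cf[!is.finite(cf)] <- 0
    cf
  }, numeric(r)))
  if (G > 1L) {
    km <- stats::kmeans(scale(coefs), centers = G, nstart = 10)
    lab <- km$cluster
  } else lab <- rep(1L, n)
  # deterministic labelling: decreasing mean first coefficient (intercept)
  ord <- order(-vapply(seq_len(G), function(g) mean(coefs[lab == g, 1]),
                       numeric(1)))
  lab <- match(lab, ord)

  classes <- vector("list", G)
  for (g in seq_len(G)) {
    sel <- which(lab == g)
    rows <- unlist(lapply(sel, function(i)
      md$sub_start[i] + seq_len(md$sub_len[i])))
    fit <- stats::lm.fit(md$X[rows, , drop = FALSE], md$y[rows])
    beta <- fit$coefficients
    beta[!is.finite(beta)] <- 0
    sigma2 <- max(stats::var(fit$residuals) * 0.5, 0.05)
    Sigma_diag <- pmax(apply(coefs[sel, , drop = FALSE], 2, stats::var), 0.05)
    Sigma_diag[!is.finite(Sigma_diag)] <- 0.5
    sv <- weibull_ph_init(md$Tobs[sel], md$delta[sel],
                          md$Wt[sel, , drop = FALSE])
    perturb <- function(x, s) x + stats::rnorm(length(x), 0, s * perturb_scale)
    classes[[g]] <- class_params(
      beta = perturb(beta, 0.5),
      sigma2 = exp(perturb(log(sigma2), 0.3)),
      Sigma_diag = exp(perturb(log(Sigma_diag), 0.3)),
      phi0 = exp(perturb(log(sv$phi0), 0.2)),
      phi1 = perturb(sv$phi1, 0.5),
      gamma = perturb(sv$gamma, 0.2),
      alpha = stats::rnorm(1, 0, 0.25))
  }
  psi0 <- stats::rnorm(max(G - 1L, 0L), 0, 0.5)
  psi <- matrix(stats::rnorm(max(G - 1L, 0L) * md$pW, 0, 0.5),
                max(G - 1L, 0L), md$pW)
  b <- array(stats::rnorm(n * r * G, 0, 0.3), dim = c(n, r, G))
  list(classes = classes, psi0 = psi0, psi = psi, b = b)
}

# Weibull PH initials from an AFT fit (survreg), association ignored
weibull_ph_init <- function(Tobs, delta, Wt) {
  q <- ncol(Wt)
  fallback <- list(phi0 = 1,
                   phi1 = log(max(sum(delta), 0.5) / max(sum(Tobs), 1e-8)),
                   gamma = rep(0, q))
  if (sum(delta) < 3 || all(Tobs <= 0)) return(fallback)
  df <- data.frame(.T = pmax(Tobs, 1e-6), .d = delta)
  fm <- if (q > 0) {
    W <- as.data.frame(Wt); names(W) <- paste0("w", seq_len(q))
    df <- cbind(df, W)
    stats::as.formula(paste("survival::Surv(.T, .d) ~",
                            paste(names(W), collapse = "+")))
  } else survival::Surv(.T, .d) ~ 1
  fit <- tryCatch(survival::survreg(fm, data = df, dist = "weibull"),
                  error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$scale) || fit$scale <= 0) return(fallback)
  shape <- 1 / fit$scale
  cf <- stats::coef(fit)
  out <- list(phi0 = min(max(shape, 0.2), 6),
              phi1 = -cf[[1]] / fit$scale,
              gamma = if (q > 0) -cf[-1] / fit$scale else numeric(0))
  if (any(!is.finite(unlist(out)))) return(fallback)
  out
}

#' Run one NUTS chain on the marginalized joint posterior
#'
#' @param config a [jlcm_chains()] configuration.
#' @param spec a [jlcm_spec()] object.
#' @param priors a [jlcm_priors()] object.
#' @param data a [jlcm_data()] object.
#' @param chain_index chain number (drives the derived seed).
#' @return a `jlcm_chain` object: retained draws (unconstrained and
#'   natural-scale structural parameters), per-draw sampling and
#'   natural-scale joint log densities, divergence counts and per-parameter
#'   split-Rhat / effective sample size.
#' @export
run_chain <- function(config, spec, priors, data, chain_index = 1) {
  md <- prepare_model_data(data, spec, priors, config$parameterization)
  seed <- chain_seed(config$base_seed, chain_index)
  init <- initialize_params(data, spec, seed = seed,
                            perturb_scale = config$perturb_scale)
  par0 <- pack_draw(init, md)
  set.seed(seed)
  fit <- jlcm_nuts_cpp(md, par0, iter = config$iter, warmup = config$warmup,
                       thin = config$thin, adapt_delta = config$adapt_delta,
                       max_treedepth = config$max_treedepth)
  lp_joint <- fit$lp_joint
  fit$divergent <- as.logical(fit$divergent)

  d <- md_dims(md)
  theta_un <- fit$draws[, seq_len(d$n_theta), drop = FALSE]
  colnames(theta_un) <- md$theta_names
  theta <- theta_un
  logcols <- grepl("^log_", colnames(theta))
  theta[, logcols] <- exp(theta[, logcols])
  colnames(theta) <- sub("^log_", "", colnames(theta))

  diag_tab <- chain_diagnostics_table(theta_un)
  div_frac <- fit$n_divergent / config$iter
  if (div_frac > 0.1)
    warning(sprintf("chain %d: %.1f%% divergent transitions", chain_index,
                    100 * div_frac))
  thr <- if (is.null(config$rhat_threshold)) 1.01 else config$rhat_threshold
  convergent <- all(is.na(diag_tab$rhat) | diag_tab$rhat < thr)

  structure(list(draws = fit$draws, theta = theta, lp = fit$lp,
                 lp_joint = lp_joint, diagnostics = diag_tab,
                 convergent = convergent, n_divergent = fit$n_divergent,
                 treedepth = fit$treedepth, accept_stat = fit$accept_stat,
                 step_size = fit$step_size, seed = seed,
                 chain_index = chain_index, md = md, spec = spec,
                 priors = priors, config = config),
            class = "jlcm_chain")
}

#' @export
print.jlcm_chain <- function(x, ...) {
  cat("JLCM chain", x$chain_index, ":", nrow(x$draws), "retained draws,",
      x$n_divergent, "divergences,",
      if (x$convergent) "convergent" else "NOT convergent",
      sprintf("(max split-Rhat %.3f)\n", max(x$diagnostics$rhat, na.rm = TRUE)))
  invisible(x)
}

#' Run M independently initialized chains and weigh them
#'
#' Chains are mutually independent: each gets a seed derived
#' deterministically from `base_seed` and its index, its own perturbed
#' initialization, and its own NUTS adaptation. After sampling, each
#' convergent chain receives a truncated-harmonic-mean log evidence weight
#' and the dominant chain is flagged.
#'
#' @inheritParams run_chain
#' @return a `jlcm_chainset`: list with `chains`, per-chain `log_evidence`,
#'   `convergent` flags and the `selected` chain index.
#' @export
run_parallel_chains <- function(config, spec, priors, data) {
  chains <- lapply(seq_len(config$M), function(k)
    run_chain(config, spec, priors, data, chain_index = k))
  conv <- vapply(chains, `[[`, logical(1), "convergent")
  if (!any(conv))
    stop("no chain converged (all split-Rhat >= 1.01); ",
         "consider longer runs or more informative priors")
  cs <- structure(list(chains = chains, convergent = conv,
                       config = config, log_evidence = rep(NA_real_, length(chains)),
                       selected = NA_integer_),
                  class = "jlcm_chainset")
  set.seed(chain_seed(config$base_seed, 0L))  # deterministic epsilon subsample
  sel <- select_chain(cs, beta_trunc = config$beta_trunc)
  cs$log_evidence <- attr(sel, "log_evidence")
  cs$selected <- as.integer(sel)
  cs
}

#' @export
print.jlcm_chainset <- function(x, ...) {
  cat("JLCM chain set:", length(x$chains), "chains\n")
  for (k in seq_along(x$chains)) {
    cat(sprintf("  chain %d: %s  log-evidence %s%s\n", k,
                if (x$convergent[k]) "convergent" else "non-convergent",
                formatC(x$log_evidence[k], format = "f", digits = 2),
                if (identical(x$selected, k)) "  [selected]" else ""))
  }
  invisible(x)
}

# split-Rhat and effective sample size per monitored scalar parameter
chain_diagnostics_table <- function(theta_un) {
  S <- nrow(theta_un)
  rhat <- apply(theta_un, 2, split_rhat)
  ess <- tryCatch(as.numeric(coda::effectiveSize(coda::mcmc(theta_un))),
                  error = function(e) rep(NA_real_, ncol(theta_un)))
  data.frame(param = colnames(theta_un),
             mean = colMeans(theta_un),
             sd = apply(theta_un, 2, stats::sd),
             rhat = rhat, ess = ess, row.names = NULL)
}

#' Split-Rhat of a single scalar chain
#'
#' Potential scale reduction computed from the two halves of one chain;
#' values near 1 indicate within-chain stationarity. Constant sequences
#' return `NA`.
#'
#' @param x numeric vector of draws.
#' @return scalar split-Rhat.
#' @export
split_rhat <- function(x) {
  S <- length(x)
  if (S < 4) return(NA_real_)
  half <- floor(S / 2)
  xs <- list(x[seq_len(half)], x[(S - half + 1):S])
  W <- mean(vapply(xs, stats::var, numeric(1)))
  if (!is.finite(W) || W == 0) return(NA_real_)
  B <- half * stats::var(vapply(xs, mean, numeric(1)))
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Convergence diagnostics of a chain or chain set
#'
#' @param x a `jlcm_chain` or `jlcm_chainset`.
#' @return a data frame of per-parameter split-Rhat, effective sample size,
#'   mean and SD (one block per chain for a chain set, with a `chain`
#'   column).
#' @export
convergence_diagnostics <- function(x) {
  if (inherits(x, "jlcm_chain")) return(x$diagnostics)
  if (inherits(x, "jlcm_chainset")) {
    out <- do.call(rbind, lapply(seq_along(x$chains), function(k)
      cbind(chain = k, x$chains[[k]]$diagnostics)))
    return(out)
  }
  stop("`x` must be a jlcm_chain or jlcm_chainset")
}

# natural-scale ParamDraw from retained draw s of a chain
chain_draw <- function(chain, s) unpack_draw(chain$draws[s, ], chain$md)
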