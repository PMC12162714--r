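# Predictive model comparison: pointwise log-likelihood matrix, WAIC,
# PSIS-LOO, the paired z-score test, and forward selection of the number of
# latent classes.

#' Pointwise log-likelihood matrix of a chain
#'
#' Entry `(i, s)` is the class-marginalized log-likelihood of subject `i`
#' under retained draw `s`:
#' `log sum_g pi_ig p(y_i | b_ig, g) p(T_i, Delta_i | b_ig, g)`, i.e. the
#' integrand targeted by LOOIC/WAIC, conditional on the sampled random
#' effects with the class indicator marginalized per draw.
#'
#' @param chain a `jlcm_chain`.
#' @return `n x S` matrix.
#' @export
pointwise_loglik <- function(chain) {
  md <- chain$md
  S <- nrow(chain$draws)
  out <- matrix(NA_real_, md$n, S)
  for (s in seq_len(S)) {
    lw <- jlcm_class_logweights_cpp(chain$draws[s, ], md)
    m <- apply(lw, 1, max)
    out[, s] <- m + log(rowSums(exp(lw - m)))
  }
  if (any(!is.finite(out))) {
    bad <- which(!is.finite(out), arr.ind = TRUE)[1, ]
    stop("non-finite pointwise log-likelihood at subject ", bad[1],
         ", draw ", bad[2])
  }
  out
}

new_ic_result <- function(method, pointwise, se, p_eff, pareto_k = NULL) {
  elpd <- sum(pointwise)
  structure(list(method = method, elpd = elpd, se = se, ic = -2 * elpd,
                 pointwise = pointwise, p_eff = p_eff, pareto_k = pareto_k,
                 n = length(pointwise)),
            class = "jlcm_ic")
}

#' @export
print.jlcm_ic <- function(x, ...) {
  cat(sprintf("%s: %.1f (elpd %.1f, SE %.1f, p_eff %.1f, n %d)\n",
              toupper(x$method), x$ic, x$elpd, x$se, x$p_eff, x$n))
  if (!is.null(x$pareto_k)) {
    nbad <- sum(x$pareto_k > 0.7)
    if (nbad > 0) cat(sprintf("  %d of %d Pareto-k values > 0.7\n", nbad, x$n))
  }
  invisible(x)
}

#' Widely applicable information criterion
#'
#' `elpd_i = log mean_s p(D_i | draw_s) - var_s log p(D_i | draw_s)`;
#' reported on the deviance scale (`-2 elpd`) with
#' `SE = sqrt(n) * sd(pointwise elpd)`.
#'
#' @param ll `n x S` pointwise log-likelihood matrix (see
#'   [pointwise_loglik()]).
#' @return a `jlcm_ic` object.
#' @export
compute_waic <- function(ll) {
  ll <- as.matrix(ll)
  S <- ncol(ll)
  if (S < 2) stop("need at least 2 draws")
  lpd <- apply(ll, 1, logmeanexp)
  p_i <- apply(ll, 1, stats::var)
  pointwise <- lpd - p_i
  new_ic_result("waic", pointwise,
                se = sqrt(nrow(ll)) * stats::sd(pointwise), p_eff = sum(p_i))
}

logmeanexp <- function(x) { m <- max(x); m + log(mean(exp(x - m))) }

#' Pareto-smoothed importance-sampling leave-one-out criterion
#'
#' Leave-one-out expected log predictive density estimated by importance
#' sampling with Pareto-smoothed weights: the largest importance ratios of
#' each subject are replaced by quantiles of a generalized Pareto
#' distribution fitted to the tail, and the tail-shape estimate `k` is
#' reported as a reliability diagnostic.
#'
#' @inheritParams compute_waic
#' @return a `jlcm_ic` object with per-subject `pareto_k`; a warning is
#'   attached when more than 10% of subjects exceed `k = 0.7`.
#' @export
compute_looic <- function(ll) {
  ll <- as.matrix(ll)
  n <- nrow(ll); S <- ncol(ll)
  if (S < 2) stop("need at least 2 draws")
  pointwise <- numeric(n); ks <- numeric(n); p_loo_ref <- numeric(n)
  for (i in seq_len(n)) {
    psis <- psis_smooth(-ll[i, ])
    lw <- psis$log_weights - logsumexp(psis$log_weights)
    pointwise[i] <- logsumexp(lw + ll[i, ])
    ks[i] <- psis$k
    p_loo_ref[i] <- logmeanexp(ll[i, ])
  }
  out <- new_ic_result("looic", pointwise,
                       se = sqrt(n) * stats::sd(pointwise),
                       p_eff = sum(p_loo_ref - pointwise), pareto_k = ks)
  if (isTRUE(mean(ks > 0.7, na.rm = TRUE) > 0.1))
    out$warning <- sprintf("%.0f%% of Pareto-k diagnostics exceed 0.7; LOO may be unreliable",
                           100 * mean(ks > 0.7))
  out
}

logsumexp <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }

# Pareto smoothing of log importance ratios (one data point)
psis_smooth <- function(log_ratios) {
  S <- length(log_ratios)
  lw <- log_ratios - max(log_ratios)
  M <- min(ceiling(0.2 * S), ceiling(3 * sqrt(S)))
  if (M < 5) return(list(log_weights = lw, k = NA_real_))
  ord <- order(lw)
  tail_ids <- ord[(S - M + 1):S]
  cut <- exp(lw[ord[S - M]])
  exceed <- exp(lw[tail_ids]) - cut
  if (max(exceed) <= 0) return(list(log_weights = lw, k = NA_real_))
  fit <- gpd_fit(exceed)
  # replace tail by expected GPD order statistics, capped at the max ratio
  p <- (seq_len(M) - 0.5) / M
  smoothed <- cut + qgpd(p, fit$k, fit$sigma)
  smoothed <- pmin(pmax(smoothed, .Machine$double.xmin), exp(max(lw)))
  lw[tail_ids[order(exp(lw[tail_ids]))]] <- log(smoothed)
  list(log_weights = lw, k = fit$k)
}

# generalized Pareto fit (Zhang & Stephens 2009 profile posterior mean),
# with the small-sample regularization of the tail-shape estimate
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  prior <- 3
  m <- 30 + floor(sqrt(n))
  bs <- 1 / x[n] +
    (1 - sqrt(m / (seq_len(m) - 0.5))) / (prior * x[max(floor(n / 4 + 0.5), 1)])
  ks <- vapply(bs, function(b) -mean(log1p(-b * x)), numeric(1))
  L <- n * (log(bs / ks) + ks - 1)
  w <- 1 / vapply(seq_len(m), function(j) sum(exp(L - L[j])), numeric(1))
  b <- sum(bs * w)
  kr <- mean(log1p(-b * x))        # GPD shape (standard xi convention)
  sigma <- -kr / b
  k <- (n * kr + 5) / (n + 10)     # shrink toward 0.5 for small tails
  list(k = k, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

#' Compare two models by the paired z-score on elpd
#'
#' `SE(delta) = sqrt(n) * sd(pointwise differences)`; the z-score is
#' positive when model `b` predicts better (lower deviance-scale IC), and
#' the one-tailed p-value refers to that direction.
#'
#' @param a,b `jlcm_ic` objects on the same `n` subjects (same criterion).
#' @return list of class `jlcm_ic_comparison`: `delta_ic`, `delta_elpd`,
#'   `se`, `z`, `p_value`.
#' @export
compare_models <- function(a, b) {
  if (a$n != b$n) stop("pointwise vectors have different lengths (",
                       a$n, " vs ", b$n, ")")
  d <- b$pointwise - a$pointwise
  delta <- sum(d)
  se <- sqrt(a$n) * stats::sd(d)
  z <- if (se == 0) 0 else delta / se
  structure(list(delta_ic = -2 * delta, delta_elpd = delta, se = se, z = z,
                 p_value = stats::pnorm(z, lower.tail = FALSE)),
            class = "jlcm_ic_comparison")
}

#' @export
print.jlcm_ic_comparison <- function(x, ...) {
  cat(sprintf("delta IC (deviance) %.1f, z = %.2f, one-tailed p = %.4g\n",
              x$delta_ic, x$z, x$p_value))
  invisible(x)
}

#' Forward selection of the number of latent classes
#'
#' Starting from the simplest candidate, iteratively compares the current
#' best model with each more complex candidate (in increasing order of `G`)
#' and adopts the candidate only if (i) its predictive improvement is
#' significant at level `alpha` by the one-tailed z test and (ii) its
#' effective class count strictly exceeds the current best's. Terminates
#' after the most complex candidate has been compared.
#'
#' @param fits list of candidates; each element must carry an `ic`
#'   (`jlcm_ic`) and a `g_eff` (effective class count) and a `G`. A
#'   [jlcm_fit()] result qualifies directly; `ic` defaults to its LOOIC.
#' @param alpha one-tailed significance level (default 0.001).
#' @param criterion `"looic"` or `"waic"` (picked from fit objects).
#' @return list of class `jlcm_selection`: chosen `G` and an audit `trail`
#'   data frame (one row per comparison).
#' @export
forward_select <- function(fits, alpha = 0.001, criterion = c("looic", "waic")) {
  criterion <- match.arg(criterion)
  cand <- lapply(fits, as_candidate, criterion = criterion)
  Gs <- vapply(cand, `[[`, numeric(1), "G")
  if (anyDuplicated(Gs)) stop("duplicate candidate G values")
  cand <- cand[order(Gs)]
  Gs <- sort(Gs)
  if (!all(diff(Gs) == 1))
    stop("candidates must cover consecutive G values; got ",
         paste(Gs, collapse = ", "))
  zcrit <- stats::qnorm(1 - alpha)
  best <- 1L
  trail <- NULL
  for (j in seq_along(cand)[-1]) {
    cmp <- compare_models(cand[[best]]$ic, cand[[j]]$ic)
    adopt <- (cmp$z > zcrit) && (cand[[j]]$g_eff > cand[[best]]$g_eff)
    trail <- rbind(trail, data.frame(
      G_current = cand[[best]]$G, G_candidate = cand[[j]]$G,
      ic_current = cand[[best]]$ic$ic, ic_candidate = cand[[j]]$ic$ic,
      z = cmp$z, p_value = cmp$p_value,
      g_eff_current = cand[[best]]$g_eff, g_eff_candidate = cand[[j]]$g_eff,
      adopted = adopt))
    if (adopt) best <- j
  }
  structure(list(G = cand[[best]]$G, trail = trail, alpha = alpha,
                 criterion = criterion),
            class = "jlcm_selection")
}

as_candidate <- function(f, criterion) {
  if (inherits(f, "jlcm_fit"))
    return(list(G = f$spec$G, ic = f[[criterion]], g_eff = f$g_eff))
  if (is.list(f) && !is.null(f$ic) && !is.null(f$g_eff) && !is.null(f$G))
    return(f[c("G", "ic", "g_eff")])
  stop("each candidate needs `G`, `ic` and `g_eff` (or be a jlcm_fit)")
}

#' @export
print.jlcm_selection <- function(x, ...) {
  cat("Forward selection (", toupper(x$criterion), ", alpha = ",
      format(x$alpha), "): chose G = ", x$G, "\n", sep = "")
  print(x$trail, digits = 4)
  invisible(x)
}
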