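# Truncated harmonic mean estimation of a chain's marginal-likelihood
# weight, and evidence-based selection of the dominant chain.

#' Truncated harmonic mean log evidence from posterior draws
#'
#' Estimates the log marginal likelihood from draws of an (unnormalized)
#' posterior density. Draws whose unnormalized log density exceeds the upper
#' `beta_trunc` quantile threshold form the high-density set; an indicator
#' kernel of radius `epsilon` localized on that set plays the role of the
#' instrumental density, whose ball volume is computed exactly in the
#' standardized metric so that the estimate is an actual log evidence (not
#' only defined up to a constant).
#'
#' @param theta matrix of draws (rows = draws; structural parameters only).
#' @param lp_joint vector of unnormalized log joint density at each draw.
#' @param beta_trunc truncation fraction in (0, 1); default 0.8.
#' @param sds per-coordinate standard deviations used to standardize the
#'   metric (defaults to the column SDs of `theta`). Coordinates with zero
#'   SD are dropped from the distance.
#' @param epsilon ball radius in the standardized metric; default the 5th
#'   percentile of pairwise distances among a subsample of at most 500
#'   draws.
#' @return scalar log evidence estimate, with attributes `epsilon` and
#'   `n_active` (draws with a nonzero kernel value).
#' @export
log_evidence_thm <- function(theta, lp_joint, beta_trunc = 0.8,
                             sds = NULL, epsilon = NULL) {
  theta <- as.matrix(theta)
  Tn <- nrow(theta)
  if (Tn != length(lp_joint)) stop("`theta` rows and `lp_joint` length differ")
  if (beta_trunc <= 0 || beta_trunc >= 1) stop("`beta_trunc` must be in (0, 1)")
  if (is.null(sds)) sds <- apply(theta, 2, stats::sd)
  keep <- is.finite(sds) & sds > 0
  if (!any(keep)) stop("all coordinates degenerate; cannot define a metric")
  Ts <- sweep(theta[, keep, drop = FALSE], 2, sds[keep], "/")
  dm <- ncol(Ts)

  thr <- stats::quantile(lp_joint, probs = 1 - beta_trunc, names = FALSE)
  H <- which(lp_joint > thr)
  if (!length(H)) stop("high-density set is empty; cannot truncate")

  if (is.null(epsilon)) epsilon <- default_thm_epsilon(Ts)
  # count high-density neighbours of every draw within epsilon
  counts <- ball_counts(Ts, Ts[H, , drop = FALSE], epsilon)
  # log volume of the epsilon-ball mapped back to the unstandardized metric
  log_vol <- dm / 2 * log(pi) - lgamma(dm / 2 + 1) + dm * log(epsilon) +
    sum(log(sds[keep]))
  log_h <- ifelse(counts > 0, log(counts), -Inf) - log_vol -
    log(beta_trunc) - log(Tn)
  active <- is.finite(log_h)
  if (!any(active)) stop("kernel vanished at every draw; epsilon too small")
  # log( (1/T) sum h_i / p_i ) , then negate
  terms <- log_h[active] - lp_joint[active]
  m <- max(terms)
  log_inv <- m + log(sum(exp(terms - m))) - log(Tn)
  structure(-log_inv, epsilon = epsilon, n_active = sum(active))
}

default_thm_epsilon <- function(Ts) {
  Tn <- nrow(Ts)
  sub <- if (Tn > 500) sort(sample.int(Tn, 500)) else seq_len(Tn)
  dd <- stats::dist(Ts[sub, , drop = FALSE])
  eps <- stats::quantile(dd, probs = 0.05, names = FALSE)
  if (!is.finite(eps) || eps <= 0) eps <- max(stats::median(dd), 1e-8)
  eps
}

# number of rows of `ref` within `eps` of each row of `x` (Euclidean)
ball_counts <- function(x, ref, eps) {
  nx <- nrow(x)
  counts <- integer(nx)
  rn2 <- rowSums(ref^2)
  chunk <- max(1L, floor(2e6 / max(nrow(ref), 1L)))
  i <- 1L
  e2 <- eps^2
  while (i <= nx) {
    j <- min(i + chunk - 1L, nx)
    xi <- x[i:j, , drop = FALSE]
    d2 <- outer(rowSums(xi^2), rn2, "+") - 2 * xi %*% t(ref)
    counts[i:j] <- rowSums(d2 < e2)
    i <- j + 1L
  }
  counts
}

#' Log evidence weight of one chain
#'
#' Applies the truncated harmonic mean estimator to a chain's retained
#' structural-parameter draws and recorded natural-scale log joint
#' densities. Random effects are excluded from the distance metric: their
#' dimension grows with the sample size and would make every
#' `epsilon`-ball empty.
#'
#' @param chain a `jlcm_chain` (see [run_chain()]).
#' @param beta_trunc truncation fraction.
#' @param sds,epsilon optional shared metric (see [log_evidence_thm()]);
#'   supplied by [select_chain()] so that weights of different chains are
#'   computed in the same metric.
#' @return scalar log evidence.
#' @export
chain_log_evidence <- function(chain, beta_trunc = 0.8, sds = NULL,
                               epsilon = NULL) {
  log_evidence_thm(chain$theta, chain$lp_joint, beta_trunc = beta_trunc,
                   sds = sds, epsilon = epsilon)
}

#' Select the dominant chain by evidence weight
#'
#' Computes the truncated-harmonic-mean weight of every convergent chain in
#' a shared standardized metric (pooled coordinate SDs, one epsilon) and
#' returns the index of the heaviest; ties break to the lowest index, and
#' non-convergent chains are excluded.
#'
#' @param chainset a `jlcm_chainset` (see [run_parallel_chains()]).
#' @param beta_trunc truncation fraction.
#' @return selected chain index, with attribute `log_evidence` (NA for
#'   non-convergent chains).
#' @export
select_chain <- function(chainset, beta_trunc = 0.8) {
  conv <- which(chainset$convergent)
  if (!length(conv)) stop("no convergent chain to select from")
  pooled <- do.call(rbind, lapply(chainset$chains[conv], `[[`, "theta"))
  sds <- apply(pooled, 2, stats::sd)
  keep <- is.finite(sds) & sds > 0
  sub <- if (nrow(pooled) > 500) {
    pooled[sort(sample.int(nrow(pooled), 500)), keep, drop = FALSE]
  } else pooled[, keep, drop = FALSE]
  eps <- default_thm_epsilon(sweep(sub, 2, sds[keep], "/"))
  lev <- rep(NA_real_, length(chainset$chains))
  for (k in conv) {
    lev[k] <- tryCatch(
      as.numeric(chain_log_evidence(chainset$chains[[k]], beta_trunc,
                                    sds = sds, epsilon = eps)),
      error = function(e) NA_real_)
  }
  if (all(is.na(lev[conv]))) stop("evidence estimation failed for all chains")
  best <- conv[which.max(replace(lev, is.na(lev), -Inf)[conv])]
  structure(best, log_evidence = lev)
}
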