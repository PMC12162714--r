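# No-U-Turn sampler (Hoffman & Gelman, Algorithm 6) with dual-averaging
# step-size adaptation and windowed diagonal mass-matrix estimation.
# Generic over a log-density-and-gradient callback so that it can be
# exercised on closed-form targets independently of the joint model.

#' Sample from a differentiable log density with the No-U-Turn sampler
#'
#' @param lp_grad function taking a parameter vector and returning
#'   `list(lp = <scalar>, grad = <vector>)`. Non-finite `lp` is treated as a
#'   rejected (divergent) proposal, never as an error.
#' @param init initial parameter vector.
#' @param iter total iterations including warmup.
#' @param warmup adaptation iterations discarded from the output.
#' @param thin keep every `thin`-th post-warmup draw.
#' @param adapt_delta target mean acceptance statistic (default 0.8).
#' @param max_treedepth maximum doubling depth (default 10).
#' @param inv_mass optional fixed diagonal inverse mass (posterior variance
#'   scale); estimated during warmup when `NULL`.
#' @param init_step optional initial step size; found heuristically when
#'   `NULL`.
#' @return list with `draws` (matrix, retained draws by row), `lp`,
#'   `divergent`, `treedepth`, `accept_stat` (per retained draw),
#'   `step_size`, `inv_mass`, `n_divergent` (all iterations).
#' @export
nuts_sample <- function(lp_grad, init, iter = 2000, warmup = floor(iter / 2),
                        thin = 1, adapt_delta = 0.8, max_treedepth = 10,
                        inv_mass = NULL, init_step = NULL) {
  if (warmup >= iter) stop("`warmup` must be smaller than `iter`")
  d <- length(init)
  eval_lp <- function(q) {
    out <- tryCatch(lp_grad(q), error = function(e) NULL)
    if (is.null(out) || !is.finite(out$lp) || any(!is.finite(out$grad)))
      return(list(lp = -Inf, grad = numeric(d)))
    out
  }

  minv <- if (is.null(inv_mass)) rep(1, d) else rep(inv_mass, length.out = d)
  adapt_mass <- is.null(inv_mass)
  cur <- eval_lp(init)
  if (!is.finite(cur$lp)) stop("initial point has non-finite log density")
  q <- init

  kinetic <- function(p) 0.5 * sum(p * p * minv)
  leapfrog <- function(q, p, grad, eps) {
    p <- p + 0.5 * eps * grad
    q <- q + eps * minv * p
    e <- eval_lp(q)
    p <- p + 0.5 * eps * e$grad
    list(q = q, p = p, lp = e$lp, grad = e$grad)
  }

  # reasonable initial step size (Alg. 4)
  find_eps <- function(q, cur) {
    eps <- 1
    p <- stats::rnorm(d) / sqrt(minv)
    H0 <- cur$lp - kinetic(p)
    st <- leapfrog(q, p, cur$grad, eps)
    H1 <- st$lp - kinetic(st$p)
    if (!is.finite(H1)) { # shrink until finite
      for (k in 1:40) {
        eps <- eps / 2
        st <- leapfrog(q, p, cur$grad, eps)
        H1 <- st$lp - kinetic(st$p)
        if (is.finite(H1)) break
      }
      if (!is.finite(H1)) return(1e-6)
    }
    a <- if (H1 - H0 > log(0.5)) 1 else -1
    for (k in 1:40) {
      eps <- eps * 2^a
      st <- leapfrog(q, p, cur$grad, eps)
      H1 <- st$lp - kinetic(st$p)
      if (!is.finite(H1)) H1 <- -Inf
      if (a * (H1 - H0) < a * log(0.5)) break
    }
    eps
  }

  eps <- if (is.null(init_step)) find_eps(q, cur) else init_step
  # dual averaging state
  mu <- log(10 * eps); log_eps_bar <- 0; Hbar <- 0; m_adapt <- 0
  da_gamma <- 0.05; da_t0 <- 10; da_kappa <- 0.75

  # mass-adaptation windows (step-only buffers around doubling windows)
  w_init <- max(5L, floor(0.15 * warmup))
  w_term <- max(5L, floor(0.10 * warmup))
  win_lo <- w_init + 1L
  win_hi <- warmup - w_term
  wlen <- 25L
  next_win <- if (win_hi > win_lo) min(win_lo + wlen - 1L, win_hi) else -1L
  wsum <- numeric(d); wsum2 <- numeric(d); wn <- 0L

  n_keep <- floor((iter - warmup) / thin)
  draws <- matrix(NA_real_, n_keep, d)
  lp_out <- numeric(n_keep); div_out <- logical(n_keep)
  td_out <- integer(n_keep); acc_out <- numeric(n_keep)
  n_div_total <- 0L; keep_i <- 0L

  DIV_MAX <- 1000  # Hamiltonian error treated as divergence

  build_tree <- function(q, p, grad, lp, logu, v, j, H0) {
    if (j == 0L) {
      st <- leapfrog(q, p, grad, v * eps)
      Hn <- st$lp - kinetic(st$p)
      if (!is.finite(Hn)) Hn <- -Inf
      n1 <- as.integer(logu <= Hn)
      div <- (logu - DIV_MAX) > Hn
      a <- min(1, exp(Hn - H0))
      if (!is.finite(a)) a <- 0
      list(qm = st$q, pm = st$p, gm = st$grad, lpm = st$lp,
           qp = st$q, pp = st$p, gp = st$grad, lpp = st$lp,
           qn = st$q, lpn = st$lp, n = n1, s = as.integer(!div),
           alpha = a, nalpha = 1L, div = div)
    } else {
      t1 <- build_tree(q, p, grad, lp, logu, v, j - 1L, H0)
      if (t1$s == 1L) {
        if (v == -1) {
          t2 <- build_tree(t1$qm, t1$pm, t1$gm, t1$lpm, logu, v, j - 1L, H0)
          t1$qm <- t2$qm; t1$pm <- t2$pm; t1$gm <- t2$gm; t1$lpm <- t2$lpm
        } else {
          t2 <- build_tree(t1$qp, t1$pp, t1$gp, t1$lpp, logu, v, j - 1L, H0)
          t1$qp <- t2$qp; t1$pp <- t2$pp; t1$gp <- t2$gp; t1$lpp <- t2$lpp
        }
        if (t2$n > 0L && stats::runif(1) < t2$n / (t1$n + t2$n)) {
          t1$qn <- t2$qn; t1$lpn <- t2$lpn
        }
        dq <- t1$qp - t1$qm
        ok <- (sum(dq * minv * t1$pm) >= 0) && (sum(dq * minv * t1$pp) >= 0)
        t1$s <- as.integer(t2$s == 1L && ok)
        t1$n <- t1$n + t2$n
        t1$alpha <- t1$alpha + t2$alpha
        t1$nalpha <- t1$nalpha + t2$nalpha
        t1$div <- t1$div || t2$div
      }
      t1
    }
  }

  for (m in seq_len(iter)) {
    p0 <- stats::rnorm(d) / sqrt(minv)
    H0 <- cur$lp - kinetic(p0)
    logu <- H0 - stats::rexp(1)
    qm <- q; pm <- p0; gm <- cur$grad; lpm <- cur$lp
    qp <- q; pp <- p0; gp <- cur$grad; lpp <- cur$lp
    qn <- q; lpn <- cur$lp; gn <- cur$grad
    n_tot <- 1L; s <- 1L; j <- 0L
    alpha_sum <- 0; nalpha_sum <- 0L; diverged <- FALSE
    while (s == 1L && j < max_treedepth) {
      v <- sample(c(-1, 1), 1L)
      if (v == -1) {
        tr <- build_tree(qm, pm, gm, lpm, logu, v, j, H0)
        qm <- tr$qm; pm <- tr$pm; gm <- tr$gm; lpm <- tr$lpm
      } else {
        tr <- build_tree(qp, pp, gp, lpp, logu, v, j, H0)
        qp <- tr$qp; pp <- tr$pp; gp <- tr$gp; lpp <- tr$lpp
      }
      if (tr$s == 1L && tr$n > 0L && stats::runif(1) < min(1, tr$n / n_tot)) {
        qn <- tr$qn; lpn <- tr$lpn
      }
      n_tot <- n_tot + tr$n
      alpha_sum <- alpha_sum + tr$alpha
      nalpha_sum <- nalpha_sum + tr$nalpha
      diverged <- diverged || tr$div
      dq <- qp - qm
      ok <- (sum(dq * minv * pm) >= 0) && (sum(dq * minv * pp) >= 0)
      s <- as.integer(tr$s == 1L && ok)
      j <- j + 1L
    }
    if (!identical(qn, q)) {
      q <- qn
      cur <- eval_lp(q)   # refresh cached gradient at the new point
    }
    accept_stat <- if (nalpha_sum > 0) alpha_sum / nalpha_sum else 0
    if (diverged) n_div_total <- n_div_total + 1L

    if (m <= warmup) {
      m_adapt <- m_adapt + 1
      frac <- 1 / (m_adapt + da_t0)
      Hbar <- (1 - frac) * Hbar + frac * (adapt_delta - accept_stat)
      log_eps <- mu - sqrt(m_adapt) / da_gamma * Hbar
      log_eps_bar <- m_adapt^(-da_kappa) * log_eps +
        (1 - m_adapt^(-da_kappa)) * log_eps_bar
      eps <- exp(log_eps)
      if (adapt_mass && m >= win_lo && m <= win_hi) {
        wsum <- wsum + q; wsum2 <- wsum2 + q * q; wn <- wn + 1L
        if (m == next_win || m == win_hi) {
          if (wn >= 10L) {
            v_est <- (wsum2 - wsum^2 / wn) / (wn - 1L)
            minv <- v_est * wn / (wn + 5) + 1e-3 * 5 / (wn + 5)
            minv[minv <= 0 | !is.finite(minv)] <- 1e-3
            # restart step-size adaptation around the current step
            eps <- find_eps(q, cur)
            mu <- log(10 * eps); log_eps_bar <- 0; Hbar <- 0; m_adapt <- 0
          }
          wsum[] <- 0; wsum2[] <- 0; wn <- 0L
          wlen <- 2L * wlen
          next_win <- min(m + wlen, win_hi)
        }
      }
      if (m == warmup) eps <- exp(log_eps_bar)
    } else {
      k <- m - warmup
      if (k %% thin == 0L && keep_i < n_keep) {
        keep_i <- keep_i + 1L
        draws[keep_i, ] <- q
        lp_out[keep_i] <- cur$lp
        div_out[keep_i] <- diverged
        td_out[keep_i] <- j
        acc_out[keep_i] <- accept_stat
      }
    }
  }

  list(draws = draws, lp = lp_out, divergent = div_out, treedepth = td_out,
       accept_stat = acc_out, step_size = eps, inv_mass = minv,
       n_divergent = n_div_total)
}
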