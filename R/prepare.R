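# Flattening of a jlcm_data + jlcm_spec (+ priors) into the plain-vector
# model-data list consumed by the compiled log-posterior. All design
# matrices, including those at the per-subject Gauss-Legendre nodes on
# (0, T_i), are built once here.

assoc_code <- function(association)
  match(association, c("none", "current_value", "current_slope")) - 1L

# Gauss-Legendre nodes/weights on (-1, 1)
gl_rule <- function(n) {
  gl <- pracma::gaussLegendre(n, -1, 1)
  list(x = gl$x, w = gl$w)
}

prepare_model_data <- function(data, spec, priors = jlcm_priors(),
                               parameterization = "non_centered") {
  stopifnot(inherits(data, "jlcm_data"), inherits(spec, "jlcm_spec"))
  cols <- data$cols
  surv <- data$surv
  long <- data$long
  n <- nrow(surv)
  if (n < 2L) stop("degenerate dataset: need at least 2 subjects")
  if (nrow(long) < 1L) stop("degenerate dataset: no longitudinal measurements")

  # longitudinal frame = visits + baseline covariates
  base_cov <- surv[match(long[[cols$id]], surv[[cols$id]]), , drop = FALSE]
  lframe <- base_cov
  lframe[[spec$time]] <- long[[cols$time]]
  lframe[[all.vars(spec$fixed)[1L]]] <- long[[cols$y]]
  X <- eval_design(stats::delete.response(stats::terms(spec$fixed)), lframe)
  Z <- eval_design(spec$random, lframe)
  p <- ncol(X); r <- ncol(Z)
  if (r < 1L) stop("random-effect design must have at least one column")

  idx <- match(long[[cols$id]], surv[[cols$id]])
  sub_len <- tabulate(idx, nbins = n)
  if (any(sub_len == 0L))
    stop("subject(s) without longitudinal measurements: ",
         paste(surv[[cols$id]][sub_len == 0L], collapse = ", "))
  sub_start <- c(0L, cumsum(sub_len)[-n])

  # survival designs at the observed time and at the quadrature nodes
  Tobs <- surv[[cols$time]]
  delta <- as.integer(surv[[cols$event]])
  Wt <- eval_design(spec$survival, surv_frame(surv, spec, Tobs),
                    drop_intercept = TRUE)
  q <- ncol(Wt)
  sframe_T <- surv_frame(surv, spec, Tobs)
  XT <- eval_design(stats::delete.response(stats::terms(spec$fixed)), sframe_T)
  ZT <- eval_design(spec$random, sframe_T)

  nq <- spec$n_quad
  gl <- gl_rule(nq)
  # node times s_ik = T_i/2 * (x_k + 1); weights include the T_i/2 factor
  sq <- as.vector(t(outer(Tobs / 2, gl$x + 1)))        # n*nq, subject-major
  wq <- as.vector(t(outer(Tobs / 2, gl$w)))
  wq[rep(Tobs == 0, each = nq)] <- 0
  sq[sq <= 0] <- 1                                      # dummy for T = 0
  qframe <- surv[rep(seq_len(n), each = nq), , drop = FALSE]
  qframe[[spec$time]] <- sq
  Xq <- eval_design(stats::delete.response(stats::terms(spec$fixed)), qframe)
  Zq <- eval_design(spec$random, qframe)

  md <- list(
    n = n, G = spec$G, r = r, p = p, q = q,
    pW = 0L, nq = nq, assoc = assoc_code(spec$association),
    noncentered = identical(parameterization, "non_centered"),
    use_ig = spec$G == 1L,
    y = long[[cols$y]], X = X, Z = Z,
    sub_start = as.integer(sub_start), sub_len = as.integer(sub_len),
    Tobs = Tobs, logT = ifelse(Tobs > 0, log(Tobs), 0), delta = delta,
    Wt = Wt, XT = XT, ZT = ZT, Xq = Xq, Zq = Zq,
    sq = sq, logsq = log(sq), wq = wq,
    W = matrix(0, n, 0))

  if (!is.null(spec$membership)) {
    W <- eval_design(spec$membership, surv, drop_intercept = TRUE)
    md$W <- W
    md$pW <- ncol(W)
  }
  if (spec$association == "current_slope") {
    md$XTs <- eval_design(spec$fixed_slope, sframe_T, drop_intercept = TRUE)
    md$ZTs <- eval_design(spec$random_slope, sframe_T, drop_intercept = TRUE)
    md$Xqs <- eval_design(spec$fixed_slope, qframe, drop_intercept = TRUE)
    md$Zqs <- eval_design(spec$random_slope, qframe, drop_intercept = TRUE)
    if (ncol(md$XTs) != p || ncol(md$ZTs) != r)
      stop("slope designs must have the same number of columns as the designs ",
           "they differentiate")
  }

  md <- c(md, prior_fields(priors))
  md$ids <- surv[[cols$id]]
  md$theta_names <- theta_names(md)
  md$colnames_X <- colnames(X)
  md$colnames_W <- colnames(md$W)
  md$colnames_Wt <- colnames(Wt)
  md
}

surv_frame <- function(surv, spec, times) {
  df <- surv
  df[[spec$time]] <- times
  df
}

prior_fields <- function(priors) {
  priors[c("scale_beta", "scale_surv", "scale_psi", "shape_phi", "rate_phi",
           "scale_sigma2", "alpha_b", "lambda", "ig_shape", "ig_scale")]
}

# dimensions helper mirroring the C++ layout
md_dims <- function(md) {
  a <- if (md$assoc != 0L) 1L else 0L
  per_class <- md$p + 1L + md$r + 2L + md$q + a
  n_theta <- md$G * per_class + (md$G - 1L) * (1L + md$pW)
  list(G = md$G, p = md$p, r = md$r, q = md$q, pW = md$pW, n = md$n,
       assoc = md$assoc, per_class = per_class, n_theta = n_theta,
       n_par = n_theta + md$n * md$G * md$r,
       noncentered = isTRUE(md$noncentered))
}

theta_names <- function(md) {
  d <- md_dims(md)
  a <- if (d$assoc != 0L) 1L else 0L
  nm <- character(0)
  for (g in seq_len(d$G)) {
    nm <- c(nm,
            sprintf("beta[%d,%d]", g, seq_len(d$p) - 1L),
            sprintf("log_sigma2[%d]", g),
            sprintf("log_Sigma[%d,%d]", g, seq_len(d$r)),
            sprintf("log_phi0[%d]", g),
            sprintf("phi1[%d]", g),
            if (d$q > 0) sprintf("gamma[%d,%d]", g, seq_len(d$q)) else character(0),
            if (a) sprintf("alpha[%d]", g) else character(0))
  }
  for (g in seq_len(d$G - 1L)) {
    nm <- c(nm, sprintf("psi0[%d]", g),
            if (d$pW > 0) sprintf("psi[%d,%d]", g, seq_len(d$pW)) else character(0))
  }
  nm
}

# pack a natural-scale ParamDraw into the unconstrained sampling vector
pack_draw <- function(draw, md) {
  d <- md_dims(md)
  th <- numeric(d$n_par)
  pos <- 1L
  for (g in seq_len(d$G)) {
    cp <- draw$classes[[g]]
    th[pos:(pos + d$p - 1L)] <- cp$beta; pos <- pos + d$p
    th[pos] <- log(cp$sigma2); pos <- pos + 1L
    th[pos:(pos + d$r - 1L)] <- log(cp$Sigma_diag); pos <- pos + d$r
    th[pos] <- log(cp$phi0); pos <- pos + 1L
    th[pos] <- cp$phi1; pos <- pos + 1L
    if (d$q > 0) { th[pos:(pos + d$q - 1L)] <- cp$gamma; pos <- pos + d$q }
    if (d$assoc != 0L) { th[pos] <- cp$alpha; pos <- pos + 1L }
  }
  for (g in seq_len(d$G - 1L)) {
    th[pos] <- draw$psi0[g]; pos <- pos + 1L
    if (d$pW > 0) { th[pos:(pos + d$pW - 1L)] <- draw$psi[g, ]; pos <- pos + d$pW }
  }
  # random effects, subject-major then class
  b <- draw$b  # array n x r x G
  for (i in seq_len(d$n)) {
    for (g in seq_len(d$G)) {
      v <- b[i, , g]
      if (d$noncentered) v <- v / sqrt(draw$classes[[g]]$Sigma_diag)
      th[pos:(pos + d$r - 1L)] <- v
      pos <- pos + d$r
    }
  }
  th
}

# unpack the unconstrained sampling vector into a natural-scale ParamDraw
unpack_draw <- function(par, md) {
  d <- md_dims(md)
  stopifnot(length(par) == d$n_par)
  classes <- vector("list", d$G)
  pos <- 1L
  for (g in seq_len(d$G)) {
    beta <- par[pos:(pos + d$p - 1L)]; pos <- pos + d$p
    sigma2 <- exp(par[pos]); pos <- pos + 1L
    Sigma_diag <- exp(par[pos:(pos + d$r - 1L)]); pos <- pos + d$r
    phi0 <- exp(par[pos]); pos <- pos + 1L
    phi1 <- par[pos]; pos <- pos + 1L
    gamma <- numeric(0)
    if (d$q > 0) { gamma <- par[pos:(pos + d$q - 1L)]; pos <- pos + d$q }
    alpha <- 0
    if (d$assoc != 0L) { alpha <- par[pos]; pos <- pos + 1L }
    classes[[g]] <- class_params(beta = beta, sigma2 = sigma2,
                                 Sigma_diag = Sigma_diag, phi0 = phi0,
                                 phi1 = phi1, gamma = gamma, alpha = alpha)
  }
  psi0 <- numeric(max(d$G - 1L, 0L))
  psi <- matrix(0, max(d$G - 1L, 0L), d$pW)
  for (g in seq_len(d$G - 1L)) {
    psi0[g] <- par[pos]; pos <- pos + 1L
    if (d$pW > 0) { psi[g, ] <- par[pos:(pos + d$pW - 1L)]; pos <- pos + d$pW }
  }
  b <- array(0, dim = c(d$n, d$r, d$G))
  for (i in seq_len(d$n)) {
    for (g in seq_len(d$G)) {
      v <- par[pos:(pos + d$r - 1L)]
      if (d$noncentered) v <- v * sqrt(classes[[g]]$Sigma_diag)
      b[i, , g] <- v
      pos <- pos + d$r
    }
  }
  list(classes = classes, psi0 = psi0, psi = psi, b = b)
}
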