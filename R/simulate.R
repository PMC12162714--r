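# Synthetic joint datasets with known ground truth: class-specific linear
# mixed trajectories, Weibull hazards with a current-value association, and
# class membership either at fixed proportions or driven by covariates
# through the softmax submodel.

#' True parameter values of the benchmark two-class design
#'
#' The per-class generating values of the two-class heterogeneous-population
#' design used by the simulation study: widely separated mean trajectories
#' (intercepts +-8.03), a shared residual variance of 0.4761, mirrored
#' random-effect variances, and class-specific Weibull hazards with
#' association strengths 0.38 and 0.08.
#'
#' @return list of two [class_params()] objects.
#' @export
table2_truths <- function() {
  list(
    class_params(beta = c(8.03, -0.16, -5.86), sigma2 = 0.4761,
                 Sigma_diag = c(0.87, 0.02), phi0 = 1.8, phi1 = -4.85,
                 gamma = -0.02, alpha = 0.38),
    class_params(beta = c(-8.03, 0.46, 12.2), sigma2 = 0.4761,
                 Sigma_diag = c(0.02, 0.91), phi0 = 1.4, phi1 = -4.85,
                 gamma = 0.09, alpha = 0.08))
}

#' Simulation design
#'
#' Bundles everything the generators need. The four bundled membership
#' scenarios share the longitudinal/survival truths of [table2_truths()]
#' and differ in how class membership is generated:
#' fixed proportions (scenario 1), softmax on a standard-normal covariate
#' (scenario 2, `psi = (-0.4, 1)`), softmax on gender and age (scenario 3,
#' `psi = (2, 4, -0.1)`), or softmax on gender, age and the extra covariate
#' (scenario 4, `psi = (2, 4, -0.1, 1)`).
#'
#' @param name bundled design name (`"setting2_scenario1"` ..
#'   `"setting2_scenario4"`), or `NULL` to build a custom design from the
#'   remaining arguments.
#' @param n sample size (default 900).
#' @param truths list of per-class [class_params()] generating values.
#' @param membership list: either `list(type = "fixed_proportions",
#'   proportions = ...)` or `list(type = "softmax", covariates = <names>,
#'   psi0 = <scalar>, psi = <vector>)`.
#' @param visit_times planned measurement times; visits after the observed
#'   event/censoring time are discarded (default yearly, 0..14).
#' @param censor_bound upper bound of the uniform censoring law (17.5).
#' @param age_mean,age_sd the age covariate law (45, 15.70).
#' @param seed integer seed; every generator is a pure function of
#'   (design, seed).
#' @return list of class `sim_design`.
#' @export
sim_design <- function(name = NULL, n = 900, truths = table2_truths(),
                       membership = list(type = "fixed_proportions",
                                         proportions = c(0.5, 0.5)),
                       visit_times = 0:14, censor_bound = 17.5,
                       age_mean = 45, age_sd = 15.70, seed = 1) {
  if (!is.null(name)) {
    membership <- switch(
      name,
      setting2_scenario1 = list(type = "fixed_proportions",
                                proportions = c(0.5, 0.5)),
      setting2_scenario2 = list(type = "softmax", covariates = "xtilde",
                                psi0 = -0.4, psi = 1),
      setting2_scenario3 = list(type = "softmax",
                                covariates = c("male", "age"),
                                psi0 = 2, psi = c(4, -0.1)),
      setting2_scenario4 = list(type = "softmax",
                                covariates = c("male", "age", "xtilde"),
                                psi0 = 2, psi = c(4, -0.1, 1)),
      stop("unknown design name: ", name))
  }
  G <- length(truths)
  if (membership$type == "fixed_proportions") {
    if (length(membership$proportions) != G ||
        abs(sum(membership$proportions) - 1) > 1e-8)
      stop("`proportions` must have length G and sum to 1")
  }
  if (censor_bound <= 0) stop("`censor_bound` must be > 0")
  structure(list(name = name, G = G, n = as.integer(n), truths = truths,
                 membership = membership,
                 visit_times = sort(unique(visit_times)),
                 censor_bound = censor_bound, age_mean = age_mean,
                 age_sd = age_sd, seed = as.integer(seed)),
            class = "sim_design")
}

#' Simulate baseline covariates
#'
#' `male ~ Bernoulli(0.5)`, `age ~ Normal(age_mean, age_sd^2)`,
#' `xtilde ~ Normal(0, 1)`.
#'
#' @param n sample size.
#' @param seed integer seed.
#' @param age_mean,age_sd age law parameters.
#' @return data frame with columns `id`, `male`, `age`, `xtilde`.
#' @export
simulate_covariates <- function(n, seed = 1, age_mean = 45, age_sd = 15.70) {
  set.seed(seed)
  data.frame(id = seq_len(n),
             male = stats::rbinom(n, 1, 0.5),
             age = stats::rnorm(n, age_mean, age_sd),
             xtilde = stats::rnorm(n))
}

#' Assign latent class labels
#'
#' Fixed-proportion designs draw iid categorical labels; softmax designs
#' compute each subject's membership probabilities from the design's
#' `psi` values via [membership_probs()] and draw from them.
#'
#' @param design a [sim_design()].
#' @param covariates output of [simulate_covariates()].
#' @param seed integer seed.
#' @return integer labels in `1..G`.
#' @export
assign_classes <- function(design, covariates, seed = 1) {
  set.seed(seed)
  n <- nrow(covariates)
  m <- design$membership
  if (m$type == "fixed_proportions") {
    return(sample.int(design$G, n, replace = TRUE, prob = m$proportions))
  }
  W <- as.matrix(covariates[, m$covariates, drop = FALSE])
  psi <- matrix(m$psi, nrow = design$G - 1L, byrow = TRUE)
  vapply(seq_len(n), function(i) {
    pr <- membership_probs(m$psi0, psi, W[i, ], design$G)
    sample.int(design$G, 1L, prob = pr)
  }, integer(1))
}

#' Simulate class-specific longitudinal trajectories
#'
#' `y_i(t) = beta_g0 + beta_g1 t + b_ig0 + b_ig1 t + beta_g2 male_i +
#' eps_ig(t)` with `b_ig ~ N(0, Sigma_g)` and iid Gaussian noise, evaluated
#' on the full visit schedule (truncation to the observation window happens
#' when the dataset is assembled).
#'
#' @param labels class labels.
#' @param covariates covariate table.
#' @param truths per-class [class_params()].
#' @param visit_times measurement schedule.
#' @param seed integer seed.
#' @return list with `long` (id, time, y) and `b` (n x 2 matrix of each
#'   subject's own-class random effects).
#' @export
simulate_longitudinal <- function(labels, covariates, truths,
                                  visit_times = 0:14, seed = 1) {
  set.seed(seed)
  n <- length(labels)
  nt <- length(visit_times)
  b <- matrix(NA_real_, n, 2)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cp <- truths[[labels[i]]]
    b[i, ] <- stats::rnorm(2, 0, sqrt(cp$Sigma_diag))
    mu <- cp$beta[1] + cp$beta[2] * visit_times + b[i, 1] +
      b[i, 2] * visit_times + cp$beta[3] * covariates$male[i]
    y <- mu + stats::rnorm(nt, 0, sqrt(cp$sigma2))
    rows[[i]] <- data.frame(id = covariates$id[i], time = visit_times, y = y)
  }
  list(long = do.call(rbind, rows), b = b)
}

# cumulative hazard of the generating model: phi0 * int_0^t s^(phi0-1)
# exp(c0 + c1 s) ds by Gauss-Legendre (same rule as the likelihood)
sim_cumhaz <- function(t, phi0, c0, c1, gl) {
  s <- t / 2 * (gl$x + 1)
  w <- t / 2 * gl$w
  sum(w * exp(log(phi0) + (phi0 - 1) * log(s) + c0 + c1 * s))
}

#' Simulate event and censoring times
#'
#' Event times solve `H(t) = -log U` by bracketed root finding on the
#' generating cumulative hazard (evaluated with the same Gauss-Legendre
#' rule as the likelihood); censoring is uniform on `(0, censor_bound)`.
#' Subjects whose cumulative hazard never reaches the target before a
#' horizon of `10 * censor_bound` are censored and counted in the
#' `n_horizon` diagnostic.
#'
#' @param labels class labels.
#' @param covariates covariate table.
#' @param b matrix of own-class random effects (from
#'   [simulate_longitudinal()]).
#' @param truths per-class [class_params()].
#' @param censor_bound uniform censoring upper bound.
#' @param seed integer seed.
#' @return list with `surv` (id, time, event + covariates), `T_star`, `C`
#'   and `n_horizon`.
#' @export
simulate_event_times <- function(labels, covariates, b, truths,
                                 censor_bound = 17.5, seed = 1) {
  set.seed(seed)
  n <- length(labels)
  gl <- gl_rule(15)
  horizon <- 10 * censor_bound
  targets <- stats::rexp(n)
  C <- stats::runif(n, 0, censor_bound)
  T_star <- numeric(n)
  for (i in seq_len(n)) {
    cp <- truths[[labels[i]]]
    c0 <- cp$phi1 + cp$gamma[1] * covariates$age[i] +
      cp$alpha * (cp$beta[1] + cp$beta[3] * covariates$male[i] + b[i, 1])
    c1 <- cp$alpha * (cp$beta[2] + b[i, 2])
    Hh <- sim_cumhaz(horizon, cp$phi0, c0, c1, gl)
    if (!is.finite(Hh) || Hh < targets[i]) {
      T_star[i] <- Inf
    } else {
      T_star[i] <- stats::uniroot(
        function(t) sim_cumhaz(t, cp$phi0, c0, c1, gl) - targets[i],
        lower = 1e-10, upper = horizon, tol = 1e-10)$root
    }
  }
  Tobs <- pmin(T_star, C)
  surv <- data.frame(id = covariates$id, time = Tobs,
                     event = as.integer(T_star <= C))
  surv <- cbind(surv, covariates[, setdiff(names(covariates), "id"),
                                 drop = FALSE])
  list(surv = surv, T_star = T_star, C = C,
       n_horizon = sum(is.infinite(T_star)))
}

#' Simulate a complete joint dataset with ground truth
#'
#' Composes the covariate, class-assignment, longitudinal and event-time
#' generators; visits after the observed time are discarded. Fully
#' reproducible: every sub-generator receives a seed derived from
#' `design$seed`.
#'
#' @param design a [sim_design()].
#' @return list with `data` (a [jlcm_data()]), `truth` (labels, random
#'   effects, latent event/censoring times, horizon-censoring count) and
#'   the `design`.
#' @export
simulate_dataset <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  s <- design$seed
  cov <- simulate_covariates(design$n, seed = s, age_mean = design$age_mean,
                             age_sd = design$age_sd)
  labels <- assign_classes(design, cov, seed = s + 1L)
  lng <- simulate_longitudinal(labels, cov, design$truths,
                               design$visit_times, seed = s + 2L)
  ev <- simulate_event_times(labels, cov, lng$b, design$truths,
                             design$censor_bound, seed = s + 3L)
  Tmap <- stats::setNames(ev$surv$time, as.character(ev$surv$id))
  long <- lng$long[lng$long$time <= Tmap[as.character(lng$long$id)] + 1e-12, ]
  # every subject keeps at least the baseline visit (T > 0 a.s.)
  data <- jlcm_data(long, ev$surv)
  list(data = data,
       truth = list(labels = labels, b = lng$b, T_star = ev$T_star,
                    C = ev$C, n_horizon = ev$n_horizon),
       design = design)
}

#' Model specification matching the simulation designs
#'
#' The estimation models used with the simulated data: `membership_model =
#' 1` assumes homogeneous membership probabilities; `membership_model = 2`
#' lets membership depend on gender and age (correctly specified for
#' scenario 3).
#'
#' @param G number of classes.
#' @param membership_model 1 (no membership covariates) or 2 (gender + age).
#' @return a [jlcm_spec()].
#' @export
scenario_spec <- function(G = 2, membership_model = 2) {
  jlcm_spec(G = G, fixed = y ~ time + male, random = ~ time,
            survival = ~ age,
            membership = if (membership_model == 2) ~ male + age else NULL,
            association = "current_value")
}
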