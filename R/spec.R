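#' Specify a shared-parameter joint latent class model
#'
#' Describes the structure of the joint model: the number of latent classes,
#' the fixed- and random-effect designs of the class-specific linear mixed
#' longitudinal submodel, the exogenous risk covariates of the Weibull
#' proportional-hazards submodel, the covariates of the softmax class
#' membership submodel, and the association structure linking the two
#' processes.
#'
#' Design formulas are evaluated against the *baseline* (survival) table with
#' an added `time` column, so they may use the time variable, any baseline
#' covariate, and transformations of either (e.g. `~ time + I(time^2) + male`
#' or `~ I((age - 65)/10)`). The longitudinal table contributes only the
#' subject id, the visit times and the response; covariates entering any
#' design must be time-constant and live in the survival table.
#'
#' For the `current_slope` association the time derivative of the mean
#' trajectory is required. It is declared, not derived: supply `fixed_slope`
#' and `random_slope` as formulas (or functions of the design frame returning
#' a matrix) that evaluate to the derivative of each column of the
#' corresponding design with respect to time. For the default linear design
#' `~ time` the derivative rows are `(0, 1)`, declared as
#' `~ 0 + I(0 * time) + I(1 + 0 * time)`.
#'
#' @param G number of latent classes (>= 1).
#' @param fixed two-sided formula `response ~ ...` for the fixed-effect
#'   design of the longitudinal submodel.
#' @param random one-sided formula for the random-effect design; its column
#'   count is the random-effect dimension `r`.
#' @param survival one-sided formula for the exogenous risk covariates
#'   (no intercept column is kept: the log-scale intercept of the Weibull
#'   baseline hazard plays that role).
#' @param membership one-sided formula for the class-membership covariates,
#'   or `NULL` for homogeneous membership probabilities.
#' @param association `"current_value"`, `"current_slope"`, or `"none"`.
#'   With `"none"` the hazard does not depend on the random effects and the
#'   model reduces to the basic joint latent class model.
#' @param n_quad Gauss-Legendre quadrature order used for the cumulative
#'   hazard integral (default 15).
#' @param fixed_slope,random_slope declared time derivatives of `fixed` /
#'   `random` (see Details); required when `association = "current_slope"`.
#' @param time,id names of the time and subject-id columns.
#'
#' @return an object of class `jlcm_spec`.
#' @export
#' @examples
#' jlcm_spec(G = 2, fixed = y ~ time + male, random = ~ time,
#'           survival = ~ age, membership = ~ male + age)
jlcm_spec <- function(G, fixed = y ~ time, random = ~ time,
                      survival = ~ 1, membership = NULL,
                      association = c("current_value", "current_slope", "none"),
                      n_quad = 15, fixed_slope = NULL, random_slope = NULL,
                      time = "time", id = "id") {
  association <- match.arg(association)
  if (!is.numeric(G) || length(G) != 1L || G < 1 || G != round(G))
    stop("`G` must be a single integer >= 1")
  if (n_quad < 2) stop("`n_quad` must be >= 2")
  if (length(fixed) != 3L) stop("`fixed` must be a two-sided formula")
  if (association == "current_slope" &&
      (is.null(fixed_slope) || is.null(random_slope)))
    stop("current_slope association requires declared `fixed_slope` and ",
         "`random_slope` derivative designs")
  structure(
    list(G = as.integer(G), fixed = fixed, random = random,
         survival = survival, membership = membership,
         association = association, n_quad = as.integer(n_quad),
         fixed_slope = fixed_slope, random_slope = random_slope,
         time = time, id = id),
    class = "jlcm_spec")
}

#' @export
print.jlcm_spec <- function(x, ...) {
  cat("Shared-parameter JLCM specification\n")
  cat("  classes (G):      ", x$G, "\n")
  cat("  fixed:            ", deparse(x$fixed), "\n")
  cat("  random:           ", deparse(x$random), "\n")
  cat("  survival:         ", deparse(x$survival), "\n")
  cat("  membership:       ",
      if (is.null(x$membership)) "(intercept only)" else deparse(x$membership), "\n")
  cat("  association:      ", x$association, "\n")
  cat("  quadrature order: ", x$n_quad, "\n")
  invisible(x)
}

# evaluate a design description (formula or function) on a frame that holds
# the time column and the baseline covariates; returns a numeric matrix
eval_design <- function(desc, df, drop_intercept = FALSE) {
  if (is.null(desc)) return(matrix(0, nrow(df), 0))
  if (is.function(desc)) {
    m <- desc(df)
    if (!is.matrix(m) || nrow(m) != nrow(df)) stop("design function must return a matrix with one row per input row")
    return(m)
  }
  m <- stats::model.matrix(desc, df)
  if (drop_intercept) {
    keep <- colnames(m) != "(Intercept)"
    m <- m[, keep, drop = FALSE]
  }
  m
}

# functions of time returning design rows for one subject (baseline row `cov`)
subject_design_fns <- function(spec, cov) {
  cov <- as.data.frame(cov)
  fx <- function(t) {
    df <- cov[rep(1L, length(t)), , drop = FALSE]
    df[[spec$time]] <- t
    eval_design(stats::delete.response(stats::terms(spec$fixed)), df)
  }
  fz <- function(t) {
    df <- cov[rep(1L, length(t)), , drop = FALSE]
    df[[spec$time]] <- t
    eval_design(spec$random, df)
  }
  fxs <- fzs <- NULL
  if (!is.null(spec$fixed_slope)) {
    fxs <- function(t) {
      df <- cov[rep(1L, length(t)), , drop = FALSE]
      df[[spec$time]] <- t
      eval_design(spec$fixed_slope, df, drop_intercept = TRUE)
    }
  }
  if (!is.null(spec$random_slope)) {
    fzs <- function(t) {
      df <- cov[rep(1L, length(t)), , drop = FALSE]
      df[[spec$time]] <- t
      eval_design(spec$random_slope, df, drop_intercept = TRUE)
    }
  }
  list(fx = fx, fz = fz, fxs = fxs, fzs = fzs)
}
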