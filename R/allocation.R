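# Posterior latent-class allocation: exact draws of the class indicators
# from their full conditional, empirical membership probabilities, MAP
# labels and the effective class size.

#' Full-conditional class weights of one subject under one draw
#'
#' The categorical full conditional of the latent indicator: weights
#' proportional to `p(y_i | b_ig, g) p(T_i, Delta_i | b_ig, g) pi_ig`,
#' normalized in log space.
#'
#' @param i subject index.
#' @param draw a natural-scale parameter draw.
#' @param data a [jlcm_data()] object.
#' @param spec a [jlcm_spec()] object.
#' @return probability vector of length `G`.
#' @export
class_weights_per_draw <- function(i, draw, data, spec) {
  lw <- subject_class_logliks(i, draw, data, spec)
  m <- max(lw)
  if (!is.finite(m))
    stop("all class weights underflowed for subject ", i)
  w <- exp(lw - m)
  w / sum(w)
}

#' Sample latent class indicators for every retained draw
#'
#' For each retained draw `j` and subject `i`, draws one class label from
#' the exact full conditional evaluated at that draw's parameters and
#' random effects.
#'
#' @param chain a `jlcm_chain` (the selected chain).
#' @param seed integer seed for reproducibility.
#' @return integer matrix, draws by subjects, entries in `1..G`.
#' @export
sample_class_indicators <- function(chain, seed = 1) {
  md <- chain$md
  S <- nrow(chain$draws)
  n <- md$n; G <- md$G
  set.seed(seed)
  out <- matrix(NA_integer_, S, n)
  for (s in seq_len(S)) {
    lw <- jlcm_class_logweights_cpp(chain$draws[s, ], md)
    # Gumbel-max: exact categorical draw per subject, vectorized
    g <- -log(-log(matrix(stats::runif(n * G), n, G)))
    out[s, ] <- max.col(lw + g, ties.method = "first")
  }
  out
}

#' Posterior class membership probabilities from indicator draws
#'
#' Empirical per-subject frequencies of the sampled indicators; each row
#' sums to one exactly.
#'
#' @param indicators integer matrix (draws by subjects) from
#'   [sample_class_indicators()].
#' @param G number of classes (defaults to the largest label observed).
#' @return list of class `jlcm_membership` with `probs` (n by G matrix),
#'   `labels` (MAP labels) and the `indicators` themselves.
#' @export
posterior_class_probs <- function(indicators, G = max(indicators)) {
  S <- nrow(indicators)
  if (S < 1) stop("need at least one indicator draw")
  probs <- t(apply(indicators, 2, function(col) tabulate(col, G) / S))
  if (G == 1L) probs <- matrix(probs, ncol = 1L)
  structure(list(probs = probs, labels = map_assign(probs),
                 indicators = indicators),
            class = "jlcm_membership")
}

#' Maximum a posteriori class assignment
#'
#' Argmax of each subject's posterior membership probabilities; ties break
#' to the lowest class index.
#'
#' @param posterior a `jlcm_membership` object or a probability matrix.
#' @return integer label vector.
#' @export
map_assign <- function(posterior) {
  probs <- if (inherits(posterior, "jlcm_membership")) posterior$probs else posterior
  apply(as.matrix(probs), 1, which.max)
}

#' Effective number of classes
#'
#' Number of classes whose estimated posterior proportion (share of MAP
#' labels) strictly exceeds `threshold` — a guard against counting
#' near-empty classes produced by overfitted mixtures.
#'
#' @param labels integer MAP label vector (or a `jlcm_membership`).
#' @param threshold proportion threshold in `[0, 1)`.
#' @param G number of classes (defaults to the largest label).
#' @return integer count.
#' @export
effective_class_size <- function(labels, threshold = 0.01, G = NULL) {
  if (inherits(labels, "jlcm_membership")) labels <- labels$labels
  if (threshold < 0 || threshold >= 1) stop("`threshold` must be in [0, 1)")
  if (is.null(G)) G <- max(labels)
  prop <- tabulate(labels, G) / length(labels)
  sum(prop > threshold)
}
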