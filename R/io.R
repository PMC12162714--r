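# Result bundles: a fitted model is written as plain-text artifacts
# (columnar draws, diagnostics, membership, information criteria, and a
# provenance block sufficient to re-run the fit).

#' Write a fit result as a self-describing bundle
#'
#' @param fit a [jlcm_fit()] result.
#' @param dir output directory (created if missing).
#' @param data_paths optional named character vector recording where the
#'   input CSVs came from (stored in the provenance block).
#' @return invisibly, `dir`.
#' @export
write_fit_bundle <- function(fit, dir, data_paths = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(fit$chain$theta),
                   file.path(dir, "draws.csv"), row.names = FALSE)
  utils::write.csv(convergence_diagnostics(fit$chains),
                   file.path(dir, "diagnostics.csv"), row.names = FALSE)
  mem <- data.frame(id = fit$chain$md$ids %||% seq_len(nrow(fit$membership)),
                    fit$membership, label = fit$labels)
  names(mem) <- c("id", paste0("prob_class", seq_len(fit$G)), "label")
  utils::write.csv(mem, file.path(dir, "membership.csv"), row.names = FALSE)
  ic <- list(G = fit$G,   # *_se on the deviance scale, like the IC itself
             looic = fit$looic$ic, looic_se = 2 * fit$looic$se,
             waic = fit$waic$ic, waic_se = 2 * fit$waic$se,
             p_loo = fit$looic$p_eff, p_waic = fit$waic$p_eff,
             pointwise_elpd_loo = fit$looic$pointwise,
             pointwise_elpd_waic = fit$waic$pointwise,
             pareto_k = fit$looic$pareto_k,
             g_eff = fit$g_eff, class_threshold = fit$class_threshold,
             selected_chain = fit$selected,
             log_evidence = fit$log_evidence)
  jsonlite::write_json(ic, file.path(dir, "ic.json"), auto_unbox = TRUE,
                       digits = NA)
  cfg <- fit$chains$config
  prov <- list(package = "bjlcm",
               version = as.character(utils::packageVersion("bjlcm")),
               chains = cfg[c("M", "iter", "warmup", "thin", "base_seed",
                              "parameterization", "adapt_delta",
                              "perturb_scale", "max_treedepth", "beta_trunc",
                              "rhat_threshold")],
               chain_seeds = vapply(fit$chains$chains, `[[`, numeric(1), "seed"),
               priors = unclass(fit$priors),
               spec = list(G = fit$spec$G,
                           fixed = deparse(fit$spec$fixed),
                           random = deparse(fit$spec$random),
                           survival = deparse(fit$spec$survival),
                           membership = if (is.null(fit$spec$membership))
                             NULL else deparse(fit$spec$membership),
                           association = fit$spec$association,
                           n_quad = fit$spec$n_quad),
               data = as.list(data_paths))
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a fit bundle's model-comparison block
#'
#' Loads what [forward_select()] needs from a bundle directory: the
#' information criteria with their pointwise vectors and the effective
#' class count.
#'
#' @param dir bundle directory written by [write_fit_bundle()].
#' @return list with `G`, `ic` (LOOIC as a `jlcm_ic`), `ic_waic`, `g_eff`.
#' @export
read_fit_bundle_ic <- function(dir) {
  ic <- jsonlite::read_json(file.path(dir, "ic.json"), simplifyVector = TRUE)
  looic <- new_ic_result("looic", ic$pointwise_elpd_loo,
                         se = ic$looic_se / 2, p_eff = ic$p_loo,
                         pareto_k = ic$pareto_k)
  waic <- new_ic_result("waic", ic$pointwise_elpd_waic,
                        se = ic$waic_se / 2, p_eff = ic$p_waic)
  list(G = ic$G, ic = looic, ic_waic = waic, g_eff = ic$g_eff)
}
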