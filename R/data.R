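#' Assemble a joint longitudinal / survival dataset
#'
#' Joins a long-format longitudinal table (one row per visit) with a
#' one-row-per-subject survival table into a validated container used by all
#' fitting functions. Membership covariates are drawn from the survival
#' table by name at fit time.
#'
#' @param longitudinal data frame with columns `id`, `time`, `y` (names
#'   configurable via `id`, `time`, `y`).
#' @param survival data frame with columns `id`, `time` (observed event or
#'   censoring time), `event` (0/1), plus any baseline covariates.
#' @param id,time,y,event column names.
#' @return an object of class `jlcm_data`: a list with elements `long`
#'   (visits, sorted by id and time), `surv` (one row per subject) and `ids`.
#' @export
jlcm_data <- function(longitudinal, survival, id = "id", time = "time",
                      y = "y", event = "event") {
  longitudinal <- as.data.frame(longitudinal)
  survival <- as.data.frame(survival)
  need_l <- c(id, time, y)
  need_s <- c(id, time, event)
  miss_l <- setdiff(need_l, names(longitudinal))
  miss_s <- setdiff(need_s, names(survival))
  if (length(miss_l)) stop("longitudinal table lacks column(s): ",
                           paste(miss_l, collapse = ", "))
  if (length(miss_s)) stop("survival table lacks column(s): ",
                           paste(miss_s, collapse = ", "))
  if (anyDuplicated(survival[[id]]))
    stop("survival table has duplicated subject id(s): ",
         paste(unique(survival[[id]][duplicated(survival[[id]])]), collapse = ", "))
  key <- paste(longitudinal[[id]], longitudinal[[time]])
  if (anyDuplicated(key))
    stop("duplicate (id, time) rows in longitudinal table: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  ids_l <- unique(longitudinal[[id]])
  ids_s <- survival[[id]]
  only_l <- setdiff(ids_l, ids_s)
  only_s <- setdiff(ids_s, ids_l)
  if (length(only_l)) stop("subject(s) present only in longitudinal table: ",
                           paste(only_l, collapse = ", "))
  if (length(only_s)) stop("subject(s) present only in survival table: ",
                           paste(only_s, collapse = ", "))
  ev <- survival[[event]]
  if (!all(ev %in% c(0, 1))) stop("`", event, "` must be 0/1")
  if (any(!is.finite(survival[[time]])) || any(survival[[time]] < 0))
    stop("observed times must be finite and >= 0")
  if (any(survival[[time]] == 0 & ev == 1))
    stop("event indicated at time 0 for subject(s): ",
         paste(ids_s[survival[[time]] == 0 & ev == 1], collapse = ", "))
  if (any(!is.finite(longitudinal[[y]])))
    stop("non-finite longitudinal responses")
  if (any(!is.finite(longitudinal[[time]])) || any(longitudinal[[time]] < 0))
    stop("visit times must be finite and >= 0")
  # visits after the observed event/censoring time are inconsistent
  Tmap <- stats::setNames(survival[[time]], as.character(ids_s))
  late <- longitudinal[[time]] > Tmap[as.character(longitudinal[[id]])] + 1e-8
  if (any(late)) {
    bad <- longitudinal[late, c(id, time)]
    stop("visit(s) after the observed survival time: ",
         paste(sprintf("subject %s at t=%g", bad[[id]], bad[[time]]),
               collapse = "; "))
  }

  ord_s <- order(ids_s)
  survival <- survival[ord_s, , drop = FALSE]
  ord_l <- order(match(longitudinal[[id]], survival[[id]]), longitudinal[[time]])
  longitudinal <- longitudinal[ord_l, , drop = FALSE]
  rownames(longitudinal) <- rownames(survival) <- NULL
  structure(list(long = longitudinal, surv = survival, ids = survival[[id]],
                 cols = list(id = id, time = time, y = y, event = event)),
            class = "jlcm_data")
}

#' @export
print.jlcm_data <- function(x, ...) {
  cat("Joint dataset:", length(x$ids), "subjects,",
      nrow(x$long), "longitudinal measurements,",
      sprintf("%.1f%% events\n", 100 * mean(x$surv[[x$cols$event]])))
  invisible(x)
}

#' Number of subjects in a joint dataset
#' @param data a `jlcm_data` object.
#' @return integer subject count.
#' @export
n_subjects <- function(data) length(data$ids)

#' Read a joint dataset from two CSV files
#'
#' @param long_csv path to the longitudinal CSV (columns `id`, `time`, `y`,
#'   plus covariates).
#' @param surv_csv path to the survival CSV (columns `id`, `time`, `event`,
#'   plus baseline covariates).
#' @param ... column-name overrides passed to [jlcm_data()].
#' @return a `jlcm_data` object.
#' @export
read_joint_dataset <- function(long_csv, surv_csv, ...) {
  jlcm_data(utils::read.csv(long_csv), utils::read.csv(surv_csv), ...)
}

#' Write a joint dataset to two CSV files
#'
#' @param data a `jlcm_data` object.
#' @param long_csv,surv_csv output paths.
#' @return invisibly, the two paths.
#' @export
write_joint_dataset <- function(data, long_csv, surv_csv) {
  utils::write.csv(data$long, long_csv, row.names = FALSE)
  utils::write.csv(data$surv, surv_csv, row.names = FALSE)
  invisible(c(long_csv, surv_csv))
}
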