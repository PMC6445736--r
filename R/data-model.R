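#' Longitudinal biomarker data
#'
#' Constructs a `longitudinal_data` object: long-format repeated
#' measurements with one row per (subject, visit).  Rows are canonicalised
#' to be sorted by subject id and, within subject, strictly increasing in
#' time; duplicated (id, time) pairs are an error.
#'
#' @param id vector of subject identifiers (coerced to character).
#' @param time numeric measurement times in years since baseline
#'   (non-negative).
#' @param value numeric biomarker values (e.g. SBP in mmHg).
#' @return A data frame of class `longitudinal_data` with columns
#'   `id`, `time`, `value`.
#' @seealso [read_long_csv()], [naive_estimates()]
#' @export
longitudinal_data <- function(id, time, value) {
  df <- data.frame(id = as.character(id), time = as.numeric(time),
                   value = as.numeric(value), stringsAsFactors = FALSE)
  validate_longitudinal(df)
}

validate_longitudinal <- function(df, where = "longitudinal data") {
  stopifnot(all(c("id", "time", "value") %in% names(df)))
  if (anyNA(df$time) || anyNA(df$value) || anyNA(df$id))
    stop(where, ": missing values are not allowed", call. = FALSE)
  if (any(df$time < 0))
    stop(where, ": negative measurement times", call. = FALSE)
  key <- paste(df$id, df$time, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf("%s: duplicate (id, time) pair: id='%s', time=%g",
                 where, d$id, d$time), call. = FALSE)
  }
  df <- df[order(df$id, df$time), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("longitudinal_data", "data.frame")
  df
}

#' Per-subject survival data
#'
#' @param id vector of unique subject identifiers.
#' @param time positive follow-up times in years
#'   (`T* = min(event time, censoring time)`).
#' @param status event indicator, 0 = censored, 1 = event.
#' @return A data frame of class `survival_data` with columns `id`,
#'   `time`, `status`.
#' @export
survival_data <- function(id, time, status) {
  df <- data.frame(id = as.character(id), time = as.numeric(time),
                   status = as.integer(status), stringsAsFactors = FALSE)
  validate_survival(df)
}

validate_survival <- function(df, where = "survival data") {
  stopifnot(all(c("id", "time", "status") %in% names(df)))
  if (anyNA(df)) stop(where, ": missing values are not allowed", call. = FALSE)
  if (anyDuplicated(df$id))
    stop(where, ": duplicated subject id: ",
         df$id[duplicated(df$id)][1L], call. = FALSE)
  if (any(df$time <= 0)) stop(where, ": follow-up times must be > 0", call. = FALSE)
  if (!all(df$status %in% c(0L, 1L)))
    stop(where, ": status must be 0 or 1", call. = FALSE)
  df$status <- as.integer(df$status)
  df$time <- as.numeric(df$time)
  df <- df[order(df$id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("survival_data", "data.frame")
  df
}

#' Baseline covariate table
#'
#' One row per subject; an `id` column plus real-valued covariate columns
#' (already encoded, no missing entries).
#'
#' @param df data frame with an `id` column and numeric covariates.
#' @return A data frame of class `covariate_table`.
#' @export
covariate_table <- function(df) {
  stopifnot("id" %in% names(df))
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id))
    stop("covariate table: duplicated subject id", call. = FALSE)
  if (anyDuplicated(names(df)))
    stop("covariate table: duplicated column names", call. = FALSE)
  if (anyNA(df)) stop("covariate table: missing entries", call. = FALSE)
  num <- setdiff(names(df), "id")
  for (v in num) df[[v]] <- as.numeric(df[[v]])
  df <- df[order(df$id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("covariate_table", "data.frame")
  df
}

#' Assemble an analysis dataset
#'
#' Bundles longitudinal measurements, survival outcomes and (optionally)
#' baseline covariates.  Every subject with measurements must have a
#' survival record.  If `t_sep` is set the object represents the
#' separated-follow-up layout produced by [separate_followup()]: all
#' measurement times lie in `[0, t_sep)` on the original clock and
#' survival times are expressed as time since `t_sep`.
#'
#' @param longitudinal a [longitudinal_data()] object (or coercible data
#'   frame with columns id, time, value).
#' @param survival a [survival_data()] object (or data frame with columns
#'   id, time, status).
#' @param covariates optional [covariate_table()].
#' @param t_sep optional separation time in years (see
#'   [separate_followup()]).
#' @return An object of class `analysis_dataset`: a list with elements
#'   `longitudinal`, `survival`, `covariates`, `t_sep`.
#' @export
analysis_dataset <- function(longitudinal, survival, covariates = NULL,
                             t_sep = NULL) {
  longitudinal <- validate_longitudinal(as.data.frame(longitudinal))
  survival <- validate_survival(as.data.frame(survival))
  if (!is.null(covariates)) covariates <- covariate_table(as.data.frame(covariates))
  missing_ids <- setdiff(unique(longitudinal$id), survival$id)
  if (length(missing_ids))
    stop("subjects with measurements but no survival record: ",
         paste(utils::head(missing_ids, 5L), collapse = ", "), call. = FALSE)
  if (!is.null(covariates)) {
    missing_cov <- setdiff(survival$id, covariates$id)
    if (length(missing_cov))
      stop("subjects missing from covariate table: ",
           paste(utils::head(missing_cov, 5L), collapse = ", "), call. = FALSE)
  }
  out <- structure(list(longitudinal = longitudinal, survival = survival,
                        covariates = covariates, t_sep = t_sep),
                   class = "analysis_dataset")
  out
}

#' @export
print.analysis_dataset <- function(x, ...) {
  n_subj <- nrow(x$survival)
  n_obs <- nrow(x$longitudinal)
  cat("<analysis_dataset>\n")
  cat(sprintf("  subjects: %d  (events: %d, censored: %d)\n", n_subj,
              sum(x$survival$status == 1L), sum(x$survival$status == 0L)))
  cat(sprintf("  measurements: %d  (%.2f per subject with measurements)\n",
              n_obs, n_obs / length(unique(x$longitudinal$id))))
  if (!is.null(x$t_sep))
    cat(sprintf("  separated follow-up: t_sep = %g y (survival clock origin reset)\n",
                x$t_sep))
  if (!is.null(x$covariates))
    cat("  baseline covariates:",
        paste(setdiff(names(x$covariates), "id"), collapse = ", "), "\n")
  invisible(x)
}

#' Separate longitudinal from survival follow-up
#'
#' Splits follow-up at `t_sep`: only measurements taken strictly before
#' `t_sep` are retained for the longitudinal model, and survival analysis
#' is conditional on being at risk at `t_sep`.  Subjects whose follow-up
#' ends at or before `t_sep` (event or censoring) are dropped entirely,
#' and the survival clock of the remaining subjects is reset so that time
#' 0 corresponds to `t_sep`.  This removes informative truncation of the
#' measurement stream by the event at the cost of discarding the dropped
#' information.
#'
#' Applying the function twice with the same `t_sep` is a no-op the second
#' time (the dataset records its separation time).
#'
#' @param data an [analysis_dataset()].
#' @param t_sep separation time in years, > 0 (original clock).
#' @param quiet suppress the message reporting dropped counts.
#' @return A new `analysis_dataset` with `t_sep` recorded.
#' @export
separate_followup <- function(data, t_sep, quiet = FALSE) {
  stopifnot(inherits(data, "analysis_dataset"), is.numeric(t_sep),
            length(t_sep) == 1L, t_sep > 0)
  if (!is.null(data$t_sep)) {
    if (isTRUE(all.equal(data$t_sep, t_sep))) return(data)
    stop("dataset already separated at t_sep = ", data$t_sep, call. = FALSE)
  }
  surv <- data$survival
  keep_subj <- surv$time > t_sep
  if (!any(keep_subj))
    stop("no survival follow-up remains after t_sep = ", t_sep, call. = FALSE)
  n_drop_subj <- sum(!keep_subj)
  surv <- surv[keep_subj, , drop = FALSE]
  surv$time <- surv$time - t_sep

  long <- data$longitudinal
  keep_meas <- long$time < t_sep & long$id %in% surv$id
  n_drop_meas <- nrow(long) - sum(keep_meas)
  long <- long[keep_meas, , drop = FALSE]

  cov <- data$covariates
  if (!is.null(cov)) cov <- cov[cov$id %in% surv$id, , drop = FALSE]
  if (!quiet)
    message(sprintf(
      "separate_followup: dropped %d subject(s) with follow-up ending at or before t_sep, %d measurement(s)",
      n_drop_subj, n_drop_meas))
  analysis_dataset(long, surv, cov, t_sep = t_sep)
}
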