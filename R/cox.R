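#' Cox proportional-hazards fit for subject-level covariates
#'
#' Stage two of the two-stage procedure: a semiparametric Cox regression
#' `h_i(t) = h0(t) exp(alpha' U_i + gamma' W_i)` of the survival outcome
#' on per-subject covariates (estimated usual level and variability plus
#' any baseline covariates).  Estimation is by maximum partial likelihood
#' with the Efron tie correction; standard errors come from the inverse
#' observed information, and 95% intervals are Wald
#' (`estimate +/- 1.96 SE`).  Covariate uncertainty from stage one is not
#' propagated: `U_i` is treated as fixed.
#'
#' @param covariates data frame with an `id` column and numeric covariate
#'   columns (`U_i` and `W_i` together).
#' @param survival a [survival_data()] object.
#' @return An object of class `cox_fit`: list with `coefficients`, `se`,
#'   `vcov`, `ci` (2-column matrix), `n_subjects`, `n_events`, and the
#'   underlying `survival::coxph` fit as `fit`.
#' @export
fit_cox <- function(covariates, survival) {
  survival <- validate_survival(as.data.frame(survival))
  stopifnot(is.data.frame(covariates), "id" %in% names(covariates))
  vars <- setdiff(names(covariates), "id")
  if (!length(vars)) stop("no covariate columns", call. = FALSE)
  df <- merge(as.data.frame(survival), covariates, by = "id")
  if (nrow(df) == 0L) stop("no subjects with both survival and covariates",
                           call. = FALSE)
  if (sum(df$status) == 0L) stop("no events in the data", call. = FALSE)
  if (anyNA(df[vars])) stop("missing covariate values", call. = FALSE)

  fml <- stats::as.formula(paste("survival::Surv(time, status) ~",
                                 paste(sprintf("`%s`", vars), collapse = " + ")))
  warn <- NULL
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "efron"),
    warning = function(w) {
      warn <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    })
  cf <- coef(fit)
  if (anyNA(cf) || (!is.null(warn) && grepl("singular", warn)))
    stop("covariate matrix is rank deficient (collinear columns: ",
         paste(names(cf)[is.na(cf)], collapse = ", "), ")", call. = FALSE)
  if (!is.null(warn) && grepl("infinite|did not converge|out of range", warn))
    stop("Cox partial likelihood did not converge (possible monotone ",
         "likelihood / separation): ", warn, call. = FALSE)
  se <- sqrt(diag(fit$var))
  names(cf) <- names(se) <- vars
  ci <- cbind(lower = cf - qnorm(0.975) * se, upper = cf + qnorm(0.975) * se)
  rownames(ci) <- vars
  structure(list(coefficients = cf, se = se, vcov = fit$var, ci = ci,
                 n_subjects = nrow(df), n_events = sum(df$status),
                 fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> %d subjects, %d events\n", x$n_subjects, x$n_events))
  print(data.frame(logHR = x$coefficients, se = x$se,
                   lower95 = x$ci[, 1L], upper95 = x$ci[, 2L],
                   z = x$coefficients / x$se))
  invisible(x)
}

#' @export
coef.cox_fit <- function(object, ...) object$coefficients

#' @export
vcov.cox_fit <- function(object, ...) object$vcov

#' Two-stage association fit: longitudinal estimates into a Cox model
#'
#' Stage one estimates each subject's usual level and variability either
#' naively ([naive_estimates()]) or by the posterior means of a
#' location-scale mixed model ([fit_locscale()] + [subject_effects()]).
#' Stage two enters these as covariates `U_i` in a Cox regression,
#' optionally adjusted for baseline covariates `W_i`
#' (`spec$survival_covariates`).  Subjects without stage-one estimates
#' (too few measurements for the naive method) are dropped from stage
#' two.
#'
#' @param data an [analysis_dataset()].
#' @param stage1 `"naive"` or a [model_spec()] for an `lmm*` model.
#' @param mcmc an [mcmc_control()] (ignored for the naive method).
#' @param min_measurements minimum measurement count for the naive
#'   method.
#' @param sd_denominator naive SD denominator, `"n"` or `"n-1"`.
#' @return A `cox_fit`; the stage-one output is attached as attribute
#'   `"stage1"`.
#' @export
two_stage_fit <- function(data, stage1 = "naive", mcmc = mcmc_control(),
                          min_measurements = 2,
                          sd_denominator = c("n", "n-1")) {
  stopifnot(inherits(data, "analysis_dataset"))
  if (identical(stage1, "naive")) {
    est <- naive_estimates(data, min_measurements = min_measurements,
                           sd_denominator = match.arg(sd_denominator))
    U <- data.frame(id = est$id, level = est$mean, sd = est$sd,
                    stringsAsFactors = FALSE)
    wvars <- character()
  } else {
    stopifnot(inherits(stage1, "model_spec"))
    est <- subject_effects(fit_locscale(data, stage1, mcmc))
    U <- data.frame(id = est$id, level = est$bp_hat, sd = est$sd_hat,
                    stringsAsFactors = FALSE)
    if (!is.null(est$slope_hat)) U$slope <- est$slope_hat
    wvars <- stage1$survival_covariates
  }
  if (length(wvars)) {
    cov <- data$covariates
    missing <- setdiff(wvars, names(cov))
    if (length(missing)) stop("survival covariate(s) not found: ",
                              paste(missing, collapse = ", "), call. = FALSE)
    U <- merge(U, cov[c("id", wvars)], by = "id")
  }
  out <- fit_cox(U, data$survival)
  attr(out, "stage1") <- est
  out
}
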