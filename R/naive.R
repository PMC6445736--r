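#' Naive per-subject estimates of usual level and variability
#'
#' Computes, for each subject, the estimators customarily used in the
#' cardiovascular literature: the mean of the repeated measurements as
#' the usual level and their dispersion as the visit-to-visit
#' variability, plus the coefficient of variation (CV = SD/mean) and the
#' average real variability (ARV, the mean absolute change between
#' successive time-ordered visits).
#'
#' The variability is `sqrt(sum((Y_ij - mean_i)^2) / d_i)` with
#' `d_i = n_i` (`sd_denominator = "n"`, the population form) or
#' `d_i = n_i - 1` (`"n-1"`, the sample SD common in applied work).
#' Subjects with fewer than `min_measurements` measurements are excluded
#' and counted in the `n_excluded` attribute.
#'
#' @param data a [longitudinal_data()] object (or an
#'   [analysis_dataset()], whose longitudinal component is used).
#' @param min_measurements minimum measurements per retained subject
#'   (>= 2; the SD is undefined below 2).
#' @param sd_denominator `"n"` or `"n-1"`.
#' @param quiet suppress the message reporting excluded subjects.
#' @return A data frame of class `naive_estimates` with columns `id`,
#'   `n_used`, `mean`, `sd`, `cv`, `arv`; attribute `excluded` holds the
#'   ids of excluded subjects.
#' @export
naive_estimates <- function(data, min_measurements = 2,
                            sd_denominator = c("n", "n-1"), quiet = TRUE) {
  if (inherits(data, "analysis_dataset")) data <- data$longitudinal
  data <- validate_longitudinal(as.data.frame(data))
  sd_denominator <- match.arg(sd_denominator)
  stopifnot(min_measurements >= 2)
  if (nrow(data) == 0L) stop("no measurements", call. = FALSE)

  idx <- split(seq_len(nrow(data)), data$id)
  n_i <- lengths(idx)
  keep <- n_i >= min_measurements
  if (!any(keep))
    stop("all subjects have fewer than ", min_measurements,
         " measurements", call. = FALSE)
  excluded <- names(idx)[!keep]
  if (length(excluded) && !quiet)
    message("naive_estimates: excluded ", length(excluded),
            " subject(s) with fewer than ", min_measurements, " measurements")

  est <- lapply(idx[keep], function(ii) {
    y <- data$value[ii]                 # already time-ordered per subject
    n <- length(y)
    m <- mean(y)
    denom <- if (sd_denominator == "n") n else n - 1
    s <- sqrt(sum((y - m)^2) / denom)
    c(n_used = n, mean = m, sd = s,
      cv = if (m != 0) s / m else NA_real_,
      arv = mean(abs(diff(y))))
  })
  out <- data.frame(id = names(idx)[keep],
                    do.call(rbind, est),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "excluded") <- excluded
  attr(out, "sd_denominator") <- sd_denominator
  class(out) <- c("naive_estimates", "data.frame")
  out
}
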