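#' Brooks-Gelman potential scale reduction factor
#'
#' Computes the corrected potential scale reduction factor for one
#' parameter from `m >= 2` chains of equal retained length `n`.  With
#' within-chain variance `W` (mean of the per-chain sample variances) and
#' between-chain variance `B` (`n` times the sample variance of the chain
#' means), the statistic is
#' `Rhat = sqrt( ((n-1)/n * W + (m+1)/(m*n) * B) / W )`.
#' For converged chains Rhat is close to 1; values above about 1.05
#' indicate that the chains have not mixed.  For finite `n` the statistic
#' can dip slightly below 1 (to `sqrt((n-1)/n)` when the chains are
#' identical).
#'
#' @param x a `locscale_fit` / `joint_fit`, a list of numeric vectors
#'   (one per chain), or a matrix with one column per chain.
#' @param param parameter name (required for fit objects).
#' @return The scalar potential scale reduction factor.
#' @export
gelman_rubin <- function(x, param = NULL) {
  if (inherits(x, c("locscale_fit", "joint_fit"))) {
    if (is.null(param)) stop("'param' is required for fit objects", call. = FALSE)
    if (!param %in% colnames(x$draws[[1L]]))
      stop("unknown parameter: ", param, call. = FALSE)
    chains <- lapply(x$draws, function(m) m[, param])
  } else if (is.matrix(x)) {
    chains <- lapply(seq_len(ncol(x)), function(j) x[, j])
  } else if (is.list(x)) {
    chains <- lapply(x, as.numeric)
  } else stop("cannot interpret 'x' as chains", call. = FALSE)

  m <- length(chains)
  if (m < 2L) stop("at least 2 chains are required", call. = FALSE)
  n <- unique(lengths(chains))
  if (length(n) != 1L) stop("chains must have equal length", call. = FALSE)
  if (n < 2L) stop("chains too short", call. = FALSE)

  means <- vapply(chains, mean, 0)
  vars <- vapply(chains, var, 0)
  W <- mean(vars)
  B_over_n <- var(means)               # = B / n
  if (W == 0) return(if (B_over_n == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + (m + 1) / m * B_over_n) / W)
}
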