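#' Model specification for location-scale mixed and joint models
#'
#' The four longitudinal specifications share one naming scheme:
#' `lmm1`/`jm1` random intercept, no correlation between the intercept
#' and the log residual SD; `lmm2`/`jm2` random intercept with
#' correlation; `lmm3`/`jm3` random intercept and slope, slopes and
#' intercept correlated with each other but not with the log residual
#' SD; `lmm4`/`jm4` fully correlated intercept, slope and log residual
#' SD.
#'
#' @param model one of `"lmm1"`..`"lmm4"`, `"jm1"`..`"jm4"`.
#' @param fixed_covariates names of covariate-table columns entering the
#'   longitudinal mean (time-constant).
#' @param survival_covariates names of covariate-table columns entering
#'   the hazard (joint model and two-stage survival adjustment).
#' @return A list of class `model_spec` with fields `model`,
#'   `has_slope`, `correlated`, `fixed_covariates`, `survival_covariates`.
#' @export
model_spec <- function(model = "lmm2", fixed_covariates = character(),
                       survival_covariates = character()) {
  model <- match.arg(model, c(paste0("lmm", 1:4), paste0("jm", 1:4)))
  idx <- as.integer(substr(model, nchar(model), nchar(model)))
  structure(list(model = model,
                 has_slope = idx >= 3L,
                 correlated = idx %in% c(2L, 4L),
                 fixed_covariates = as.character(fixed_covariates),
                 survival_covariates = as.character(survival_covariates)),
            class = "model_spec")
}

#' MCMC configuration
#'
#' Defaults follow common practice for these models: diffuse priors
#' (uniform `U(0, 100)` on SDs, uniform `U(-1, 1)` on correlations,
#' normal `N(0, 100^2)` on location parameters), burn-in of 1000 updates
#' and 1000 retained draws.  Joint-model fits use a longer burn-in (2000)
#' and thinning of 4 by default (see [fit_joint()]) because the
#' association coefficients mix more slowly.
#'
#' @param chains number of chains (>= 2 for convergence diagnostics).
#' @param burn_in burn-in iterations per chain; adaptation of the
#'   random-walk steps happens here and is then frozen.
#' @param n_keep retained draws per chain (after thinning).
#' @param thin thinning interval.
#' @param seed master seed; per-chain seeds are derived deterministically.
#' @param sd_prior_upper upper bound of the uniform prior on SDs.
#' @param normal_prior_sd SD of the normal prior on location parameters
#'   (fixed effects, `mu_sigma`, association coefficients, log baseline
#'   hazard levels).
#' @param rhat_threshold convergence threshold for the Brooks-Gelman
#'   statistic; a warning is issued when any reported parameter exceeds
#'   it (only checked with >= 2 chains).
#' @return A list of class `mcmc_control`.
#' @export
mcmc_control <- function(chains = 2, burn_in = 1000, n_keep = 1000,
                         thin = 1, seed = 1, sd_prior_upper = 100,
                         normal_prior_sd = 100, rhat_threshold = 1.05) {
  stopifnot(chains >= 1, burn_in >= 0, n_keep >= 1, thin >= 1,
            sd_prior_upper > 0, normal_prior_sd > 0)
  structure(list(chains = as.integer(chains), burn_in = as.integer(burn_in),
                 n_keep = as.integer(n_keep), thin = as.integer(thin),
                 seed = as.integer(seed), sd_prior_upper = sd_prior_upper,
                 normal_prior_sd = normal_prior_sd,
                 rhat_threshold = rhat_threshold),
            class = "mcmc_control")
}

# Assemble sampler inputs from an analysis_dataset and a model_spec.
# Subjects are those present in the longitudinal data, in sorted id order;
# observations are contiguous per subject and time-ordered.
build_mcmc_inputs <- function(data, spec) {
  long <- data$longitudinal
  if (nrow(long) == 0L) stop("no longitudinal measurements", call. = FALSE)
  ids <- unique(long$id)            # sorted by validate_longitudinal
  idx <- match(long$id, ids)
  n_i <- tabulate(idx, nbins = length(ids))
  subj_start <- c(0L, cumsum(n_i)[-length(n_i)])

  p_names <- "(Intercept)"
  X <- matrix(1, nrow(long), 1L)
  if (length(spec$fixed_covariates)) {
    cov <- data$covariates
    if (is.null(cov)) stop("fixed_covariates given but no covariate table",
                           call. = FALSE)
    missing <- setdiff(spec$fixed_covariates, names(cov))
    if (length(missing)) stop("covariate(s) not found: ",
                              paste(missing, collapse = ", "), call. = FALSE)
    ci <- match(long$id, cov$id)
    X <- cbind(X, as.matrix(cov[ci, spec$fixed_covariates, drop = FALSE]))
    p_names <- c(p_names, spec$fixed_covariates)
  }
  if (spec$has_slope) {
    X <- cbind(X, long$time)
    p_names <- c(p_names, "time")
  }

  # crude initial values from per-subject summaries
  mu_y <- mean(long$value)
  sub_mean <- vapply(split(long$value, idx), mean, 0)
  sub_sd <- vapply(split(long$value, idx),
                   function(v) if (length(v) >= 2L) sd(v) else NA_real_, 0)
  s_init <- log(pmax(sub_sd, 1e-3))
  s_init[is.na(s_init)] <- mean(s_init, na.rm = TRUE)
  if (all(is.na(sub_sd))) s_init[] <- 0
  b0_init <- sub_mean - mu_y

  list(y = long$value, subj_start = subj_start, subj_len = n_i,
       tt = long$time, X = X, p_names = p_names, ids = ids,
       beta_init = c(mu_y, rep(0, ncol(X) - 1L)),
       b0_init = b0_init, s_init = s_init,
       mu_sigma_init = mean(s_init),
       tau0_init = max(sd(b0_init), 0.5),
       tau_sigma_init = max(sd(s_init), 0.1))
}

pop_colnames <- function(p_names, spec) {
  taus <- if (spec$has_slope) c("tau0", "tau1", "tau_sigma")
          else c("tau0", "tau_sigma")
  c(p_names, "mu_sigma", taus, "rho01", "rho0s", "rho1s")
}

# Columns of the raw pop matrix that are actually sampled for this spec.
active_pop_cols <- function(cols, spec) {
  drop <- character()
  if (!spec$has_slope) drop <- c(drop, "rho01", "rho1s")
  if (!spec$correlated) drop <- c(drop, "rho0s", if (spec$has_slope) "rho1s")
  setdiff(cols, unique(drop))
}

#' Fit a Bayesian location-scale mixed model
#'
#' Fits `Y_ij = beta' X_i (+ beta_t t_ij) + b0_i (+ b1_i t_ij) + e_ij`
#' with `e_ij ~ N(0, sigma_i^2)` and `(b0_i [, b1_i], log sigma_i)`
#' multivariate normal; the subject-specific residual SD `sigma_i` is
#' log-normal and optionally correlated with the random effects
#' (see [model_spec()]).  Estimation is by adaptive
#' Metropolis-within-Gibbs MCMC under diffuse priors (uniform on SDs and
#' correlations, normal `N(0, 100^2)` on location parameters).
#'
#' @param data an [analysis_dataset()] (or a [longitudinal_data()]
#'   object, in which case no survival information is needed).
#' @param spec a [model_spec()]; one of the `lmm*` models.
#' @param mcmc an [mcmc_control()].
#' @param store_subject_draws keep the full per-subject draws
#'   (memory-heavy for large N); posterior means are always available.
#' @param fixed optional list pinning parameters, used mainly for
#'   validation studies: fields `beta` (fixed-effect vector) and/or all
#'   of `mu_sigma`, `tau0`, `tau_sigma`, `rho` (plus `tau1`, `rho01`,
#'   `rho1s` for slope models) to freeze the population distribution.
#' @return An object of class `locscale_fit` with elements `draws` (list
#'   of per-chain matrices of population-parameter draws), `subject`
#'   (data frame of per-subject posterior means), `subject_draws`,
#'   `rhat`, `spec`, `mcmc`.
#' @export
fit_locscale <- function(data, spec = model_spec("lmm2"),
                         mcmc = mcmc_control(), store_subject_draws = FALSE,
                         fixed = NULL) {
  if (inherits(data, "longitudinal_data")) {
    data <- list(longitudinal = data, covariates = NULL)
  }
  stopifnot(inherits(spec, "model_spec"), inherits(mcmc, "mcmc_control"))
  if (!startsWith(spec$model, "lmm"))
    stop("fit_locscale expects an lmm* spec; use fit_joint for jm*",
         call. = FALSE)
  inp <- build_mcmc_inputs(data, spec)
  q <- if (spec$has_slope) 2L else 1L
  d <- q + 1L

  fix_beta <- !is.null(fixed$beta)
  fix_pop <- !is.null(fixed$mu_sigma)
  if (fix_pop) {
    need <- c("mu_sigma", "tau0", "tau_sigma", "rho")
    if (spec$has_slope) need <- c(need, "tau1", "rho01", "rho1s")
    miss <- setdiff(need, names(fixed))
    if (length(miss)) stop("fixed population parameters incomplete: need ",
                           paste(miss, collapse = ", "), call. = FALSE)
  }

  chains <- vector("list", mcmc$chains)
  sub_draws <- if (store_subject_draws) vector("list", mcmc$chains) else NULL
  mean_b0 <- mean_b1 <- mean_sig <- 0
  cn <- pop_colnames(inp$p_names, spec)

  for (ch in seq_len(mcmc$chains)) {
    set.seed(mcmc$seed + ch - 1L)
    jit <- function(x, s) x + rnorm(length(x), 0, s)
    beta0 <- if (fix_beta) fixed$beta else jit(inp$beta_init, 0.5)
    u0 <- matrix(0, length(inp$ids), d)
    u0[, 1L] <- jit(inp$b0_init, 0.5)
    u0[, d] <- jit(inp$s_init, 0.05)
    if (fix_pop) {
      mu_s0 <- fixed$mu_sigma
      tau0v <- if (spec$has_slope) c(fixed$tau0, fixed$tau1, fixed$tau_sigma)
               else c(fixed$tau0, fixed$tau_sigma)
      r01 <- if (spec$has_slope) fixed$rho01 else 0
      r0s <- fixed$rho
      r1s <- if (spec$has_slope) fixed$rho1s else 0
    } else {
      mu_s0 <- inp$mu_sigma_init
      tau0v <- if (spec$has_slope) c(inp$tau0_init, 0.5, inp$tau_sigma_init)
               else c(inp$tau0_init, inp$tau_sigma_init)
      r01 <- r0s <- r1s <- 0
    }
    res <- locscale_mcmc_cpp(inp$y, inp$subj_start, inp$subj_len, inp$tt,
                             inp$X, spec$has_slope, spec$correlated,
                             mcmc$burn_in, mcmc$n_keep, mcmc$thin,
                             mcmc$sd_prior_upper, mcmc$normal_prior_sd,
                             beta0, u0, mu_s0, tau0v, r01, r0s, r1s,
                             fix_beta, fix_pop, store_subject_draws)
    pop <- res$pop
    colnames(pop) <- cn
    keep_cols <- active_pop_cols(cn, spec)
    chains[[ch]] <- pop[, keep_cols, drop = FALSE]
    mean_b0 <- mean_b0 + res$mean_b0 / mcmc$chains
    mean_sig <- mean_sig + res$mean_sigma / mcmc$chains
    if (spec$has_slope) mean_b1 <- mean_b1 + res$mean_b1 / mcmc$chains
    if (store_subject_draws) sub_draws[[ch]] <- res$subject_draws
  }

  subject <- data.frame(id = inp$ids, mean_b0 = mean_b0,
                        mean_sigma = mean_sig, stringsAsFactors = FALSE)
  if (spec$has_slope) subject$mean_b1 <- mean_b1

  fit <- structure(list(draws = chains, subject = subject,
                        subject_draws = sub_draws, spec = spec, mcmc = mcmc,
                        fixed = fixed, n_subjects = length(inp$ids),
                        accept_sigma = NA_real_),
                   class = "locscale_fit")
  fit$rhat <- fit_rhat(fit)
  check_rhat(fit)
  fit
}

fit_rhat <- function(fit) {
  if (length(fit$draws) < 2L) return(NULL)
  params <- colnames(fit$draws[[1L]])
  vapply(params, function(p) gelman_rubin(fit, p), 0)
}

check_rhat <- function(fit) {
  if (is.null(fit$rhat)) return(invisible())
  bad <- fit$rhat[!is.na(fit$rhat) & fit$rhat > fit$mcmc$rhat_threshold]
  if (length(bad))
    warning("Brooks-Gelman diagnostic above ", fit$mcmc$rhat_threshold,
            " for: ", paste(sprintf("%s (%.3f)", names(bad), bad),
                            collapse = ", "), call. = FALSE)
  invisible()
}

#' @export
print.locscale_fit <- function(x, ...) {
  cat("<locscale_fit>", x$spec$model, "-", x$n_subjects, "subjects,",
      length(x$draws), "chain(s) x", nrow(x$draws[[1L]]), "draws\n")
  print(summary_draws(x))
  invisible(x)
}

summary_draws <- function(fit) {
  all <- do.call(rbind, fit$draws)
  out <- data.frame(mean = colMeans(all), sd = apply(all, 2, sd),
                    q2.5 = apply(all, 2, quantile, 0.025),
                    q97.5 = apply(all, 2, quantile, 0.975))
  if (!is.null(fit$rhat)) out$rhat <- fit$rhat[rownames(out)]
  out
}

#' Posterior summary of population parameters
#'
#' @param object a `locscale_fit` or `joint_fit`.
#' @param ... unused.
#' @return Data frame with posterior mean, SD, central 95% interval and
#'   (with >= 2 chains) the Brooks-Gelman statistic per parameter.
#' @export
summary.locscale_fit <- function(object, ...) summary_draws(object)

#' Per-subject posterior-mean effects
#'
#' Extracts the estimated usual level (posterior mean of the intercept
#' plus the subject's random intercept), residual SD (posterior mean of
#' `sigma_i`, not of `log sigma_i`) and, for slope models, the
#' subject-specific slope.  These are the stage-one outputs of the
#' two-stage survival procedure.
#'
#' @param fit a `locscale_fit` or `joint_fit`.
#' @return Data frame of class `subject_effects` with columns `id`,
#'   `bp_hat`, `sd_hat` and, for slope models, `slope_hat`.
#' @export
subject_effects <- function(fit) {
  stopifnot(inherits(fit, c("locscale_fit", "joint_fit")))
  if (is.null(fit$subject)) stop("fit contains no per-subject draws",
                                 call. = FALSE)
  all <- do.call(rbind, fit$draws)
  beta0 <- mean(all[, "(Intercept)"])
  out <- data.frame(id = fit$subject$id,
                    bp_hat = beta0 + fit$subject$mean_b0,
                    sd_hat = fit$subject$mean_sigma,
                    stringsAsFactors = FALSE)
  if (!is.null(fit$subject$mean_b1)) {
    beta_t <- mean(all[, "time"])
    out$slope_hat <- beta_t + fit$subject$mean_b1
  }
  class(out) <- c("subject_effects", "data.frame")
  out
}
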