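#' Baseline-hazard cutpoints at event-time quantiles
#'
#' Chooses the breakpoints of the piecewise-constant baseline hazard:
#' `K` intervals whose `K - 1` interior boundaries sit at the
#' `j/K` empirical quantiles (type-7 linear interpolation) of the
#' observed event times, with `t_0 = 0` and the final boundary at the
#' maximum follow-up time.  When evaluating the cumulative hazard the
#' last hazard level extends beyond the final boundary, so times past it
#' are well-defined.
#'
#' @param event_times positive event times (subjects with `status == 1`).
#' @param K number of hazard intervals (>= 1).
#' @param max_time final boundary; defaults to `max(event_times)` and in
#'   model fitting is the maximum follow-up time over all subjects.
#' @return Numeric vector of `K + 1` increasing cutpoints starting at 0.
#' @export
hazard_cutpoints <- function(event_times, K, max_time = max(event_times)) {
  stopifnot(K >= 1, all(event_times > 0))
  if (length(unique(event_times)) < K)
    stop("fewer than K = ", K, " distinct event times; reduce K",
         call. = FALSE)
  interior <- if (K > 1L)
    quantile(event_times, probs = seq_len(K - 1L) / K, names = FALSE, type = 7)
  else numeric()
  cp <- c(0, interior, max_time)
  if (any(diff(cp) <= 0))
    stop("cutpoints not strictly increasing (heavily tied event times); ",
         "reduce K", call. = FALSE)
  cp
}

#' Cumulative hazard of a piecewise-constant baseline
#'
#' Evaluates `H(t) = exp(eta) * sum_k h0_k * |(t_{k-1}, t_k] n (0, t]|`,
#' the analytically integrated step hazard scaled by a subject's hazard
#' linear predictor `eta`.  Times beyond the last cutpoint accrue hazard
#' at the final level `h0_K`.
#'
#' @param t non-negative time(s).
#' @param eta hazard linear predictor (scalar).
#' @param cutpoints `K + 1` increasing boundaries starting at 0 (from
#'   [hazard_cutpoints()]).
#' @param h0 `K` positive hazard levels.
#' @return `H(t)`, vectorised over `t`.
#' @export
cumulative_hazard <- function(t, eta, cutpoints, h0) {
  stopifnot(length(h0) == length(cutpoints) - 1L, all(h0 > 0), all(t >= 0))
  K <- length(h0)
  lower <- cutpoints[-length(cutpoints)]
  upper <- cutpoints[-1L]
  upper[K] <- Inf                      # last level extends indefinitely
  H0 <- vapply(t, function(ti) {
    sum(h0 * pmax(0, pmin(ti, upper) - lower))
  }, 0)
  exp(eta) * H0
}

# Occupancy matrix: time spent by each subject in each hazard interval,
# with the last interval unbounded above.
occupancy_matrix <- function(time, cutpoints) {
  K <- length(cutpoints) - 1L
  lower <- cutpoints[-length(cutpoints)]
  upper <- cutpoints[-1L]
  upper[K] <- Inf
  out <- vapply(time, function(ti) pmax(0, pmin(ti, upper) - lower),
                numeric(K))
  matrix(out, nrow = length(time), ncol = K, byrow = TRUE)
}

# Interval index of each follow-up time (1-based; beyond the last
# boundary maps to K).
interval_index <- function(time, cutpoints) {
  K <- length(cutpoints) - 1L
  pmin(findInterval(time, cutpoints[-1L], left.open = TRUE) + 1L, K)
}

#' Joint log-likelihood at fixed parameter values
#'
#' Evaluates the complete-data log-likelihood of the joint model at given
#' subject effects and parameters: the sum over subjects of the normal
#' longitudinal log-density
#' `sum_j log N(Y_ij | beta'X_i (+ beta_t t), b0_i (+ b1_i t), sigma_i^2)`
#' plus the piecewise-exponential survival term
#' `delta_i * (log h0(T_i) + eta_i) - H_i(T_i)` with
#' `eta_i = alpha' (b0_i [, b1_i], sigma_i) + gamma' W_i`.  The random
#' effects are treated as known; population terms for `(b, log sigma)`
#' are not included.  Intended for validation and diagnostics.
#'
#' @param data an [analysis_dataset()].
#' @param effects data frame with `id`, `b0`, `sigma` (and `b1` for slope
#'   models).
#' @param beta fixed-effect vector (intercept first; time coefficient
#'   last for slope models).
#' @param alpha association coefficients for `(b0 [, b1], sigma)`.
#' @param gamma coefficients of the survival baseline covariates (may be
#'   empty).
#' @param cutpoints,h0 piecewise-constant baseline hazard.
#' @param spec a [model_spec()].
#' @return Scalar log-likelihood.
#' @export
joint_loglik <- function(data, effects, beta, alpha, gamma = numeric(),
                         cutpoints, h0, spec = model_spec("jm2")) {
  long <- data$longitudinal
  surv <- data$survival
  i <- match(long$id, effects$id)
  mu <- beta[1L] + effects$b0[i]
  if (length(spec$fixed_covariates)) {
    Xc <- as.matrix(data$covariates[match(long$id, data$covariates$id),
                                    spec$fixed_covariates, drop = FALSE])
    mu <- mu + drop(Xc %*% beta[seq_along(spec$fixed_covariates) + 1L])
  }
  if (spec$has_slope)
    mu <- mu + (beta[length(beta)] + effects$b1[i]) * long$time
  ll_long <- sum(stats::dnorm(long$value, mu, effects$sigma[i], log = TRUE))

  j <- match(surv$id, effects$id)
  a_mat <- cbind(effects$b0[j],
                 if (spec$has_slope) effects$b1[j],
                 effects$sigma[j])
  eta <- drop(a_mat %*% alpha)
  if (length(gamma)) {
    Wm <- as.matrix(data$covariates[match(surv$id, data$covariates$id),
                                    spec$survival_covariates, drop = FALSE])
    eta <- eta + drop(Wm %*% gamma)
  }
  k_i <- interval_index(surv$time, cutpoints)
  H <- vapply(seq_len(nrow(surv)), function(s)
    cumulative_hazard(surv$time[s], eta[s], cutpoints, h0), 0)
  ll_surv <- sum(surv$status * (log(h0[k_i]) + eta) - H)
  ll_long + ll_surv
}

#' Fit a shared-random-effects joint model
#'
#' Fits the location-scale longitudinal submodel of [fit_locscale()]
#' simultaneously with a proportional-hazards survival submodel
#' `h_i(t) = h0(t) exp(alpha' (b0_i [, b1_i], sigma_i) + gamma' W_i)`,
#' where `h0` is piecewise constant on `K` intervals with breakpoints at
#' the event-time quantiles ([hazard_cutpoints()]).  The shared effects
#' are the subject's random intercept (and slope) and the residual SD
#' `sigma_i` itself, so `alpha` is interpreted per unit of the biomarker.
#' Sampling is adaptive Metropolis-within-Gibbs; the random effects are
#' proposed from their longitudinal full conditional and accepted with
#' the survival-likelihood ratio.
#'
#' @param data an [analysis_dataset()] with survival outcomes.
#' @param spec a [model_spec()]; one of the `jm*` models.
#' @param K number of baseline-hazard intervals.
#' @param mcmc an [mcmc_control()]; the defaults here are a burn-in of
#'   2000 and thinning of 4 (association parameters are strongly
#'   autocorrelated).
#' @param store_subject_draws keep full per-subject draws.
#' @param fix_alpha freeze `alpha` and `gamma` at 0 (factorises the
#'   likelihood; used for validation against [fit_locscale()]).
#' @return An object of class `joint_fit` (also `locscale_fit`-like):
#'   list with `draws`, `subject`, `subject_draws`, `rhat`, `cutpoints`,
#'   `spec`, `mcmc`.
#' @export
fit_joint <- function(data, spec = model_spec("jm2"), K = 15,
                      mcmc = mcmc_control(burn_in = 2000, thin = 4),
                      store_subject_draws = FALSE, fix_alpha = FALSE) {
  stopifnot(inherits(data, "analysis_dataset"), inherits(spec, "model_spec"),
            inherits(mcmc, "mcmc_control"))
  if (!startsWith(spec$model, "jm"))
    stop("fit_joint expects a jm* spec; use fit_locscale for lmm*",
         call. = FALSE)
  surv <- data$survival
  long_ids <- unique(data$longitudinal$id)
  if (!setequal(surv$id, long_ids))
    surv <- surv[surv$id %in% long_ids, , drop = FALSE]
  n_events <- sum(surv$status)
  if (n_events < K)
    stop("fewer events (", n_events, ") than hazard intervals K = ", K,
         "; reduce K", call. = FALSE)
  inp <- build_mcmc_inputs(data, spec)
  stopifnot(identical(inp$ids, surv$id))   # both sorted by id
  q <- if (spec$has_slope) 2L else 1L
  d <- q + 1L

  cp <- hazard_cutpoints(surv$time[surv$status == 1L], K,
                         max_time = max(surv$time))
  Occ <- occupancy_matrix(surv$time, cp)
  kidx <- interval_index(surv$time, cp) - 1L

  wvars <- spec$survival_covariates
  W <- matrix(0, nrow(surv), 0L)
  if (length(wvars)) {
    cov <- data$covariates
    missing <- setdiff(wvars, names(cov))
    if (length(missing)) stop("survival covariate(s) not found: ",
                              paste(missing, collapse = ", "), call. = FALSE)
    W <- as.matrix(cov[match(surv$id, cov$id), wvars, drop = FALSE])
  }

  # initial hazard levels: overall event rate per interval exposure
  h_init <- pmax(colSums(Occ) * 0 + n_events / sum(surv$time), 1e-6)
  logh_init <- log(h_init)

  chains <- vector("list", mcmc$chains)
  sub_draws <- if (store_subject_draws) vector("list", mcmc$chains) else NULL
  mean_b0 <- mean_b1 <- mean_sig <- 0
  cn <- c(pop_colnames(inp$p_names, spec),
          c("alpha0", if (spec$has_slope) "alpha1", "alpha_sigma"),
          if (length(wvars)) paste0("gamma_", wvars),
          paste0("h0_", seq_len(K)))

  for (ch in seq_len(mcmc$chains)) {
    set.seed(mcmc$seed + ch - 1L)
    jit <- function(x, s) x + rnorm(length(x), 0, s)
    beta0 <- jit(inp$beta_init, 0.5)
    u0 <- matrix(0, length(inp$ids), d)
    u0[, 1L] <- jit(inp$b0_init, 0.5)
    u0[, d] <- jit(inp$s_init, 0.05)
    tau0v <- if (spec$has_slope) c(inp$tau0_init, 0.5, inp$tau_sigma_init)
             else c(inp$tau0_init, inp$tau_sigma_init)
    res <- joint_mcmc_cpp(inp$y, inp$subj_start, inp$subj_len, inp$tt,
                          inp$X, spec$has_slope, spec$correlated,
                          as.integer(surv$status), kidx, Occ, W,
                          mcmc$burn_in, mcmc$n_keep, mcmc$thin,
                          mcmc$sd_prior_upper, mcmc$normal_prior_sd,
                          beta0, u0, inp$mu_sigma_init, tau0v, 0, 0, 0,
                          rep(0, q + 1L), rep(0, ncol(W)), logh_init,
                          fix_alpha, store_subject_draws)
    pop <- res$pop
    colnames(pop) <- cn
    keep_cols <- c(active_pop_cols(pop_colnames(inp$p_names, spec), spec),
                   setdiff(cn, pop_colnames(inp$p_names, spec)))
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
                        cutpoints = cp, K = K, n_subjects = length(inp$ids),
                        n_events = n_events),
                   class = c("joint_fit", "locscale_fit"))
  fit$rhat <- fit_rhat(fit)
  check_rhat(fit)
  fit
}

#' Posterior mean and credible interval of the association coefficients
#'
#' @param fit a `joint_fit`.
#' @param level credible level (default 0.95, central quantiles).
#' @return Data frame with rows for each association coefficient
#'   (`alpha0`, `alpha_sigma`, ...) giving posterior mean, SD and the
#'   credible interval.
#' @export
association <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "joint_fit"))
  all <- do.call(rbind, fit$draws)
  pars <- grep("^alpha", colnames(all), value = TRUE)
  a <- (1 - level) / 2
  out <- data.frame(
    mean = colMeans(all[, pars, drop = FALSE]),
    sd = apply(all[, pars, drop = FALSE], 2, sd),
    lower = apply(all[, pars, drop = FALSE], 2, quantile, a),
    upper = apply(all[, pars, drop = FALSE], 2, quantile, 1 - a))
  rownames(out) <- pars
  out
}

#' @export
print.joint_fit <- function(x, ...) {
  cat("<joint_fit>", x$spec$model, "-", x$n_subjects, "subjects,",
      x$n_events, "events,", x$K, "hazard intervals\n")
  s <- summary_draws(x)
  print(s[!grepl("^h0_", rownames(s)), , drop = FALSE])
  invisible(x)
}
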