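test_that("hazard cutpoints sit at event-time quantiles", {
  cp <- hazard_cutpoints(1:15, K = 3)
  expect_equal(cp, c(0, quantile(1:15, c(1/3, 2/3), names = FALSE), 15))
  # K = 1: single interval, constant (exponential) baseline
  expect_equal(hazard_cutpoints(c(2, 9, 4), K = 1), c(0, 9))
  expect_error(hazard_cutpoints(c(1, 2), K = 5), "fewer than K")
})

test_that("cumulative hazard accumulates the step function exactly", {
  cp <- c(0, 2, 5, 10)
  h0 <- c(0.1, 0.4, 0.05)
  expect_equal(cumulative_hazard(0, 0.3, cp, h0), 0)
  # single interval: exponential closed form, including beyond the boundary
  expect_equal(cumulative_hazard(c(3, 12), 0.7, c(0, 10), 0.2),
               0.2 * c(3, 12) * exp(0.7))
  # hand-accumulated value inside the third interval
  expect_equal(cumulative_hazard(7, 0, cp, h0),
               0.1 * 2 + 0.4 * 3 + 0.05 * 2)
  # last level extends past the final cutpoint
  expect_equal(cumulative_hazard(14, 0, cp, h0),
               0.1 * 2 + 0.4 * 3 + 0.05 * 9)
})

test_that("joint log-likelihood matches a hand-assembled sum", {
  long <- longitudinal_data(id = rep(c("a", "b"), each = 2),
                            time = c(0, 1, 0, 1),
                            value = c(118, 121, 131, 128))
  surv <- survival_data(c("a", "b"), c(4, 9), c(1, 0))
  ds <- analysis_dataset(long, surv)
  eff <- data.frame(id = c("a", "b"), b0 = c(-2, 10), sigma = c(7, 9))
  beta <- 120; alpha <- c(0.02, 0.05); cp <- c(0, 5, 9); h0 <- c(0.01, 0.03)
  got <- joint_loglik(ds, eff, beta, alpha, cutpoints = cp, h0 = h0,
                      spec = model_spec("jm2"))
  # longitudinal part: N(y | beta + b0, sigma^2) per measurement
  ll <- dnorm(118, 118, 7, log = TRUE) + dnorm(121, 118, 7, log = TRUE) +
        dnorm(131, 130, 9, log = TRUE) + dnorm(128, 130, 9, log = TRUE)
  # survival part, subject a: event at t = 4 in interval 1
  eta_a <- 0.02 * (-2) + 0.05 * 7
  ll <- ll + log(0.01) + eta_a - exp(eta_a) * (0.01 * 4)
  # subject b: censored at t = 9 (through both intervals)
  eta_b <- 0.02 * 10 + 0.05 * 9
  ll <- ll - exp(eta_b) * (0.01 * 5 + 0.03 * 4)
  expect_equal(got, ll, tolerance = 1e-12)
})

test_that("with the association frozen at zero the joint model factorises", {
  set.seed(41)
  sim <- simulate_dataset(sim_config(n_subjects = 200, n_visits = 4))
  ctl <- mcmc_control(chains = 1, burn_in = 600, n_keep = 600, seed = 9)
  jf <- fit_joint(sim$data, model_spec("jm2"), K = 5, mcmc = ctl,
                  fix_alpha = TRUE)
  lf <- fit_locscale(sim$data, model_spec("lmm2"), ctl)
  sj <- summary(jf); sl <- summary(lf)
  expect_true(all(sj[c("alpha0", "alpha_sigma"), "mean"] == 0))
  for (p in c("mu_sigma", "tau_sigma", "tau0")) {
    expect_lt(abs(sj[p, "mean"] - sl[p, "mean"]),
              0.75 * (sj[p, "sd"] + sl[p, "sd"]))
  }
})

test_that("the joint fit is calibrated against the observed event count", {
  set.seed(42)
  sim <- simulate_dataset(sim_config(n_subjects = 400, n_visits = 4))
  jf <- fit_joint(sim$data, model_spec("jm2"), K = 8,
                  mcmc = mcmc_control(chains = 1, burn_in = 800,
                                      n_keep = 400, thin = 2, seed = 10))
  s <- summary(jf)
  # posterior-mean expected events sum_i 1 - exp(-H_i(T_i)) vs observed
  eff <- subject_effects(jf)
  h0 <- s[paste0("h0_", 1:8), "mean"]
  a0 <- s["alpha0", "mean"]; as_ <- s["alpha_sigma", "mean"]
  surv <- sim$data$survival
  eta <- a0 * (eff$bp_hat - s["(Intercept)", "mean"]) + as_ * eff$sd_hat
  Hi <- vapply(seq_len(nrow(surv)), function(i)
    cumulative_hazard(surv$time[i], eta[i], jf$cutpoints, h0), 0)
  expected <- sum(1 - exp(-Hi))
  observed <- sum(surv$status)
  expect_lt(abs(expected - observed) / observed, 0.35)
  # association draws are available with credible intervals
  a <- association(jf)
  expect_true(all(a$lower < a$mean & a$mean < a$upper))
})

test_that("more hazard intervals fit Weibull data better", {
  set.seed(43)
  sim <- simulate_dataset(sim_config(n_subjects = 200, n_visits = 4))
  dev_for <- function(K) {
    jf <- fit_joint(sim$data, model_spec("jm1"), K = K,
                    mcmc = mcmc_control(chains = 1, burn_in = 600,
                                        n_keep = 100, thin = 2, seed = 11),
                    store_subject_draws = TRUE)
    dr <- jf$draws[[1L]]
    sd_ <- jf$subject_draws[[1L]]
    # mean deviance over a thinned set of draws
    picks <- seq(10, 100, by = 10)
    mean(vapply(picks, function(g) {
      eff <- data.frame(id = jf$subject$id, b0 = sd_$b0[g, ],
                        sigma = sd_$sigma[g, ])
      -2 * joint_loglik(sim$data, eff, beta = dr[g, "(Intercept)"],
                        alpha = dr[g, c("alpha0", "alpha_sigma")],
                        cutpoints = jf$cutpoints,
                        h0 = dr[g, paste0("h0_", seq_len(K))],
                        spec = model_spec("jm1"))
    }, 0))
  }
  expect_gt(dev_for(1), dev_for(10))
})

test_that("infeasible interval counts are rejected", {
  set.seed(44)
  sim <- simulate_dataset(sim_config(n_subjects = 40, n_visits = 4))
  n_ev <- sum(sim$data$survival$status)
  expect_error(fit_joint(sim$data, model_spec("jm2"), K = n_ev + 1),
               "fewer events")
})
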