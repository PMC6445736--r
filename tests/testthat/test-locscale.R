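# Location-scale mixed model: parameter recovery, shrinkage behaviour and
# plumbing.  Chains are kept short; assertions use posterior spread.

test_that("homoscedastic data drive tau_sigma towards zero", {
  set.seed(31)
  sim <- simulate_dataset(sim_config(n_subjects = 150, n_visits = 6,
                                     tau_sigma = 0, rho = 0))
  fit <- fit_locscale(sim$data, model_spec("lmm1"),
                      mcmc_control(chains = 1, burn_in = 500, n_keep = 500,
                                   seed = 2))
  s <- summary(fit)
  expect_lt(s["tau_sigma", "mean"], 0.12)
  eff <- subject_effects(fit)
  expect_lt(max(abs(eff$sd_hat - exp(2))) / exp(2), 0.25)
})

test_that("the correlated model recovers the generating population parameters", {
  set.seed(32)
  sim <- simulate_dataset(sim_config(n_subjects = 500, n_visits = 6))
  fit <- fit_locscale(sim$data, model_spec("lmm2"),
                      mcmc_control(chains = 2, burn_in = 800, n_keep = 800,
                                   seed = 3))
  s <- summary(fit)
  truth <- c("(Intercept)" = 120, mu_sigma = 2, tau0 = 15,
             tau_sigma = 0.5, rho0s = 0.5)
  for (p in names(truth)) {
    expect_lt(abs(s[p, "mean"] - truth[[p]]), 3.5 * s[p, "sd"])
  }
  expect_true(all(s$rhat < 1.1, na.rm = TRUE))
})

test_that("posterior-mean residual SDs shrink towards the population", {
  set.seed(33)
  sim <- simulate_dataset(sim_config(n_subjects = 400, n_visits = 4))
  fit <- fit_locscale(sim$data, model_spec("lmm2"),
                      mcmc_control(chains = 1, burn_in = 600, n_keep = 600,
                                   seed = 4))
  eff <- subject_effects(fit)
  nai <- naive_estimates(sim$data, sd_denominator = "n-1")
  stopifnot(identical(eff$id, nai$id))
  expect_lt(var(eff$sd_hat), var(nai$sd))          # shrinkage
  sig <- sim$effects$sigma[match(eff$id, sim$effects$id)]
  # borrowing strength: the model-based estimates track the truth better
  expect_lt(mean((eff$sd_hat - sig)^2), mean((nai$sd - sig)^2))
  # majority of subjects sit between their naive SD and the population level
  pop <- exp(mean(do.call(rbind, fit$draws)[, "mu_sigma"]))
  between <- (eff$sd_hat - nai$sd) * (eff$sd_hat - pop) <= 0
  expect_gt(mean(between), 0.5)
})

test_that("with more measurements the estimates track the naive SD more closely", {
  gap <- sapply(c(4, 10), function(n) {
    set.seed(34)
    sim <- simulate_dataset(sim_config(n_subjects = 250, n_visits = n))
    fit <- fit_locscale(sim$data, model_spec("lmm2"),
                        mcmc_control(chains = 1, burn_in = 500, n_keep = 500,
                                     seed = 5))
    eff <- subject_effects(fit)
    nai <- naive_estimates(sim$data, sd_denominator = "n-1")
    mean(abs(eff$sd_hat - nai$sd))
  })
  expect_lt(gap[2], gap[1])
})

test_that("population parameters can be frozen and subject draws exported", {
  set.seed(35)
  sim <- simulate_dataset(sim_config(n_subjects = 30, n_visits = 4))
  fx <- list(beta = 120, mu_sigma = 2, tau0 = 15, tau_sigma = 0.5, rho = 0.5)
  fit <- fit_locscale(sim$data, model_spec("lmm2"),
                      mcmc_control(chains = 1, burn_in = 200, n_keep = 100,
                                   seed = 6),
                      store_subject_draws = TRUE, fixed = fx)
  dr <- fit$draws[[1L]]
  expect_true(all(dr[, "mu_sigma"] == 2))
  expect_true(all(dr[, "tau0"] == 15))
  expect_true(all(dr[, "(Intercept)"] == 120))
  # posterior means in `subject` agree with the stored draws
  sd_draws <- fit$subject_draws[[1L]]$sigma
  expect_equal(fit$subject$mean_sigma, colMeans(sd_draws), tolerance = 1e-12)
  eff <- subject_effects(fit)
  expect_equal(eff$sd_hat, colMeans(sd_draws), tolerance = 1e-12)
  expect_equal(eff$bp_hat, 120 + colMeans(fit$subject_draws[[1L]]$b0),
               tolerance = 1e-12)
})

test_that("subject order does not change the population posterior", {
  set.seed(36)
  sim <- simulate_dataset(sim_config(n_subjects = 200, n_visits = 5))
  long <- sim$data$longitudinal
  perm <- long[sample(nrow(long)), ]          # scrambled row order
  ctl <- mcmc_control(chains = 1, burn_in = 500, n_keep = 500, seed = 7)
  f1 <- fit_locscale(sim$data, model_spec("lmm2"), ctl)
  f2 <- fit_locscale(analysis_dataset(perm, sim$data$survival),
                     model_spec("lmm2"), ctl)
  s1 <- summary(f1); s2 <- summary(f2)
  # canonicalisation restores the same dataset, so identical sampler path
  expect_equal(s1["mu_sigma", "mean"], s2["mu_sigma", "mean"])
  expect_equal(s1["tau0", "mean"], s2["tau0", "mean"])
})

test_that("slope models run and recover a linear trend", {
  set.seed(37)
  N <- 150; n <- 6
  id <- rep(sprintf("s%03d", 1:N), each = n)
  tt <- rep(seq(0, 10, length.out = n), N)
  b0 <- rnorm(N, 0, 8); b1 <- rnorm(N, 0, 0.4); sig <- exp(rnorm(N, 1, 0.3))
  y <- 100 + 0.8 * tt + rep(b0, each = n) + rep(b1, each = n) * tt +
    rnorm(N * n) * rep(sig, each = n)
  long <- longitudinal_data(id, tt, y)
  fit <- fit_locscale(long, model_spec("lmm3"),
                      mcmc_control(chains = 1, burn_in = 600, n_keep = 500,
                                   seed = 8))
  s <- summary(fit)
  expect_lt(abs(s["time", "mean"] - 0.8), 4 * s["time", "sd"])
  expect_lt(abs(s["tau1", "mean"] - 0.4), 4 * s["tau1", "sd"])
  eff <- subject_effects(fit)
  expect_true("slope_hat" %in% names(eff))
  expect_gt(cor(eff$slope_hat, 0.8 + b1), 0.5)
})

test_that("Brooks-Gelman statistic behaves per its formula", {
  set.seed(38)
  ch <- rnorm(1000)
  expect_equal(gelman_rubin(list(ch, ch)), 1, tolerance = 2e-3)
  # separated chains: compare against an independently coded evaluation
  c1 <- rnorm(1000); c2 <- rnorm(1000, 5)
  got <- gelman_rubin(list(c1, c2))
  W <- (var(c1) + var(c2)) / 2
  Bn <- var(c(mean(c1), mean(c2)))
  manual <- sqrt(((1000 - 1) / 1000 * W + (2 + 1) / 2 * Bn) / W)
  expect_equal(got, manual, tolerance = 1e-12)
  expect_gt(got, 3)
  # well-mixed chains from the same target stay near 1
  expect_lt(gelman_rubin(list(rnorm(2000), rnorm(2000))), 1.05)
  expect_error(gelman_rubin(list(ch)), "at least 2 chains")
  expect_error(gelman_rubin(list(c1, c2[1:10])), "equal length")
})
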