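test_that("degenerate scale distribution collapses to a point", {
  set.seed(1)
  cfg <- sim_config(n_subjects = 50, tau_sigma = 0, rho = 0)
  eff <- draw_subject_effects(cfg)
  expect_equal(eff$sigma, rep(exp(2), 50))
})

test_that("subject effects reproduce the generating moments", {
  set.seed(2)
  cfg <- sim_config(n_subjects = 20000)
  eff <- draw_subject_effects(cfg)
  n <- nrow(eff)
  # 3 * Monte-Carlo SE tolerances
  expect_lt(abs(mean(eff$b0) - 120), 3 * 15 / sqrt(n))
  expect_lt(abs(sd(eff$b0) - 15), 3 * 15 / sqrt(2 * n))
  expect_lt(abs(mean(log(eff$sigma)) - 2), 3 * 0.5 / sqrt(n))
  expect_lt(abs(sd(log(eff$sigma)) - 0.5), 3 * 0.5 / sqrt(2 * n))
  expect_lt(abs(cor(eff$b0, log(eff$sigma)) - 0.5),
            3 * (1 - 0.5^2) / sqrt(n))
})

test_that("event times follow the closed-form Weibull survivor function", {
  # with alpha0 = alpha_sigma = 0 the marginal law is Weibull(k, exp(gamma0))
  set.seed(3)
  cfg <- sim_config(n_subjects = 20000, alpha0 = 0, alpha_sigma = 0,
                    gamma0 = -6)
  eff <- draw_subject_effects(cfg)
  ev <- draw_event_time(eff$b0, eff$sigma, cfg)
  p_true <- 1 - exp(-exp(-6) * 20^2)
  p_hat <- mean(ev$status)
  expect_lt(abs(p_hat - p_true),
            3 * sqrt(p_true * (1 - p_true) / nrow(eff)))
  # survivor function at an interior time
  s10 <- mean(ev$time > 10)
  expect_lt(abs(s10 - exp(-exp(-6) * 100)), 0.012)
})

test_that("a vanishing hazard scale produces no events", {
  set.seed(4)
  cfg <- sim_config(n_subjects = 200, gamma0 = -40)
  eff <- draw_subject_effects(cfg)
  ev <- draw_event_time(eff$b0, eff$sigma, cfg)
  expect_true(all(ev$status == 0L))
  expect_true(all(ev$time == 20))
  expect_error(draw_event_time(1e6, 1, cfg), "overflow")
})

test_that("Scenario 1 keeps all measurements; Scenario 2 truncates at events", {
  set.seed(5)
  sim1 <- simulate_dataset(sim_config(scenario = 1, n_subjects = 300,
                                      n_visits = 4))
  counts <- table(sim1$data$longitudinal$id)
  expect_true(all(counts == 4L))

  set.seed(5)
  sim2 <- simulate_dataset(sim_config(scenario = 2, n_subjects = 2000,
                                      n_visits = 4))
  surv <- sim2$data$survival
  long <- sim2$data$longitudinal
  visit_times <- seq(0, 18, length.out = 4)
  for (i in which(surv$status == 1L)) {
    tt <- long$time[long$id == surv$id[i]]
    expect_true(all(tt < surv$time[i]))
    # retained = scheduled visits strictly before the event
    expect_equal(length(tt), sum(visit_times < surv$time[i]))
  }
  # censored subjects keep the full schedule (censoring at 20 > last visit)
  cens <- surv$id[surv$status == 0L]
  expect_true(all(table(long$id[long$id %in% cens]) == 4L))
  # subjects with an event before the second visit keep only baseline
  early <- surv$id[surv$status == 1L & surv$time <= 6]
  expect_gt(length(early), 0L)
  expect_true(all(table(long$id[long$id %in% early]) == 1L))
  # informative truncation: mean retained count strictly below schedule
  expect_lt(mean(table(long$id)), 4)
  expect_gt(mean(table(long$id)), 4 * (1 - mean(surv$status)))
})

test_that("simulation is reproducible under a fixed seed", {
  cfg <- sim_config(scenario = 2, n_subjects = 100)
  set.seed(42); a <- simulate_dataset(cfg)
  set.seed(42); b <- simulate_dataset(cfg)
  expect_identical(a, b)
})
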