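# Small fixture builders used across the test files.

toy_long <- function() {
  longitudinal_data(id = rep(c("A", "B", "C"), each = 3),
                    time = rep(c(0, 6, 12), 3),
                    value = c(118, 122, 120, 135, 128, 140, 110, 111, 109))
}

toy_surv <- function() {
  survival_data(id = c("A", "B", "C"), time = c(5, 15, 20),
                status = c(1, 1, 0))
}

toy_dataset <- function() analysis_dataset(toy_long(), toy_surv())

# Breslow partial log-likelihood and score for tie-free data; independent
# oracle for the Cox fitter.
breslow_loglik <- function(beta, time, status, X) {
  lp <- drop(X %*% beta)
  ll <- 0
  for (i in which(status == 1)) {
    risk <- time >= time[i]
    ll <- ll + lp[i] - log(sum(exp(lp[risk])))
  }
  ll
}

breslow_score <- function(beta, time, status, X) {
  lp <- drop(X %*% beta)
  sc <- numeric(ncol(X))
  for (i in which(status == 1)) {
    risk <- which(time >= time[i])
    wts <- exp(lp[risk])
    xbar <- colSums(X[risk, , drop = FALSE] * wts) / sum(wts)
    sc <- sc + X[i, ] - xbar
  }
  sc
}

maximise_partial_likelihood <- function(time, status, X) {
  optim(rep(0, ncol(X)),
        fn = function(b) -breslow_loglik(b, time, status, X),
        gr = function(b) -breslow_score(b, time, status, X),
        method = "BFGS", control = list(reltol = 1e-16, maxit = 500))$par
}
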