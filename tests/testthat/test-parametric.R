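make_weibull_ipd <- function(n, shape, scale, cens_q = Inf, seed = 1) {
  set.seed(seed)
  t_true <- stats::rweibull(n, shape = shape, scale = scale)
  if (!is.finite(cens_q)) return(pseudo_ipd(t_true, rep(1L, n)))
  cens <- stats::runif(n, 0, cens_q)
  pseudo_ipd(pmin(t_true, cens), as.integer(t_true <= cens))
}

test_that("exponential MLE is the closed form and agrees with flexsurv", {
  ipd <- make_weibull_ipd(400, shape = 1, scale = 20, cens_q = 60, seed = 2)
  fit <- fit_parametric(ipd, "exponential")
  lambda_hat <- sum(ipd$event) / sum(ipd$time)
  expect_equal(fit$params[["rate"]], lambda_hat, tolerance = 1e-10)
  # independent numerical route
  fs <- flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1, data = ipd,
                              dist = "exp")
  expect_equal(fit$params[["rate"]], unname(fs$res["rate", "est"]),
               tolerance = 1e-5)
  expect_equal(fit$aic, 2 * 1 - 2 * fit$loglik)
  expect_equal(fit$bic, log(nrow(ipd)) - 2 * fit$loglik)
})

test_that("fitting rejects degenerate inputs", {
  expect_error(fit_parametric(pseudo_ipd(c(1, 2), c(0L, 0L)), "weibull"),
               "zero events")
  bad <- data.frame(time = c(-1, 2), event = c(1L, 1L))
  expect_error(fit_parametric(bad, "exponential"), "non-positive")
})

test_that("Weibull parameters are recovered from censored simulation", {
  ipd <- make_weibull_ipd(5000, shape = 1.4, scale = 20, cens_q = 80,
                          seed = 3)
  expect_gt(mean(1 - ipd$event), 0.1)  # meaningful censoring share
  fit <- fit_parametric(ipd, "weibull")
  expect_lt(abs(fit$params[["scale"]] - 20) / 20, 0.05)
  expect_lt(abs(fit$params[["shape"]] - 1.4) / 1.4, 0.05)
  expect_true(fit$converged)
})

test_that("Weibull shape approaches 1 on exponential data (nesting)", {
  ipd <- make_weibull_ipd(5000, shape = 1, scale = 10, seed = 4)
  fit <- fit_parametric(ipd, "weibull")
  expect_lt(abs(fit$params[["shape"]] - 1), 0.05)
})

test_that("fitted log-likelihood dominates perturbed parameter points", {
  ipd <- make_weibull_ipd(800, shape = 1.3, scale = 25, cens_q = 90,
                          seed = 5)
  fit <- fit_parametric(ipd, "weibull")
  loglik_weibull <- function(scale, shape) {
    d <- ipd$event == 1
    sum(stats::dweibull(ipd$time[d], shape, scale, log = TRUE)) +
      sum(-(ipd$time[!d] / scale)^shape)
  }
  ll_hat <- loglik_weibull(fit$params[["scale"]], fit$params[["shape"]])
  expect_equal(ll_hat, fit$loglik, tolerance = 1e-6)
  set.seed(6)
  for (i in 1:100) {
    eps <- stats::rnorm(2, 0, 0.05)
    ll_pert <- loglik_weibull(fit$params[["scale"]] * exp(eps[1]),
                              fit$params[["shape"]] * exp(eps[2]))
    expect_lte(ll_pert, ll_hat + 1e-6)
  }
})

test_that("select_best minimizes the criterion with the documented tie rules", {
  ipd <- make_weibull_ipd(1000, shape = 1, scale = 10, seed = 7)
  fits <- fit_all_parametric(ipd)
  expect_identical(select_best(fits["weibull"], "AIC")$family, "weibull")
  expect_identical(select_best(fits, "BIC")$family, "exponential")
  expect_error(select_best(list()), "empty")

  # manufactured tie: equal criterion values, 1-parameter family wins
  f1 <- surv_fit("exponential", c(rate = 0.1)); f1$aic <- 100
  f2 <- surv_fit("weibull", c(scale = 10, shape = 1)); f2$aic <- 100
  expect_identical(select_best(list(f2, f1), "AIC")$family, "exponential")
})

test_that("survival functions behave as distributions", {
  fits <- list(
    surv_fit("exponential", c(rate = 0.07)),
    surv_fit("weibull", c(scale = 20, shape = 1.4)),
    surv_fit("loglogistic", c(scale = 20, shape = 1.7)),
    surv_fit("lognormal", c(meanlog = log(20), sdlog = 0.6)))
  tt <- seq(0, 500, by = 0.5)
  for (f in fits) {
    s <- surv_prob(f, tt)
    expect_equal(s[1], 1)
    expect_true(all(diff(s) <= 0))
    expect_lt(surv_prob(f, 1e6), 1e-3)
  }
})

test_that("per-cycle transition probabilities telescope exactly", {
  f <- surv_fit("exponential", c(rate = 0.1))
  expect_equal(cycle_transition_prob(f, 0:9, 3), rep(1 - exp(-0.3), 10))

  fw <- surv_fit("weibull", c(scale = 20, shape = 1.2))
  expect_equal(cycle_transition_prob(fw, 1, 3),
               1 - exp(-(6 / 20)^1.2 + (3 / 20)^1.2))
  # numeric oracle for the same quantity
  expect_equal(cycle_transition_prob(fw, 1, 3),
               1 - surv_prob(fw, 6) / surv_prob(fw, 3), tolerance = 1e-12)

  for (f in list(fw, surv_fit("lognormal", c(meanlog = 3, sdlog = 0.5)))) {
    K <- 40
    p <- cycle_transition_prob(f, 0:(K - 1), 3)
    expect_equal(prod(1 - p), surv_prob(f, K * 3), tolerance = 1e-10)
  }
  # exhausted survival: exit probability 1 by convention
  fx <- surv_fit("weibull", c(scale = 1, shape = 8))
  expect_equal(cycle_transition_prob(fx, 400, 3), 1)
})

test_that("median survival closed forms are correct", {
  expect_equal(median_survival(surv_fit("exponential", c(rate = 0.1))),
               log(2) / 0.1)
  expect_equal(median_survival(surv_fit("weibull",
                                        c(scale = 10, shape = 1))),
               log(2) / 0.1)
  expect_equal(median_survival(surv_fit("lognormal",
                                        c(meanlog = log(20), sdlog = 0.5))),
               20)
  expect_equal(median_survival(surv_fit("loglogistic",
                                        c(scale = 15, shape = 2))), 15)
  # each median satisfies S(median) = 1/2
  for (f in list(surv_fit("weibull", c(scale = 33, shape = 1.3)),
                 surv_fit("loglogistic", c(scale = 12, shape = 2.1)),
                 surv_fit("lognormal", c(meanlog = 2.5, sdlog = 0.8))))
    expect_equal(surv_prob(f, median_survival(f)), 0.5, tolerance = 1e-12)
})

test_that("fit summary table flags the selected family", {
  dir <- withr::local_tempdir()
  ipd <- make_weibull_ipd(500, shape = 1.5, scale = 15, seed = 8)
  tab <- write_fit_summary(fit_all_parametric(ipd),
                           file.path(dir, "fits.csv"))
  expect_equal(sum(tab$selected), 1)
  expect_setequal(tab$family,
                  c("weibull", "exponential", "loglogistic", "lognormal"))
  expect_true(file.exists(file.path(dir, "fits.csv")))
})
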