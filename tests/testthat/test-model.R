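test_that("4PL response has the stated asymptotes and midpoint", {
  th <- fourpl_params(0.1, 0.6, 0.8, 0.2)
  expect_equal(fourpl_response(0.8, th), 0.1 + 0.6 / 2)
  expect_equal(fourpl_response(1e6, th), 0.7)
  expect_equal(fourpl_response(-1e6, th), 0.1)
  # huge exponent arguments stay finite (saturate to the asymptote)
  th2 <- fourpl_params(0.05, 0.5, 2, 1e-4)
  expect_true(all(is.finite(fourpl_response(c(0, 1.999, 2.001, 4), th2))))
})

test_that("4PL response matches direct evaluation at the simulation truth", {
  # frozen values computed independently by direct arithmetic on the curve
  expect_equal(fourpl_response(c(0, 0.5, 1, 2, 4), trial_truth()),
               c(0.0181786593, 0.2961563965, 0.5559849998,
                 0.5704882259, 0.5705000000),
               tolerance = 1e-9)
})

test_that("invalid 4PL parameters are rejected", {
  expect_error(fourpl_params(-0.1, 0.5, 1, 0.2), "p0")
  expect_error(fourpl_params(0.6, 0.6, 1, 0.2), "Emax")
  expect_error(fourpl_params(0.1, 0.5, 1, 0), "delta")
  expect_error(fourpl_response(1, c(0.1, NA, 1, 0.2)), "finite")
})

test_that("Emax reparameterization round-trips through the target point", {
  expect_equal(emax_from_pstar(0.3, dstar = 0.49, p0 = 0.0015,
                               ED50 = 0.49, delta = 0.14),
               2 * (0.3 - 0.0015))
  expect_equal(emax_from_pstar(0.2, 1.3, 0.2, 0.7, 0.3), 0)
  set.seed(11)
  for (k in 1:50) {
    p0 <- runif(1, 0, 0.3); ED50 <- runif(1, 0.1, 3)
    delta <- runif(1, 0.05, 1.5); dstar <- runif(1, 0, 4)
    pstar <- runif(1, p0, 0.95)
    Emax <- emax_from_pstar(pstar, dstar, p0, ED50, delta)
    th <- c(p0, Emax, ED50, delta)
    expect_equal(plband:::fourpl_eval(dstar, th[1], th[2], th[3], th[4]),
                 pstar, tolerance = 1e-12)
  }
})

test_that("binomial log-likelihood matches independent arithmetic", {
  # single group, curve flat at the observed proportion = saturated value
  one <- dose_response_data(c(0, 1), c(7L, 7L), c(20L, 20L))
  flat <- fourpl_params(0.35, 0, 1, 0.5)
  expect_equal(binomial_loglik(flat, one), 2 * -12.9489327807,
               tolerance = 1e-9)
  # zero events with the response clamped near zero: log-lik tends to 0
  zero <- dose_response_data(c(0, 1), c(0L, 0L), c(20L, 20L))
  expect_equal(binomial_loglik(fourpl_params(0, 0, 1, 0.5), zero), 0,
               tolerance = 1e-6)
  # trial data at the printed coefficients: frozen term-by-term sum
  expect_equal(binomial_loglik(trial_truth(), trial_data()),
               -166.259458, tolerance = 1e-5)
})

test_that("ML fit reproduces the trial coefficients and beats grid points", {
  fit <- trial_fit()
  expect_true(fit$converged)
  est <- coef(fit)
  expect_lt(abs(est[["p0"]] * 100 - 0.15), 0.05)
  expect_lt(abs(est[["Emax"]] * 100 - 56.9), 0.5)
  expect_lt(abs(est[["ED50"]] - 0.49), 0.01)
  expect_lt(abs(est[["delta"]] - 0.14), 0.01)
  # optimum dominates a coarse 4-D grid over the parameter box
  dat <- trial_data()
  grid <- expand.grid(p0 = seq(0, 0.3, length.out = 7),
                      Emax = seq(0.05, 0.95, length.out = 7),
                      ED50 = seq(0.01, 4, length.out = 7),
                      delta = seq(0.01, 3, length.out = 7))
  ok <- grid$p0 + grid$Emax <= 1
  ll <- apply(grid[ok, ], 1L, function(r)
    plband:::loglik_raw(dat$dose, dat$responders, dat$total,
                        r[1], r[2], r[3], r[4]))
  expect_gt(fit$loglik, max(ll) - 1e-8)
  # and the constant-model (pooled proportion) log-likelihood
  pool <- sum(dat$responders) / sum(dat$total)
  ll0 <- sum(dat$responders * log(pool) +
               (dat$total - dat$responders) * log(1 - pool))
  expect_gt(fit$loglik, ll0)
})

test_that("parameters are recovered from data generated on the curve", {
  truth <- trial_truth()
  p <- fourpl_response(c(0, 0.5, 1, 2, 4), truth)
  big <- dose_response_data(c(0, 0.5, 1, 2, 4),
                            round(p * 10000), rep(10000L, 5))
  fit <- fit_fourpl(big)
  expect_equal(unname(coef(fit)), unname(truth), tolerance = 0.05)
})

test_that("delta-method se agrees with parametric-bootstrap spread", {
  fit <- trial_fit()
  dat <- trial_data()
  se <- predict(fit, dat$dose, se.fit = TRUE)$se.fit
  set.seed(42)
  p <- predict(fit, dat$dose)
  sims <- replicate(500, {
    y <- rbinom(5, dat$total, p)
    f <- fit_fourpl(dose_response_data(dat$dose, y, dat$total),
                    vcov = FALSE)
    predict(f, dat$dose)
  })
  emp_sd <- apply(sims, 1L, sd)
  # the linearization tracks the resampling spread at the design doses
  # except 1 mg, where strong curvature of the fitted surface makes the
  # delta-method se conservative (larger than the resampling sd)
  expect_true(all((abs(se - emp_sd) / emp_sd)[-3] < 0.25))
  expect_gt(se[3], emp_sd[3])
  expect_lt(se[3], 2 * emp_sd[3])
})

test_that("profile log-likelihood peaks at the fitted response", {
  fit <- trial_fit()
  dat <- trial_data()
  for (d in c(0, 0.5, 2)) {
    ph <- predict(fit, d)
    at_peak <- profile_loglik(dat, d, ph, fit = fit)
    expect_equal(at_peak$loglik, fit$loglik, tolerance = 1e-4)
    # profile is unimodal and never exceeds the unconstrained maximum
    ps <- seq(max(ph - 0.15, 0.001), min(ph + 0.15, 0.999), length.out = 31)
    ll <- vapply(ps, function(p)
      profile_loglik(dat, d, p, fit = fit)$loglik, numeric(1))
    expect_true(all(ll <= fit$loglik + 1e-6))
    below <- ps < ph
    expect_true(all(diff(ll[below]) > -1e-3))
    expect_true(all(diff(ll[!below]) < 1e-3))
  }
})

test_that("profiled curve passes through the target and stays valid", {
  fit <- trial_fit()
  dat <- trial_data()
  r <- profile_loglik(dat, 1.2, 0.4, fit = fit)
  expect_true(r$converged)
  expect_equal(unname(fourpl_response(1.2, r$params)), 0.4,
               tolerance = 1e-6)
  expect_gte(r$params[["p0"]], 0)
  expect_lte(r$params[["p0"]] + r$params[["Emax"]], 1 + 1e-4)
})
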