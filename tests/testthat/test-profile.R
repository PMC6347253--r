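test_that("chi-squared threshold drops by the textbook amounts", {
  expect_equal(ci_threshold(0, 0.05), -1.92073, tolerance = 1e-4)
  expect_equal(ci_threshold(-100, 0.05), -101.92073, tolerance = 1e-4)
  # alpha -> 1: the drop vanishes
  expect_equal(ci_threshold(5, 1 - 1e-9), 5, tolerance = 1e-6)
  # chi-squared(1) quantile at 1 - 0.3173 is ~1 (normal-square relation)
  expect_equal(ci_threshold(0, 0.3173), -0.5, tolerance = 1e-3)
  expect_error(ci_threshold(0, 1.2), "alpha")
  expect_error(ci_threshold(Inf, 0.05), "finite")
})

test_that("initial brackets follow the dose-ordered propagation rules", {
  est <- c(0.02, 0.30, 0.57)
  se <- c(0.015, 0.05, 0.12)
  # highest dose, upper side: phat + 5 se, capped at 1
  expect_equal(initial_bracket(3, "upper", est, se, rep(NA_real_, 3)),
               c(0.57, 1))
  se2 <- c(0.015, 0.05, 0.01)
  expect_equal(initial_bracket(3, "upper", est, se2, rep(NA_real_, 3)),
               c(0.57, 0.62))
  # inner dose inherits the next-higher upper limit
  expect_equal(initial_bracket(2, "upper", est, se, c(NA, NA, 0.8)),
               c(0.30, 0.8))
  # lowest dose, lower side: [0, phat]; inner inherits next-lower limit
  expect_equal(initial_bracket(1, "lower", est, se, rep(NA_real_, 3)),
               c(0, 0.02))
  expect_equal(initial_bracket(2, "lower", est, se, c(0.004, NA, NA)),
               c(0.004, 0.30))
  expect_error(initial_bracket(2, "upper", est, se, rep(NA_real_, 3)),
               "ordering contract")
  expect_error(initial_bracket(2, "lower", est, se, rep(NA_real_, 3)),
               "ordering contract")
})

test_that("brackets from the trial fit contain the scan-oracle limit", {
  fit <- trial_fit()
  dat <- trial_data()
  pr <- predict(fit, dat$dose, se.fit = TRUE)
  up4 <- initial_bracket(5, "upper", pr$fit, pr$se.fit, rep(NA_real_, 5))
  lim4 <- scan_limit(dat, fit, 4, "upper", step = 1e-3)
  expect_true(up4[1] <= lim4 && lim4 <= up4[2])
  lo0 <- initial_bracket(1, "lower", pr$fit, pr$se.fit, rep(NA_real_, 5))
  lim0 <- scan_limit(dat, fit, 0, "lower", step = 1e-3)
  expect_true(lo0[1] <= lim0 && lim0 <= lo0[2])
})

test_that("bisection finds the threshold crossing of the profile", {
  fit <- trial_fit()
  dat <- trial_data()
  cfg <- ci_config()
  for (cs in list(list(d = 4, side = "upper"),
                  list(d = 1, side = "upper"),
                  list(d = 0.5, side = "lower"))) {
    ph <- predict(fit, cs$d)
    se <- predict(fit, cs$d, se.fit = TRUE)$se.fit
    br <- if (cs$side == "upper") c(ph, min(1, ph + 5 * se)) else c(0, ph)
    res <- bisection_limit(cs$d, cs$side, br, dat, fit, cfg)
    expect_true(res$converged)
    oracle <- scan_limit(dat, fit, cs$d, cs$side, step = 1e-4)
    expect_lt(abs(res$value - oracle), 3e-4)
    # the returned limit sits essentially on the threshold
    thr <- ci_threshold(fit$loglik)
    expect_equal(profile_loglik(dat, cs$d, res$value, fit = fit)$loglik,
                 thr, tolerance = 0.05)
  }
})

test_that("bisection is self-consistent under tolerance refinement", {
  fit <- trial_fit()
  dat <- trial_data()
  ph <- predict(fit, 2)
  se <- predict(fit, 2, se.fit = TRUE)$se.fit
  br <- c(ph, min(1, ph + 5 * se))
  coarse <- bisection_limit(2, "upper", br, dat, fit,
                            ci_config(bisect_tol = 1e-3))
  fine <- bisection_limit(2, "upper", br, dat, fit,
                          ci_config(bisect_tol = 1e-4))
  expect_lt(abs(coarse$value - fine$value), 1e-3)
})

test_that("crude search stops at the threshold and agrees with bisection", {
  fit <- trial_fit()
  dat <- trial_data()
  cfg <- ci_config()
  # upper limit at the lowest dose vs the fine scan oracle
  ph0 <- predict(fit, 0)
  res <- crude_search_limit(0, "upper", ph0, dat, fit, cfg)
  expect_true(res$converged)
  expect_equal(res$method, "crude_search")
  oracle <- scan_limit(dat, fit, 0, "upper", step = 1e-4)
  expect_lt(abs(res$value - oracle), cfg$fine_step + 1e-4)
  # near-degenerate confidence level: no step passes, start returned
  res0 <- crude_search_limit(1, "upper", predict(fit, 1), dat, fit,
                             ci_config(alpha = 1 - 1e-9))
  expect_lt(abs(res0$value - predict(fit, 1)), 1e-12)
  # where bisection also works the two methods agree within the coarse step
  ph <- predict(fit, 2)
  se <- predict(fit, 2, se.fit = TRUE)$se.fit
  bis <- bisection_limit(2, "upper", c(ph, min(1, ph + 5 * se)),
                         dat, fit, cfg)
  cru <- crude_search_limit(2, "upper", ph, dat, fit, cfg)
  expect_lt(abs(bis$value - cru$value), cfg$coarse_step)
})

test_that("full band is ordered, bounded, nested across levels", {
  fit <- trial_fit()
  dat <- trial_data()
  band <- profile_ci_curve(dat, fit = fit)
  df <- as.data.frame(band)
  expect_equal(nrow(df), 41L)
  expect_true(all(df$converged))
  expect_true(all(df$lower >= 0 & df$upper <= 1))
  expect_true(all(df$lower <= df$estimate & df$estimate <= df$upper))
  # the model beats the constant model decisively (LR test), so the
  # limits are monotone in dose up to the bisection tolerance
  pool <- sum(dat$responders) / sum(dat$total)
  ll0 <- sum(dat$responders * log(pool) +
               (dat$total - dat$responders) * log(1 - pool))
  lr <- 2 * (fit$loglik - ll0)
  expect_gt(lr, qchisq(0.95, df = 3))
  expect_true(all(diff(df$lower) > -2e-4))
  expect_true(all(diff(df$upper) > -2e-4))
  # narrower confidence level nests inside the wider one
  cfg10 <- ci_config(alpha = 0.10, grid = c(0, 0.5, 1, 2, 4))
  cfg05 <- ci_config(alpha = 0.05, grid = c(0, 0.5, 1, 2, 4))
  b10 <- profile_ci_curve(dat, cfg10, fit = fit)
  b05 <- profile_ci_curve(dat, cfg05, fit = fit)
  expect_true(all(b05$lower <= b10$lower + 1e-6))
  expect_true(all(b10$upper <= b05$upper + 1e-6))
})

test_that("every returned limit sits on the chi-squared threshold", {
  fit <- trial_fit()
  dat <- trial_data()
  cfg <- ci_config(grid = c(0, 0.5, 1, 2, 4))
  band <- profile_ci_curve(dat, cfg, fit = fit)
  thr <- ci_threshold(fit$loglik, cfg$alpha)
  for (i in seq_len(nrow(band))) {
    for (lim in c(band$lower[i], band$upper[i])) {
      ll <- profile_loglik(dat, band$dose[i], lim, fit = fit)$loglik
      expect_gte(ll, thr - 0.05)
      if (abs(lim - band$estimate[i]) > 1e-6) {
        out <- lim + sign(lim - band$estimate[i]) * 2 * cfg$coarse_step
        out <- min(max(out, 0), 1)
        llo <- profile_loglik(dat, band$dose[i], out, fit = fit)$loglik
        expect_lt(llo, thr + 1e-3)
      }
    }
  }
})

test_that("grid outside the observed dose range is rejected", {
  expect_error(profile_ci_curve(trial_data(), ci_config(grid = c(0, 5)),
                                fit = trial_fit()),
               "dose range")
})
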