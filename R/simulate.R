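#' Simulate one grouped binomial dose-response dataset
#'
#' Draws `responders[i] ~ Binomial(n_per_group, f(design[i]; truth))` from a
#' 4PL truth, mirroring a parallel-group dose-finding trial with equal group
#' sizes. Uses the current RNG stream unless `seed` is given, so callers can
#' manage reproducible substreams themselves.
#'
#' @param truth True 4PL coefficients ([fourpl_params()]).
#' @param design Dose vector; default is the bundled trial design
#'   0, 0.5, 1, 2, 4 mg.
#' @param n_per_group Subjects per dose group.
#' @param seed Optional integer seed.
#' @return A [dose_response_data()] object.
#' @examples
#' truth <- fourpl_params(0.0015, 0.569, 0.49, 0.14)
#' simulate_dataset(truth, n_per_group = 50, seed = 1)
#' @export
simulate_dataset <- function(truth, design = c(0, 0.5, 1, 2, 4),
                             n_per_group, seed = NULL) {
  check_fourpl(truth)
  stopifnot(n_per_group >= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- fourpl_response(design, truth)
  y <- stats::rbinom(length(design), n_per_group, p)
  dose_response_data(design, y, rep.int(n_per_group, length(design)))
}

#' Coverage simulation study for pointwise CI methods
#'
#' Repeatedly simulates trials from a 4PL truth, constructs pointwise CIs
#' for the expected response by the requested methods, and tallies per-dose
#' coverage of the true response, per-method construction success, and the
#' largest observed limit excursions in units of the delta-method standard
#' error (the quantity that motivates the `phat + 5*se` initial bracket of
#' the band algorithm).
#'
#' Bookkeeping: for every (dose, method), `covered + noncovered + failed`
#' equals `n_sim`. A replicate counts as a construction failure for the
#' profile method when the unconstrained fit fails or more than 10% of grid
#' doses remain non-converged after the crude-search fallback; `coverage`
#' is the proportion covered among the non-failed ones (the denominator the
#' summary reports). se-multiples are recorded only where `se > 1e-8`.
#'
#' @param truth True 4PL coefficients; default: the ML estimates from the
#'   bundled trial (p0 = 0.15%, Emax = 56.9%, ED50 = 0.49 mg, delta = 0.14).
#' @param design Dose design (default 0, 0.5, 1, 2, 4 mg).
#' @param n_per_group Subjects per dose group.
#' @param n_sim Number of replicate datasets (default 1000).
#' @param alpha Nominal two-sided error rate.
#' @param methods Subset of `c("profile", "wald", "bootstrap")`.
#' @param grid Doses at which CIs are evaluated; default the design doses.
#' @param bootstrap_B Resamples per replicate for the bootstrap method.
#' @param seed Master seed; per-replicate seeds are drawn from it once, so
#'   replicate `r` is reproducible in isolation.
#' @param config Optional [ci_config()] overriding the profile-band
#'   settings (its `alpha`/`grid` are replaced by the arguments above).
#' @return A data frame of class `"coverage_study"` with one row per
#'   (method, dose): `covered`, `noncovered`, `failed`, `coverage`,
#'   `success_rate`, `max_multiple_lower`, `max_multiple_upper`; attributes
#'   carry the configuration.
#' @examples
#' \donttest{
#' run_coverage_study(n_per_group = 50, n_sim = 20, seed = 1,
#'                    grid = 2, methods = "profile")
#' }
#' @export
run_coverage_study <- function(truth = fourpl_params(0.0015, 0.569, 0.49, 0.14),
                               design = c(0, 0.5, 1, 2, 4),
                               n_per_group, n_sim = 1000, alpha = 0.05,
                               methods = "profile", grid = design,
                               bootstrap_B = 1000, seed = 1,
                               config = NULL) {
  check_fourpl(truth)
  methods <- match.arg(methods, c("profile", "wald", "bootstrap"),
                       several.ok = TRUE)
  stopifnot(n_sim >= 1, n_per_group >= 1)
  grid <- sort(grid)
  ng <- length(grid)
  true_p <- fourpl_response(grid, truth)
  if (is.null(config)) config <- ci_config(alpha = alpha, grid = grid)
  else { config$alpha <- alpha; config$grid <- grid }

  set.seed(seed)
  rep_seeds <- sample.int(2147483646L, n_sim)

  tally <- function() list(cov = integer(ng), non = integer(ng),
                           fail = integer(ng), rep_fail = 0L,
                           mult_lo = rep(-Inf, ng), mult_up = rep(-Inf, ng))
  acc <- stats::setNames(lapply(methods, function(m) tally()), methods)

  record <- function(a, curve, se) {
    dose_ok <- curve$converged & is.finite(curve$lower) &
      is.finite(curve$upper)
    inside <- dose_ok & curve$lower <= true_p & true_p <= curve$upper
    a$cov <- a$cov + as.integer(inside)
    a$non <- a$non + as.integer(dose_ok & !inside)
    a$fail <- a$fail + as.integer(!dose_ok)
    usable <- dose_ok & is.finite(se) & se > 1e-8
    ml <- ifelse(usable, (curve$estimate - curve$lower) / se, -Inf)
    mu <- ifelse(usable, (curve$upper - curve$estimate) / se, -Inf)
    a$mult_lo <- pmax(a$mult_lo, ml)
    a$mult_up <- pmax(a$mult_up, mu)
    a
  }
  fail_all <- function(a) {
    a$fail <- a$fail + 1L
    a$rep_fail <- a$rep_fail + 1L
    a
  }

  for (r in seq_len(n_sim)) {
    set.seed(rep_seeds[r])
    dat <- simulate_dataset(truth, design, n_per_group)
    fit <- tryCatch(fit_fourpl(dat), error = function(e) NULL)
    se <- if (!is.null(fit)) predict(fit, grid, se.fit = TRUE)$se.fit
          else rep(NA_real_, ng)

    for (m in methods) {
      if (is.null(fit) || !fit$converged) {
        acc[[m]] <- fail_all(acc[[m]]); next
      }
      curve <- switch(m,
        profile = tryCatch(profile_ci_curve(dat, config, fit = fit),
                           error = function(e) NULL),
        wald = tryCatch(wald_ci_curve(dat, fit, grid, alpha),
                        error = function(e) NULL),
        bootstrap = tryCatch(
          suppressWarnings(bootstrap_ci_curve(dat, grid, bootstrap_B,
                                              alpha, fit = fit)),
          error = function(e) NULL))
      bad <- is.null(curve) ||
        (m == "profile" && mean(!curve$converged) > 0.10)
      acc[[m]] <- if (bad) fail_all(acc[[m]]) else record(acc[[m]], curve, se)
    }
  }

  rows <- lapply(methods, function(m) {
    a <- acc[[m]]
    denom <- a$cov + a$non
    data.frame(method = m, dose = grid,
               covered = a$cov, noncovered = a$non, failed = a$fail,
               coverage = ifelse(denom > 0, a$cov / denom, NA_real_),
               success_rate = 1 - a$rep_fail / n_sim,
               max_multiple_lower = ifelse(is.finite(a$mult_lo),
                                           a$mult_lo, NA_real_),
               max_multiple_upper = ifelse(is.finite(a$mult_up),
                                           a$mult_up, NA_real_),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("coverage_study", "data.frame")
  attr(out, "truth") <- truth
  attr(out, "n_per_group") <- n_per_group
  attr(out, "n_sim") <- n_sim
  attr(out, "alpha") <- alpha
  attr(out, "seed") <- seed
  out
}

#' @export
print.coverage_study <- function(x, ...) {
  cat(sprintf(
    "Coverage study: n = %d per group, %d replicates, nominal %g%%\n",
    attr(x, "n_per_group"), attr(x, "n_sim"),
    100 * (1 - attr(x, "alpha"))))
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}
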