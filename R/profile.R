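#' Likelihood-ratio threshold for a profile CI
#'
#' A value `p*` lies inside the `1 - alpha` profile-likelihood CI when its
#' profile log-likelihood stays above
#' `loglik_max - 0.5 * qchisq(1 - alpha, df = 1)`; the confidence limits are
#' the crossings of that threshold. For `alpha = 0.05` the drop below the
#' maximum is 1.92073.
#'
#' @param loglik_max Maximized (unconstrained) log-likelihood.
#' @param alpha Two-sided error rate, in (0, 1).
#' @return The threshold log-likelihood value.
#' @export
ci_threshold <- function(loglik_max, alpha = 0.05) {
  if (!is.finite(loglik_max)) stop("'loglik_max' must be finite", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be a single value in (0, 1)", call. = FALSE)
  loglik_max - 0.5 * stats::qchisq(1 - alpha, df = 1)
}

#' Configuration for profile-likelihood band computation
#'
#' @param alpha Nominal two-sided error rate (default 0.05).
#' @param grid Optional dose grid; default is an equidistant grid from the
#'   lowest to the highest observed dose with spacing `grid_step` (for the
#'   bundled trial, 0 to 4 mg by 0.1 gives 41 points).
#' @param grid_step Grid spacing when `grid` is not supplied.
#' @param bisect_tol Bisection stopping width on the probability scale.
#' @param coarse_step Crude-search coarse step (probability scale).
#' @param fine_step Crude-search refinement step.
#' @param crude_trigger Fitted response below which the crude search is used
#'   directly instead of bisection (responses close to 0 are where the
#'   constrained fits are fragile).
#' @return A list of class `"ci_config"`.
#' @export
ci_config <- function(alpha = 0.05, grid = NULL, grid_step = 0.1,
                      bisect_tol = 1e-4, coarse_step = 0.01,
                      fine_step = 0.001, crude_trigger = 0.01) {
  stopifnot(alpha > 0, alpha < 1,
            bisect_tol > 0, bisect_tol < 1,
            coarse_step > 0, coarse_step < 1,
            fine_step > 0, fine_step <= coarse_step,
            grid_step > 0)
  structure(list(alpha = alpha, grid = grid, grid_step = grid_step,
                 bisect_tol = bisect_tol, coarse_step = coarse_step,
                 fine_step = fine_step, crude_trigger = crude_trigger),
            class = "ci_config")
}

## Negative profile objective. The expected response pstar at dstar is the
## profiled parameter; one 4PL coefficient is eliminated so that the curve
## passes exactly through (dstar, pstar). Algebraically this is the Emax
## substitution Emax = (pstar - p0) * A with A = 1 + exp((ED50-dstar)/delta);
## numerically the fit iterates over th = (Emax, ED50, delta) and recovers
## p0 = pstar - Emax / A. The two eliminations describe the same constrained
## model, but the (Emax, ED50, delta) coordinates stay well conditioned when
## pstar is tiny and A is huge (small-response doses), where (p0, ED50,
## delta) coordinates would need p0 to track pstar to ~1e-9.
nll_profile <- function(th, dose, y, N, dstar, pstar)
  cpp_nll_profile(th, dose, y, N, dstar, pstar)

nll_profile_grad <- function(th, dose, y, N, dstar, pstar)
  cpp_nll_profile_grad(th, dose, y, N, dstar, pstar)

#' Profile log-likelihood of the expected response at a dose
#'
#' Maximizes the binomial log-likelihood over all 4PL curves passing
#' exactly through `(dstar, pstar)` — the reparameterization in which the
#' expected response at a chosen dose is itself a parameter (see
#' [emax_from_pstar()]). Internally the optimizer iterates over
#' `(Emax, ED50, delta)` with the basal effect recovered as
#' `p0 = pstar - Emax/A`, `A = 1 + exp((ED50 - dstar)/delta)`: this is the
#' same constrained model but stays numerically well conditioned at doses
#' with a tiny expected response. The box `Emax >= 0` keeps the curve
#' monotone increasing; smooth penalties keep `p0 >= 0` and
#' `p0 + Emax <= 1`.
#'
#' @param data A [dose_response_data()] object.
#' @param dstar Dose at which the expected response is profiled.
#' @param pstar Target expected response, in `[0, 1]`.
#' @param start Optional start: a nuisance triple `(p0, ED50, delta)` or a
#'   full coefficient vector `(p0, Emax, ED50, delta)`; warm starts from a
#'   nearby constrained fit are the main convergence device of the band
#'   algorithm.
#' @param fit Optional `fourpl_fit` supplying the default start.
#' @return List with `loglik` (the profile log-likelihood at `pstar`),
#'   `nuisance` (the maximizing triple), `Emax` (implied), `params` (the
#'   full implied 4PL vector) and `converged`.
#' @examples
#' dat <- trial_nct02131662()
#' fit <- fit_fourpl(dat)
#' ph <- predict(fit, 1)
#' profile_loglik(dat, dstar = 1, pstar = ph)$loglik  # equals logLik(fit)
#' @export
profile_loglik <- function(data, dstar, pstar, start = NULL, fit = NULL) {
  stopifnot(inherits(data, "dose_response_data"),
            pstar >= 0, pstar <= 1)
  box <- param_box(data)
  if (is.null(start)) {
    if (is.null(fit)) fit <- fit_fourpl(data)
    start <- unname(fit$par)
  }
  start <- unname(start)
  # internal coordinates are (Emax, ED50, delta); a (p0, ED50, delta) start
  # is converted through the Emax substitution
  st_emax <- if (length(start) == 4L) start[c(2L, 3L, 4L)] else
    c(emax_from_pstar(pstar, dstar, min(start[1], pstar),
                      start[2], start[3]),
      start[2], start[3])
  st <- pmin(pmax(st_emax, c(0, box$lower[3], box$lower[4])),
             c(1, box$upper[3], box$upper[4]))
  # project the start into the feasible region p0 >= 0 (i.e. Emax/A <=
  # pstar): a start violating it puts the optimizer on the steep penalty
  # wall, from which it can be flung into a spurious basin. Prefer
  # steepening the curve (smaller delta raises A) and otherwise shrink Emax.
  A0 <- 1 + exp(pmin((st[2] - dstar) / st[3], 700))
  if (st[1] / A0 > pstar) {
    A_need <- st[1] / max(pstar, 1e-10) * 1.05
    if (st[2] > dstar && A_need > 2) {
      d_new <- (st[2] - dstar) / log(A_need - 1)
      if (d_new >= box$lower[4] && d_new < st[3]) st[3] <- d_new
    }
    A0 <- 1 + exp(pmin((st[2] - dstar) / st[3], 700))
    if (st[1] / A0 > pstar) st[1] <- max(pstar, 1e-10) * A0 * 0.95
    st[1] <- min(st[1], 1)
  }
  ans <- nlminb_robust(st, nll_profile,
                       lower = c(0, box$lower[3], box$lower[4]),
                       upper = c(1, box$upper[3], box$upper[4]),
                       gradient = nll_profile_grad,
                       dose = data$dose, y = data$responders,
                       N = data$total, dstar = dstar, pstar = pstar)
  if (!is.finite(ans$objective))
    return(list(loglik = NA_real_, nuisance = st, Emax = NA_real_,
                params = NULL, converged = FALSE))
  Emax <- ans$par[1]; ED50 <- ans$par[2]; delta <- ans$par[3]
  A <- 1 + exp(pmin((ED50 - dstar) / delta, 700))
  p0 <- max(pstar - Emax / A, 0)
  list(loglik = -ans$objective,
       nuisance = c(p0, ED50, delta),
       Emax = Emax,
       params = c(p0 = p0, Emax = unname(Emax),
                  ED50 = ED50, delta = delta),
       converged = ans$converged)
}

## One constrained fit inside the band computation. `state` is the per-side
## warm-start slot: last successful nuisance estimates, seeded from the
## unconstrained fit. A warm-started fit can settle in a local optimum
## carried over from a far bracket endpoint; since only the sign of
## (profile - threshold) decides the limit, any value below the threshold
## is re-checked from the unconstrained estimates and the better optimum
## kept. Returns the profile log-likelihood, or NA when no start converges.
prof_eval <- function(pstar, dstar, data, fit, state) {
  state$evals <- state$evals + 1L
  r1 <- profile_loglik(data, dstar, pstar, start = state$nuis)
  best <- if (r1$converged && is.finite(r1$loglik)) r1 else NULL
  if (is.null(best) || best$loglik < state$thr) {
    r2 <- profile_loglik(data, dstar, pstar, start = unname(fit$par))
    if (r2$converged && is.finite(r2$loglik) &&
        (is.null(best) || r2$loglik > best$loglik))
      best <- r2
  }
  if (is.null(best)) return(NA_real_)
  state$nuis <- unname(best$params)
  best$loglik
}

#' Initial bisection bracket for one confidence limit
#'
#' Implements the dose-ordered bracket propagation: upper limits are
#' computed from the highest dose downwards, so every non-top dose can use
#' the already-computed upper limit of the next-higher dose as its upper
#' bracket endpoint (profile limits of a monotone model are monotone in
#' dose when the model beats the constant model on a likelihood-ratio
#' test). At the highest dose the upper endpoint is
#' `min(1, phat + 5*se(phat))`; at the lowest dose the lower-limit bracket
#' starts at 0. The endpoint nearer the estimate is always `phat` itself.
#'
#' @param index Position in the dose grid (1 = lowest dose).
#' @param side `"lower"` or `"upper"`.
#' @param estimate Vector of fitted responses over the grid.
#' @param se Vector of delta-method standard errors over the grid.
#' @param previous Vector of already-computed limits for this side (`NA`
#'   where not yet computed).
#' @return Numeric interval `c(lo, hi)` containing the limit.
#' @export
initial_bracket <- function(index, side = c("lower", "upper"),
                            estimate, se, previous) {
  side <- match.arg(side)
  n <- length(estimate)
  ph <- estimate[index]
  if (side == "upper") {
    if (index == n) {
      s <- se[index]
      hi <- if (is.finite(s)) min(1, ph + 5 * s) else 1
      c(ph, max(hi, ph))
    } else {
      nb <- previous[index + 1L]
      if (!is.finite(nb))
        stop("ordering contract violated: upper limit at the next-higher ",
             "dose has not been computed yet", call. = FALSE)
      c(ph, max(nb, ph))
    }
  } else {
    if (index == 1L) {
      c(0, ph)
    } else {
      nb <- previous[index - 1L]
      if (!is.finite(nb))
        stop("ordering contract violated: lower limit at the next-lower ",
             "dose has not been computed yet", call. = FALSE)
      c(min(nb, ph), ph)
    }
  }
}

limit_result <- function(dose, side, value, method, converged, evals) {
  list(dose = dose, side = side, value = value, method = method,
       converged = converged, evals = evals)
}

#' Bisection search for one profile-likelihood confidence limit
#'
#' Standard bisection on `g(p*) = profile_loglik(p*) - threshold` inside the
#' supplied bracket, stopping when the bracket is narrower than
#' `config$bisect_tol` and returning the midpoint of the final interval.
#' Every constrained fit warm-starts from the nuisance estimates of the
#' immediately preceding constrained fit. If the far bracket endpoint does
#' not fall below the threshold (possible when a propagated neighbour limit
#' is slightly too tight), the bracket is widened outwards by doubling its
#' distance from the estimate up to 3 times; if it still does not fall
#' below threshold at the probability boundary, the limit is the boundary
#' value itself.
#'
#' @param dstar Grid dose.
#' @param side `"lower"` or `"upper"`.
#' @param bracket Interval `c(lo, hi)` from [initial_bracket()].
#' @param data,fit Data and unconstrained `fourpl_fit`.
#' @param config A [ci_config()].
#' @param state Internal warm-start environment; created automatically when
#'   omitted.
#' @return A list with `value` (the limit), `method`, `converged`, `evals`
#'   (number of constrained fits). `converged = FALSE` with `value = NA`
#'   signals bisection failure; callers fall back to [crude_search_limit()].
#' @export
bisection_limit <- function(dstar, side = c("lower", "upper"), bracket,
                            data, fit, config = ci_config(), state = NULL) {
  side <- match.arg(side)
  if (is.null(state)) state <- new_warm_state(fit, config$alpha)
  thr <- ci_threshold(fit$loglik, config$alpha)
  ph <- if (side == "upper") min(bracket) else max(bracket)
  far <- if (side == "upper") max(bracket) else min(bracket)
  evals0 <- state$evals

  fail <- function() limit_result(dstar, side, NA_real_, "bisection",
                                  FALSE, state$evals - evals0)

  g_far <- prof_eval(far, dstar, data, fit, state)
  if (is.na(g_far)) return(fail())
  tries <- 0L
  while (g_far >= thr && tries < 3L) {
    # bracket repair: double the distance from the estimate, cap to [0,1]
    far_new <- ph + 2 * (far - ph)
    far_new <- min(max(far_new, 0), 1)
    if (far_new == far) break
    far <- far_new
    g_far <- prof_eval(far, dstar, data, fit, state)
    if (is.na(g_far)) return(fail())
    tries <- tries + 1L
  }
  if (g_far >= thr) {
    if (far %in% c(0, 1)) # CI genuinely reaches the probability boundary
      return(limit_result(dstar, side, far, "bisection", TRUE,
                          state$evals - evals0))
    return(fail())
  }
  g_near <- prof_eval(ph, dstar, data, fit, state)
  if (is.na(g_near) || g_near < thr - 1e-6) return(fail())

  lo <- min(ph, far); hi <- max(ph, far)
  iter <- 0L
  while (hi - lo > config$bisect_tol && iter < 100L) {
    mid <- (lo + hi) / 2
    g <- prof_eval(mid, dstar, data, fit, state)
    if (is.na(g)) return(fail())
    inside <- g >= thr
    if (side == "upper") {
      if (inside) lo <- mid else hi <- mid
    } else {
      if (inside) hi <- mid else lo <- mid
    }
    iter <- iter + 1L
  }
  limit_result(dstar, side, (lo + hi) / 2, "bisection", TRUE,
               state$evals - evals0)
}

#' Crude outward search for one profile-likelihood confidence limit
#'
#' Steps the target response outwards from `start_value` (towards the limit)
#' in coarse increments while the profile log-likelihood stays at or above
#' the threshold; as soon as the next coarse step would cross the threshold,
#' refines from the last passing point with fine increments. Returns the
#' last value whose profile log-likelihood is at or above the threshold.
#' This is the fallback used for doses with expected response close to a
#' probability boundary, where the constrained fits behind bisection tend
#' not to converge; the step-by-step path keeps every fit's warm start
#' within one small step of its solution.
#'
#' @param dstar Grid dose.
#' @param side `"lower"` or `"upper"`.
#' @param start_value Starting response on the estimate's side of the limit
#'   (normally the fitted response at `dstar`).
#' @inheritParams bisection_limit
#' @return A list as for [bisection_limit()] with `method = "crude_search"`.
#'   A search that leaves `[0, 1]` without crossing the threshold returns
#'   the boundary value (0 or 1) rather than an error.
#' @export
crude_search_limit <- function(dstar, side = c("lower", "upper"),
                               start_value, data, fit,
                               config = ci_config(), state = NULL) {
  side <- match.arg(side)
  if (is.null(state)) state <- new_warm_state(fit, config$alpha)
  thr <- ci_threshold(fit$loglik, config$alpha)
  dir <- if (side == "upper") 1 else -1
  evals0 <- state$evals

  g0 <- prof_eval(start_value, dstar, data, fit, state)
  if (is.na(g0))
    return(limit_result(dstar, side, NA_real_, "crude_search", FALSE,
                        state$evals - evals0))
  if (g0 < thr)  # zero-width case, e.g. alpha near 1
    return(limit_result(dstar, side, start_value, "crude_search", TRUE,
                        state$evals - evals0))

  step_out <- function(p, step) {
    # advance while passing; return last passing value (NA eval = crossing)
    max_iter <- ceiling(1 / step) + 2L
    for (k in seq_len(max_iter)) {
      nxt <- min(max(p + dir * step, 0), 1)
      if (nxt == p) return(p)      # pinned at a probability boundary
      g <- prof_eval(nxt, dstar, data, fit, state)
      if (is.na(g) || g < thr) return(p)
      p <- nxt
    }
    p
  }
  p <- step_out(start_value, config$coarse_step)
  p <- step_out(p, config$fine_step)
  limit_result(dstar, side, p, "crude_search", TRUE, state$evals - evals0)
}

new_warm_state <- function(fit, alpha = 0.05) {
  state <- new.env(parent = emptyenv())
  state$nuis <- unname(fit$par)
  state$thr <- ci_threshold(fit$loglik, alpha)
  state$evals <- 0L
  state
}

make_pointwise_ci <- function(df, alpha, fit, threshold = NA_real_) {
  class(df) <- c("pointwise_ci", "data.frame")
  attr(df, "alpha") <- alpha
  attr(df, "loglik") <- fit$loglik
  attr(df, "threshold") <- threshold
  attr(df, "fit") <- fit
  df
}

#' Profile-likelihood pointwise confidence band for a 4PL curve
#'
#' Computes, for every dose on a grid, the profile-likelihood confidence
#' limits of the expected response. Upper limits are computed in descending
#' dose order and lower limits in ascending order, so each dose inherits a
#' tight initial bracket from its already-computed neighbour
#' ([initial_bracket()]) and each constrained fit warm-starts from the
#' previous one. Bisection is the primary root-finder; the crude search is
#' used directly where the fitted response falls below
#' `config$crude_trigger`, and as a fallback whenever bisection fails.
#'
#' @param data A [dose_response_data()] object.
#' @param config A [ci_config()].
#' @param fit Optional pre-computed `fourpl_fit` (refitted otherwise).
#' @return A data frame of class `"pointwise_ci"` with columns `dose`,
#'   `estimate`, `lower`, `upper`, `method_lower`, `method_upper`,
#'   `converged`, plus attributes `alpha`, `loglik`, `threshold` and `fit`.
#'   Doses where both bisection and crude search fail on a side carry `NA`
#'   limits and `converged = FALSE`; the rest of the band is still returned.
#' @examples
#' \donttest{
#' band <- profile_ci_curve(trial_nct02131662())
#' head(as.data.frame(band))
#' }
#' @export
profile_ci_curve <- function(data, config = ci_config(), fit = NULL) {
  stopifnot(inherits(data, "dose_response_data"),
            inherits(config, "ci_config"))
  if (is.null(fit)) fit <- fit_fourpl(data)
  if (!fit$converged)
    stop("unconstrained 4PL fit did not converge; no band computed",
         call. = FALSE)
  grid <- config$grid
  if (is.null(grid))
    grid <- seq(min(data$dose), max(data$dose), by = config$grid_step)
  if (min(grid) < min(data$dose) - 1e-9 || max(grid) > max(data$dose) + 1e-9)
    stop("dose grid must lie within the observed dose range", call. = FALSE)
  grid <- sort(grid)
  n <- length(grid)
  pr <- predict(fit, grid, se.fit = TRUE)
  est <- pr$fit; se <- pr$se.fit
  thr <- ci_threshold(fit$loglik, config$alpha)

  one_side <- function(side) {
    limits <- rep(NA_real_, n)
    method <- rep(NA_character_, n)
    ok <- rep(FALSE, n)
    state <- new_warm_state(fit, config$alpha)
    order_idx <- if (side == "upper") rev(seq_len(n)) else seq_len(n)
    for (i in order_idx) {
      res <- NULL
      if (est[i] >= config$crude_trigger) {
        br <- initial_bracket(i, side, est, se, limits)
        res <- bisection_limit(grid[i], side, br, data, fit, config, state)
      }
      if (is.null(res) || !res$converged)
        res <- crude_search_limit(grid[i], side, est[i], data, fit,
                                  config, state)
      limits[i] <- res$value
      method[i] <- res$method
      ok[i] <- res$converged
    }
    list(limits = limits, method = method, ok = ok)
  }

  up <- one_side("upper")
  lo <- one_side("lower")
  df <- data.frame(dose = grid, estimate = est,
                   lower = lo$limits, upper = up$limits,
                   method_lower = lo$method, method_upper = up$method,
                   converged = lo$ok & up$ok,
                   stringsAsFactors = FALSE)
  make_pointwise_ci(df, config$alpha, fit, thr)
}

#' @export
print.pointwise_ci <- function(x, ...) {
  cat(sprintf("Pointwise %g%% confidence band (%d grid doses)\n",
              100 * (1 - attr(x, "alpha")), nrow(x)))
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}
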