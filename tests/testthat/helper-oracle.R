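# Shared fixtures and the independent grid-scan oracle for profile limits.

trial_data <- function() trial_nct02131662()

trial_truth <- function() fourpl_params(0.0015, 0.569, 0.49, 0.14)

# Cached unconstrained fit of the trial data (computed once per test run)
trial_fit <- local({
  fit <- NULL
  function() {
    if (is.null(fit)) fit <<- fit_fourpl(trial_data())
    fit
  }
})

# Exhaustive stepwise scan of the profile log-likelihood: starting at the
# fitted response, move outward in steps of `step` (warm-chaining each
# constrained fit from its neighbour, the most reliable evaluation of the
# profile) and return the last value whose profile log-likelihood is at or
# above the chi-squared threshold. Independent of the bisection/crude-search
# root-finding logic under test. A coarse pre-scan (50x step) brackets the
# crossing first so the fine scan stays affordable.
scan_limit <- function(data, fit, dstar, side, alpha = 0.05, step = 1e-4) {
  thr <- ci_threshold(fit$loglik, alpha)
  dir <- if (side == "upper") 1 else -1
  prof <- function(p, st) profile_loglik(data, dstar, p, start = st)
  walk <- function(p, nuis, by) {
    repeat {
      nxt <- p + dir * by
      if (nxt < 0 || nxt > 1) return(list(p = p, nuis = nuis, capped = TRUE))
      r <- prof(nxt, nuis)
      if (!is.finite(r$loglik)) return(list(p = p, nuis = nuis, capped = FALSE))
      if (r$loglik < thr) return(list(p = p, nuis = nuis, capped = FALSE))
      p <- nxt
      nuis <- unname(r$params)
    }
  }
  coarse <- walk(predict(fit, dstar), unname(fit$par), 50 * step)
  fine <- walk(coarse$p, coarse$nuis, step)
  fine$p
}
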