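#' Delta-method Wald pointwise confidence band
#'
#' The textbook comparator: `phat(d) +/- z_{1-alpha/2} * se(phat(d))` at
#' each grid dose, with the standard error from the delta method (gradient
#' of the 4PL curve in the coefficients, sandwiched with the inverse
#' observed information). The limits are deliberately NOT truncated to
#' `[0, 1]`: the construction's well-known pathology for binomial
#' dose-response curves — negative lower limits near placebo, possibly
#' non-monotone bands — is exactly what the profile-likelihood band avoids,
#' and truncating would hide it.
#'
#' @param data A [dose_response_data()] object.
#' @param fit Optional pre-computed `fourpl_fit`.
#' @param grid Dose grid; defaults to the observed-range grid with step 0.1.
#' @param alpha Two-sided error rate.
#' @return A `pointwise_ci` data frame (see [profile_ci_curve()]) with
#'   `method_lower = method_upper = "wald"`.
#' @examples
#' wald_ci_curve(trial_nct02131662(), grid = c(0, 0.5, 1, 2, 4))
#' @export
wald_ci_curve <- function(data, fit = NULL, grid = NULL, alpha = 0.05) {
  stopifnot(inherits(data, "dose_response_data"))
  if (is.null(fit)) fit <- fit_fourpl(data)
  if (is.null(grid)) grid <- seq(min(data$dose), max(data$dose), by = 0.1)
  grid <- sort(grid)
  pr <- predict(fit, grid, se.fit = TRUE)
  if (anyNA(pr$se.fit))
    stop("observed information is singular; delta-method standard errors ",
         "unavailable - use profile_ci_curve() instead", call. = FALSE)
  z <- stats::qnorm(1 - alpha / 2)
  df <- data.frame(dose = grid, estimate = pr$fit,
                   lower = pr$fit - z * pr$se.fit,
                   upper = pr$fit + z * pr$se.fit,
                   method_lower = "wald", method_upper = "wald",
                   converged = TRUE, stringsAsFactors = FALSE)
  make_pointwise_ci(df, alpha, fit)
}

#' Nonparametric percentile bootstrap pointwise confidence band
#'
#' Resamples subjects with replacement within each dose group — for binary
#' outcomes grouped by dose this is exactly a stratified binomial draw
#' `responders_b[i] ~ Binomial(N_i, y_i/N_i)` — refits the 4PL to each
#' resample, and takes empirical percentiles of the refitted response at
#' each grid dose. Percentiles use plain order statistics at `ceiling(B*q)`
#' (for `B = 1000`, `alpha = 0.05`: the 25th and 975th order statistics).
#' Resamples whose refit fails are dropped and counted; a warning is issued
#' when more than 20% fail.
#'
#' @param data A [dose_response_data()] object.
#' @param grid Dose grid; defaults to the observed-range grid with step 0.1.
#' @param B Number of bootstrap resamples.
#' @param alpha Two-sided error rate.
#' @param seed Optional integer seed; a fixed seed makes the band
#'   bit-reproducible.
#' @param fit Optional pre-computed `fourpl_fit` for the point estimates.
#' @return A `pointwise_ci` data frame with attribute `n_failed` (dropped
#'   resamples).
#' @examples
#' \donttest{
#' bootstrap_ci_curve(trial_nct02131662(), grid = c(0, 1, 4),
#'                    B = 50, seed = 1)
#' }
#' @export
bootstrap_ci_curve <- function(data, grid = NULL, B = 1000, alpha = 0.05,
                               seed = NULL, fit = NULL) {
  stopifnot(inherits(data, "dose_response_data"), B >= 2)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(fit)) fit <- fit_fourpl(data)
  if (is.null(grid)) grid <- seq(min(data$dose), max(data$dose), by = 0.1)
  grid <- sort(grid)
  phat_grp <- data$responders / data$total
  k <- nrow(data)

  curves <- matrix(NA_real_, nrow = B, ncol = length(grid))
  n_failed <- 0L
  for (b in seq_len(B)) {
    yb <- stats::rbinom(k, data$total, phat_grp)
    datb <- dose_response_data(data$dose, yb, data$total)
    fb <- tryCatch(fit_fourpl(datb, vcov = FALSE), error = function(e) NULL)
    if (is.null(fb) || !fb$converged) { n_failed <- n_failed + 1L; next }
    curves[b, ] <- predict(fb, grid)
  }
  ok <- stats::complete.cases(curves)
  Beff <- sum(ok)
  if (Beff == 0L)
    stop("all bootstrap refits failed; no interval available", call. = FALSE)
  if (n_failed > 0.2 * B)
    warning(sprintf("%d of %d bootstrap refits failed (> 20%%)",
                    n_failed, B), call. = FALSE)
  curves <- curves[ok, , drop = FALSE]
  qlo <- max(1L, ceiling(Beff * alpha / 2))
  qhi <- ceiling(Beff * (1 - alpha / 2))
  lims <- apply(curves, 2L, function(v) sort(v)[c(qlo, qhi)])

  df <- data.frame(dose = grid, estimate = predict(fit, grid),
                   lower = lims[1L, ], upper = lims[2L, ],
                   method_lower = "bootstrap", method_upper = "bootstrap",
                   converged = TRUE, stringsAsFactors = FALSE)
  out <- make_pointwise_ci(df, alpha, fit)
  attr(out, "n_failed") <- n_failed
  attr(out, "B") <- B
  out
}
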