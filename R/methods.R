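# S3 methods for fitted "halott" objects.

#' @export
print.halott <- function(x, digits = 4, ...) {
  cat("Halothermal-time model fit (repeated probit regression)\n\n")
  print(x$params, digits = digits)
  cat(sprintf("\nProbit regression: R2 = %s on %d points (SE %s)\n",
              format(x$diagnostics$r2, digits = digits), x$diagnostics$n_obs,
              format(x$diagnostics$se, digits = digits)))
  invisible(x)
}

#' @export
coef.halott <- function(object, ...) {
  p <- object$params
  c(psi_b50 = p$psi_b50, sigma_psib = p$sigma_psib,
    theta_halott = p$theta_halott, t_base = p$t_base, t_opt = p$t_opt,
    t_ceil = p$t_ceil, k_t = p$k_t)
}

#' Summarize a halothermal-time model fit
#'
#' @param object a fitted [halott] object.
#' @param ... unused.
#' @return A `summary.halott` list: coefficients, probit-regression
#'   diagnostics, per-temperature supra-optimal fits and the
#'   cardinal-temperature profile estimate.
#' @export
summary.halott <- function(object, ...) {
  per_temp <- NULL
  if (length(object$per_temperature)) {
    per_temp <- do.call(rbind, lapply(names(object$per_temperature), function(nm) {
      f <- object$per_temperature[[nm]]
      data.frame(temperature_C = as.numeric(nm), psi_b50 = f$psi_b50,
                 sigma_psib = f$sigma_psib, theta_halo = f$theta_halo,
                 r2 = f$diagnostics$r2)
    }))
  }
  structure(list(coefficients = coef(object), diagnostics = object$diagnostics,
                 per_temperature = per_temp, cardinal = object$cardinal,
                 n_courses = length(unique(.course_key(object$data))),
                 call = object$call),
            class = "summary.halott")
}

#' @export
print.summary.halott <- function(x, digits = 4, ...) {
  cat("Call: "); print(x$call)
  cat("\nCoefficients:\n")
  print(round(x$coefficients, digits))
  d <- x$diagnostics
  cat(sprintf("\nProbit regression (sub-optimal pool): R2 %s, SE %s, F %s (p %s), n %d\n",
              format(d$r2, digits = digits), format(d$se, digits = digits),
              format(d$f_stat, digits = digits), format(d$sig, digits = 2),
              d$n_obs))
  if (!is.null(x$per_temperature)) {
    cat("\nSupra-optimal per-temperature halotime fits:\n")
    print(x$per_temperature, digits = digits, row.names = FALSE)
  }
  if (!is.null(x$cardinal) && !is.na(x$cardinal$t_opt))
    cat(sprintf("\nRate-profile cardinal temperatures: Tb %s, To %s, Tc %s C\n",
                format(x$cardinal$t_base, digits = digits),
                format(x$cardinal$t_opt, digits = digits),
                format(x$cardinal$t_ceil, digits = digits)))
  invisible(x)
}

#' Predict germination fractions from a fitted model
#'
#' @param object a fitted [halott] object.
#' @param newdata data.frame with columns `temperature_C`, `psi_MPa`,
#'   `time_h`; defaults to the observation grid of the fitted data.
#' @param ... unused.
#' @return Numeric vector of predicted cumulative germination fractions.
#' @export
predict.halott <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- as.data.frame(object$data)
  predict_fraction(object$params, newdata$temperature_C, newdata$psi_MPa,
                   newdata$time_h)
}

#' @export
residuals.halott <- function(object, ...) {
  object$points$probit - object$points$fitted_probit
}

#' Simulate germination datasets from a fitted model
#'
#' Draws new datasets from the generative threshold model at the fitted
#' parameters, over the same treatment grid, replication and observation
#' times as the fitted data.
#'
#' @param object a fitted [halott] object.
#' @param nsim number of datasets.
#' @param seed integer seed (as in [stats::simulate]).
#' @param ... unused.
#' @return A list of `nsim` [germination_data] objects.
#' @export
simulate.halott <- function(object, nsim = 1, seed = NULL, ...) {
  d <- as.data.frame(object$data)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  temps <- sort(unique(d$temperature_C))
  psis <- sort(unique(d$psi_MPa), decreasing = TRUE)
  n_reps <- length(unique(d$replicate))
  times <- sort(unique(d$time_h))
  obs <- min(diff(c(0, times)))
  out <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    des <- sim_design(params = object$params, temperatures = temps,
                      psis = psis, n_seeds = max(d$n_sown),
                      n_reps = n_reps, obs_interval = obs,
                      horizon = max(times), seed = seed + i - 1L)
    out[[i]] <- simulate_germination(des)
  }
  if (nsim == 1) out[[1]] else out
}

#' Diagnostic plots for a halothermal-time fit
#'
#' Panel 1: observed vs fitted probit-transformed germination fractions of
#' the sub-optimal regression pool. Panel 2: the psi = 0 germination-rate
#' profile with the fitted two-segment cardinal-temperature lines.
#'
#' @param x a fitted [halott] object.
#' @param which which panels to draw (subset of `1:2`).
#' @param ... passed to [graphics::plot].
#' @export
plot.halott <- function(x, which = 1:2, ...) {
  if (1 %in% which) {
    graphics::plot(x$points$fitted_probit, x$points$probit,
                   xlab = "fitted probit(g)", ylab = "observed probit(g)",
                   main = "Repeated probit regression", ...)
    graphics::abline(0, 1, lty = 2)
  }
  if (2 %in% which && !is.null(x$cardinal)) {
    prof <- gr_profile(x$params, seq(x$params$t_base, 50, by = 0.5),
                       g = x$settings$g)
    graphics::plot(prof$temperature_C, prof$gr, type = "l",
                   xlab = "temperature (C)", ylab = sprintf("GR(%g) (1/h)", x$settings$g),
                   main = "Germination-rate profile at psi = 0", ...)
    cd <- x$cardinal
    if (!is.null(cd$sub)) graphics::abline(cd$sub$intercept, cd$sub$slope, col = 2, lty = 3)
    if (!is.null(cd$supra)) graphics::abline(cd$supra$intercept, cd$supra$slope, col = 4, lty = 3)
  }
  invisible(x)
}
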