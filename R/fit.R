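# Repeated probit regression: parameter estimation for the halotime and
# halothermal-time threshold models, cardinal-temperature estimation, and
# probit-scale fit diagnostics.
#
# Estimation strategy (deterministic, derivative-free): a grid search over
# the time constant (and, for the global fit, the base temperature)
# maximizing the R-squared of the probit regression, refined by
# golden-section search on the best cell; ties break toward the smaller
# time constant.

.default_theta_grid <- function(n = 201, lower = 1, upper = 5000) {
  exp(seq(log(lower), log(upper), length.out = n))
}

# Regression points for the probit fits. Replicates are pooled by summing
# counts at shared observation times within each treatment; cumulative
# fractions of exactly 0 or 1 are dropped (infinite probits) unless the
# (g + 0.5)/(n + 1) continuity correction is requested.
.probit_points <- function(data, fraction_of = c("sown", "germinated"),
                           continuity = FALSE) {
  fraction_of <- match.arg(fraction_of)
  data <- as.data.frame(data)
  treat <- paste(data$temperature_C, data$psi_MPa)
  pts <- lapply(split(data, treat), function(d) {
    reps <- split(d, d$replicate)
    grids <- lapply(reps, function(r) sort(r$time_h))
    if (length(unique(vapply(grids, paste, "", collapse = ","))) != 1L)
      stop("replicate observation grids differ within treatment ",
           d$temperature_C[1], " C / ", d$psi_MPa[1], " MPa; cannot pool")
    cum <- Reduce(`+`, lapply(reps, function(r) r$cum_germinated[order(r$time_h)]))
    n <- sum(vapply(reps, function(r) r$n_sown[1], 0))
    if (fraction_of == "germinated") n <- cum[length(cum)]
    if (n == 0) return(NULL)
    g <- if (continuity) (cum + 0.5) / (n + 1) else cum / n
    data.frame(temperature_C = d$temperature_C[1], psi_MPa = d$psi_MPa[1],
               time_h = grids[[1]], g = g, n = n)
  })
  pts <- do.call(rbind, pts)
  if (is.null(pts)) return(pts)
  pts <- pts[pts$g > 0 & pts$g < 1, , drop = FALSE]
  pts$probit <- stats::qnorm(pts$g)
  # classical probit working weights n phi(probit)^2 / (g (1 - g)):
  # binomial sampling variance of the probit-scale response
  pts$weight <- pts$n * stats::dnorm(pts$probit)^2 / (pts$g * (1 - pts$g))
  rownames(pts) <- NULL
  pts
}

# (optionally weighted) simple-regression summaries of probit ~ b
.probit_reg <- function(b, y, w = NULL) {
  n <- length(y)
  if (is.null(w)) w <- rep(1, n)
  sw <- sum(w)
  mb <- sum(w * b) / sw
  my <- sum(w * y) / sw
  vb <- sum(w * (b - mb)^2)
  if (!is.finite(vb) || vb == 0) return(NULL)
  slope <- sum(w * (b - mb) * (y - my)) / vb
  intercept <- my - slope * mb
  res <- y - intercept - slope * b
  ss_res <- sum(w * res^2)
  ss_tot <- sum(w * (y - my)^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  se <- if (n > 2) sqrt(ss_res / (n - 2)) else NA_real_
  f <- if (n > 2 && ss_res > 0) (ss_tot - ss_res) / (ss_res / (n - 2)) else Inf
  p <- if (is.finite(f)) stats::pf(f, 1, n - 2, lower.tail = FALSE) else 0
  list(slope = slope, intercept = intercept, r2 = r2, se = se,
       f_stat = f, p_value = p, n_obs = n, residuals = res)
}

.reg_to_params <- function(reg) {
  # probit(g) = (b - psi_b50)/sigma  =>  slope = 1/sigma, intercept = -psi_b50/sigma
  if (reg$slope <= 0)
    warning("non-positive probit slope; base-potential spread is not identified")
  list(psi_b50 = -reg$intercept / reg$slope, sigma_psib = 1 / reg$slope)
}

.diagnostics <- function(reg) {
  list(r2 = reg$r2, se = reg$se, f_stat = reg$f_stat, sig = reg$p_value,
       n_obs = reg$n_obs)
}

#' Probit-scale goodness of fit
#'
#' Regresses observed on predicted germination fractions on the probit
#' scale and reports R-squared, the residual standard error, the
#' regression F statistic and its p-value. Fractions are clipped to
#' (1e-6, 1 - 1e-6) before the probit transform. A constant predictor
#' yields R-squared 0.
#'
#' @param observed,predicted germination fractions of equal length >= 3.
#' @return list with `r2`, `se`, `f_stat`, `sig`, `n_obs`.
#' @export
goodness_of_fit <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (length(observed) < 3) stop("need at least 3 points")
  eps <- 1e-6
  yo <- stats::qnorm(pmin(pmax(observed, eps), 1 - eps))
  yp <- stats::qnorm(pmin(pmax(predicted, eps), 1 - eps))
  reg <- .probit_reg(yp, yo)
  if (is.null(reg))
    return(list(r2 = 0, se = stats::sd(yo), f_stat = NA_real_, sig = NA_real_,
                n_obs = length(yo)))
  .diagnostics(reg)
}

#' Single-temperature halotime fit
#'
#' Repeated probit regression at one temperature: for each candidate
#' halotime constant theta the implied base potential of every observation
#' is b = psi - theta/t, and probit(g) is regressed on b; the theta
#' maximizing R-squared (grid search plus golden-section refinement) is
#' selected. The regression intercept and slope give the median and spread
#' of the base-potential distribution at that temperature.
#'
#' @param data a [germination_data] object.
#' @param temperature the temperature (deg C) whose courses are fitted.
#' @param theta_grid candidate halotime constants, MPa h (default 201
#'   log-spaced points on `[1, 5000]`).
#' @param fraction_of express cumulative fractions relative to seeds
#'   `"sown"` (default) or to the final `"germinated"` count.
#' @param continuity apply the (g + 0.5)/(n + 1) continuity correction
#'   instead of dropping fractions of exactly 0 or 1.
#' @param weights `"binomial"` (default) weights each point by the
#'   classical probit working weight n phi(probit(g))^2 / (g (1 - g));
#'   `"none"` fits by ordinary least squares.
#' @return list with `psi_b50` (MPa), `sigma_psib` (MPa), `theta_halo`
#'   (MPa h) and `diagnostics` (as in [goodness_of_fit()]).
#' @export
fit_halo_temperature <- function(data, temperature, theta_grid = NULL,
                                 fraction_of = "sown", continuity = FALSE,
                                 weights = c("binomial", "none")) {
  weights <- match.arg(weights)
  data <- as_germination_data(data)
  pts <- .probit_points(data[data$temperature_C == temperature, , drop = FALSE],
                        fraction_of = fraction_of, continuity = continuity)
  if (is.null(pts) || nrow(pts) < 3)
    stop("too few informative observations at ", temperature,
         " C (all-zero or all-complete germination?)")
  if (length(unique(pts$psi_MPa)) < 2)
    stop("need germination at >= 2 osmotic potentials at ", temperature, " C")
  if (is.null(theta_grid)) theta_grid <- .default_theta_grid()
  theta_grid <- sort(theta_grid)

  w <- if (weights == "binomial") pts$weight else NULL
  r2_of <- function(th) {
    reg <- .probit_reg(pts$psi_MPa - th / pts$time_h, pts$probit, w)
    if (is.null(reg)) -Inf else reg$r2
  }
  r2 <- vapply(theta_grid, r2_of, 0)
  k <- which.max(r2)  # which.max takes the first (smallest theta) on ties
  if (k == 1L || k == length(theta_grid))
    warning("theta at the boundary of the search grid; estimate reported at the boundary")
  lo <- theta_grid[max(k - 1L, 1L)]
  hi <- theta_grid[min(k + 1L, length(theta_grid))]
  theta <- if (lo < hi)
    stats::optimize(function(th) -r2_of(th), c(lo, hi))$minimum else theta_grid[k]
  if (r2_of(theta) < r2[k]) theta <- theta_grid[k]

  reg <- .probit_reg(pts$psi_MPa - theta / pts$time_h, pts$probit, w)
  est <- .reg_to_params(reg)
  list(psi_b50 = est$psi_b50, sigma_psib = est$sigma_psib, theta_halo = theta,
       diagnostics = .diagnostics(reg), points = pts)
}

#' Cardinal temperatures from a germination-rate profile
#'
#' Fits the classical two-segment linear model of germination rate against
#' temperature: GR rises linearly from the base temperature Tb to the
#' optimum To and falls linearly to the ceiling Tc. Zero-rate points are
#' treated as censored (no germination) and excluded from the lines. The
#' split between the rising and falling segments is chosen to maximize the
#' pooled R-squared (equivalently, minimize the pooled residual sum of
#' squares), with the split point shared by both segments. Tb and Tc are
#' the segments' x-intercepts; To is the abscissa of their intersection.
#'
#' With fewer than two positive-rate points on one side (a monotone
#' profile) the available side is fitted alone and the missing cardinal
#' temperatures are returned as `NA` with a warning.
#'
#' @param temperature temperatures, deg C.
#' @param gr germination rates (1/h) at those temperatures, typically at
#'   psi = 0; `NA` and zero rates are treated as censored.
#' @return list with `t_base`, `t_opt`, `t_ceil`, `gr_opt` (fitted rate at
#'   To), `r2` (pooled), and the two segment fits.
#' @export
cardinal_temperatures <- function(temperature, gr) {
  keep <- !is.na(gr) & gr > 0
  Tt <- temperature[keep]
  g <- gr[keep]
  o <- order(Tt)
  Tt <- Tt[o]
  g <- g[o]
  n <- length(Tt)
  if (n < 2) stop("need at least 2 positive germination rates")

  line_fit <- function(x, y) {
    f <- .probit_reg(x, y)  # same simple-regression mechanics
    list(intercept = f$intercept, slope = f$slope, sse = sum(f$residuals^2))
  }
  one_sided <- function() {
    f <- line_fit(Tt, g)
    warning("monotone germination-rate profile: one-sided cardinal estimate")
    if (f$slope > 0)
      list(t_base = -f$intercept / f$slope, t_opt = NA_real_, t_ceil = NA_real_,
           gr_opt = NA_real_, r2 = NA_real_, sub = f, supra = NULL)
    else
      list(t_base = NA_real_, t_opt = NA_real_,
           t_ceil = -f$intercept / f$slope,
           gr_opt = NA_real_, r2 = NA_real_, sub = NULL, supra = f)
  }
  if (n < 4) return(one_sided())

  best <- NULL
  for (s in 2:(n - 1)) {
    fl <- line_fit(Tt[1:s], g[1:s])
    fr <- line_fit(Tt[s:n], g[s:n])
    if (fl$slope <= 0 || fr$slope >= 0) next
    sse <- fl$sse + fr$sse
    if (is.null(best) || sse < best$sse) best <- list(sse = sse, fl = fl, fr = fr)
  }
  if (is.null(best)) return(one_sided())

  ss_tot <- sum((g - mean(g))^2)
  t_opt <- (best$fr$intercept - best$fl$intercept) / (best$fl$slope - best$fr$slope)
  list(t_base = -best$fl$intercept / best$fl$slope,
       t_opt = t_opt,
       t_ceil = -best$fr$intercept / best$fr$slope,
       gr_opt = best$fl$intercept + best$fl$slope * t_opt,
       r2 = if (ss_tot == 0) 1 else 1 - best$sse / ss_tot,
       sub = best$fl, supra = best$fr)
}

#' Fit the halothermal-time model
#'
#' The package's central estimator. A joint deterministic grid search over
#' the base temperature Tb and the halothermal time constant theta: for
#' each candidate pair, the implied base potential of every sub-optimal
#' observation is `b = psi - theta/((T - Tb) t)` and probit(g) is regressed
#' on `b`; the pair maximizing R-squared is refined by alternating
#' golden-section searches. The regression line then yields `psi_b50`
#' (median base water potential) and `sigma_psib` (its spread). Above the
#' optimum temperature, the shift coefficient `k_t` is the least-squares
#' slope of the per-temperature medians from [fit_halo_temperature()]
#' against temperature. Cardinal temperatures are estimated from the
#' interpolated GR(g) profile at psi = 0 via [cardinal_temperatures()].
#'
#' @param data a [germination_data] object (or coercible data.frame).
#' @param g reference percentile (fraction of sown) for the GR profile
#'   used in cardinal-temperature estimation.
#' @param t_opt optimum temperature used to classify sub- vs supra-optimal
#'   observations. `NULL` (default) estimates it from the data's rate
#'   profile; supplying it (e.g. from an independent profile fit) fixes
#'   the classification.
#' @param t_base_grid candidate base temperatures, deg C; default 0.5 deg C
#'   steps from 0 to one degree below the coolest temperature with
#'   germination.
#' @param theta_grid candidate halothermal time constants, MPa deg C h;
#'   default 201 log-spaced points on `[1, 5000]`.
#' @inheritParams fit_halo_temperature
#' @return An object of class `halott`: a list with `params`
#'   ([halott_params]), `diagnostics`, `per_temperature` (supra-optimal
#'   halotime fits used for `k_t`), `cardinal` (rate-profile estimate),
#'   `points` (sub-optimal regression points with fitted values), `data`
#'   and `call`.
#' @examples
#' des <- sim_design(n_seeds = 200, n_reps = 1, seed = 7)
#' fit <- halott(simulate_germination(des), t_opt = 33)
#' coef(fit)
#' @export
halott <- function(data, g = 0.5, t_opt = NULL, t_base_grid = NULL,
                   theta_grid = NULL, fraction_of = "sown",
                   continuity = FALSE, weights = c("binomial", "none")) {
  weights <- match.arg(weights)
  cl <- match.call()
  data <- as_germination_data(data)
  pts_all <- .probit_points(data, fraction_of = fraction_of,
                            continuity = continuity)
  if (is.null(pts_all) || nrow(pts_all) == 0)
    stop("no informative observations: all courses fully at 0 or complete germination")

  # cardinal temperatures from the psi = 0 rate profile (when available)
  cardinal <- NULL
  d0 <- data[data$psi_MPa == 0, , drop = FALSE]
  if (nrow(d0)) {
    grp <- vapply(split(as.data.frame(d0), d0$temperature_C), function(d) {
      reps <- split(d, d$replicate)
      cum <- Reduce(`+`, lapply(reps, function(r) r$cum_germinated[order(r$time_h)]))
      n <- sum(vapply(reps, function(r) r$n_sown[1], 0))
      gr_from_timecourse(sort(reps[[1]]$time_h), cum, n, g)$gr
    }, 0)
    temps0 <- as.numeric(names(grp))
    if (sum(!is.na(grp) & grp > 0) >= 2)
      cardinal <- tryCatch(
        suppressWarnings(cardinal_temperatures(temps0, grp)),
        error = function(e) NULL)
  }
  if (is.null(t_opt)) {
    if (is.null(cardinal) || is.na(cardinal$t_opt))
      stop("optimum temperature could not be estimated from the data; supply t_opt")
    t_opt <- cardinal$t_opt
  }

  sub <- pts_all[pts_all$temperature_C < t_opt, , drop = FALSE]
  if (length(unique(sub$temperature_C)) < 2)
    stop("need informative observations at >= 2 sub-optimal temperatures")
  if (is.null(theta_grid)) theta_grid <- .default_theta_grid()
  theta_grid <- sort(theta_grid)
  tb_max <- min(sub$temperature_C) - 1
  if (is.null(t_base_grid)) t_base_grid <- seq(0, tb_max, by = 0.5)

  w <- if (weights == "binomial") sub$weight else NULL
  r2_of <- function(tb, th) {
    reg <- .probit_reg(sub$psi_MPa - th / ((sub$temperature_C - tb) * sub$time_h),
                       sub$probit, w)
    if (is.null(reg)) -Inf else reg$r2
  }
  best <- list(r2 = -Inf, tb = NA_real_, th = NA_real_)
  for (tb in t_base_grid) {
    tt <- (sub$temperature_C - tb) * sub$time_h
    for (th in theta_grid) {
      reg <- .probit_reg(sub$psi_MPa - th / tt, sub$probit, w)
      if (!is.null(reg) && reg$r2 > best$r2)
        best <- list(r2 = reg$r2, tb = tb, th = th)
    }
  }
  if (best$th == theta_grid[1] || best$th == theta_grid[length(theta_grid)])
    warning("theta at the boundary of the search grid")
  tb <- best$tb
  th <- best$th
  for (i in 1:3) {  # alternating golden-section refinement on the best cell
    th <- stats::optimize(function(x) -r2_of(tb, x),
                          th * c(1 / 1.1, 1.1))$minimum
    tb <- stats::optimize(function(x) -r2_of(x, th),
                          c(max(0, tb - 0.75), min(tb_max, tb + 0.75)))$minimum
  }
  if (r2_of(tb, th) < best$r2) { tb <- best$tb; th <- best$th }

  reg <- .probit_reg(sub$psi_MPa - th / ((sub$temperature_C - tb) * sub$time_h),
                     sub$probit, w)
  est <- .reg_to_params(reg)
  sub$fitted_probit <- reg$intercept +
    reg$slope * (sub$psi_MPa - th / ((sub$temperature_C - tb) * sub$time_h))

  # supra-optimal shift coefficient from per-temperature medians
  supra_temps <- sort(unique(pts_all$temperature_C[pts_all$temperature_C > t_opt]))
  per_temp <- list()
  k_t <- NA_real_
  # per-temperature halotime constants live near theta/(T - Tb); widen the
  # grid floor so rescaled time units stay in range
  pt_grid <- .default_theta_grid(lower = min(theta_grid) / 100,
                                 upper = max(theta_grid))
  for (Ts in supra_temps) {
    ft <- tryCatch(fit_halo_temperature(data, Ts, theta_grid = pt_grid,
                                        fraction_of = fraction_of,
                                        continuity = continuity,
                                        weights = weights),
                   error = function(e) NULL)
    if (!is.null(ft)) per_temp[[as.character(Ts)]] <- ft
  }
  if (length(per_temp) >= 2) {
    Ts <- as.numeric(names(per_temp))
    pb <- vapply(per_temp, function(f) f$psi_b50, 0)
    k_t <- stats::cov(Ts, pb) / stats::var(Ts)
    if (k_t < 0) {
      warning("negative supra-optimal shift estimate; k_t set to NA")
      k_t <- NA_real_
    }
  } else if (length(supra_temps)) {
    warning("fewer than 2 supra-optimal temperatures with usable fits; k_t undefined")
  }

  t_ceil <- if (!is.null(cardinal) && !is.na(cardinal$t_ceil)) cardinal$t_ceil else NA_real_
  params <- halott_params(psi_b50 = est$psi_b50, sigma_psib = est$sigma_psib,
                          theta_halott = th, t_base = tb, t_opt = t_opt,
                          t_ceil = t_ceil, k_t = k_t)
  structure(list(params = params, diagnostics = .diagnostics(reg),
                 per_temperature = per_temp, cardinal = cardinal,
                 points = sub, data = data, call = cl,
                 settings = list(g = g, fraction_of = fraction_of,
                                 continuity = continuity, weights = weights)),
            class = "halott")
}
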