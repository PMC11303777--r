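# Threshold-model accumulation quantities: thermal, halo and halothermal
# time, and the probit percentile model built on them.

#' Sub-optimal thermal time
#'
#' TTsub = (T - Tb) tg: degree-hours accumulated above the base
#' temperature by the time tg.
#'
#' @param temperature incubation temperature, deg C (must be >= `t_base`).
#' @param t_base base temperature Tb, deg C.
#' @param tg time to the reference germination percentile, h.
#' @return deg C h.
#' @export
thermal_time_sub <- function(temperature, t_base, tg) {
  if (any(temperature < t_base)) stop("temperature below t_base")
  if (any(tg <= 0)) stop("tg must be > 0")
  (temperature - t_base) * tg
}

#' Supra-optimal thermal time
#'
#' TTsupra = (Tc - T) tg: degree-hours of "headroom" below the ceiling
#' temperature accumulated by tg.
#'
#' @param t_ceil ceiling temperature Tc, deg C.
#' @inheritParams thermal_time_sub
#' @return deg C h.
#' @export
thermal_time_supra <- function(t_ceil, temperature, tg) {
  if (any(temperature > t_ceil)) stop("temperature above t_ceil")
  if (any(tg <= 0)) stop("tg must be > 0")
  (t_ceil - temperature) * tg
}

#' Halotime
#'
#' theta_halo = (NaClb - NaCl) tg, with the base and applied solute levels
#' expressed on a common (MPa) scale, so the first argument is their
#' difference.
#'
#' @param base_minus_applied base-minus-applied osmotic potential, MPa.
#' @inheritParams thermal_time_sub
#' @return MPa h.
#' @export
halotime <- function(base_minus_applied, tg) {
  if (any(tg <= 0)) stop("tg must be > 0")
  base_minus_applied * tg
}

#' Halothermal time
#'
#' theta_haloTT = (NaClb - NaCl)(T - Tb) tg, i.e. [halotime()] times the
#' supra-base thermal excess.
#'
#' @inheritParams halotime
#' @inheritParams thermal_time_sub
#' @return MPa deg C h.
#' @export
halothermal_time <- function(base_minus_applied, temperature, t_base, tg) {
  if (any(temperature <= t_base)) stop("temperature must exceed t_base")
  if (any(tg <= 0)) stop("tg must be > 0")
  base_minus_applied * (temperature - t_base) * tg
}

#' Halothermal-time model parameter set
#'
#' Bundles the population parameters of the halothermal-time threshold
#' model: the normally distributed base water potential (median `psi_b50`,
#' spread `sigma_psib`), the halothermal time constant `theta_halott`, the
#' cardinal temperatures and the supra-optimal shift coefficient `k_t`
#' (MPa per deg C by which the median base potential rises above `t_opt`).
#'
#' The defaults are a published parameterization for maize germination
#' under NaCl stress and double as the generating truth of
#' [sim_design()].
#'
#' @param psi_b50 median base water potential, MPa (< 0).
#' @param sigma_psib standard deviation of the base water potential, MPa.
#' @param theta_halott halothermal time constant, MPa deg C h.
#' @param t_base,t_opt,t_ceil cardinal temperatures Tb < To < Tc, deg C
#'   (`t_ceil` may be `NA` when no supra-optimal decline was observed).
#' @param k_t supra-optimal shift of `psi_b50`, MPa/deg C (>= 0; may be
#'   `NA` when inestimable).
#' @param theta_halo optional halotime constant, MPa h (informational).
#' @return An object of class `halott_params`.
#' @export
halott_params <- function(psi_b50 = -0.87, sigma_psib = 0.30,
                          theta_halott = 56.29, t_base = 20, t_opt = 33,
                          t_ceil = 45, k_t = 0.104, theta_halo = NULL) {
  stopifnot(psi_b50 < 0, sigma_psib >= 0, theta_halott > 0)
  if (!is.na(t_opt) && t_base >= t_opt) stop("t_base must be < t_opt")
  if (!is.na(t_ceil) && !is.na(t_opt) && t_opt >= t_ceil) stop("t_opt must be < t_ceil")
  if (!is.na(k_t) && k_t < 0) stop("k_t must be >= 0")
  structure(list(psi_b50 = psi_b50, sigma_psib = sigma_psib,
                 theta_halott = theta_halott, t_base = t_base, t_opt = t_opt,
                 t_ceil = t_ceil, k_t = k_t, theta_halo = theta_halo),
            class = "halott_params")
}

#' @export
print.halott_params <- function(x, digits = 4, ...) {
  cat("Halothermal-time model parameters:\n")
  cat(sprintf("  psi_b(50): %s MPa    sigma_psib: %s MPa\n",
              format(x$psi_b50, digits = digits),
              format(x$sigma_psib, digits = digits)))
  cat(sprintf("  theta_HaloTT: %s MPa C h    k_T: %s MPa/C\n",
              format(x$theta_halott, digits = digits),
              format(x$k_t, digits = digits)))
  cat(sprintf("  cardinal temperatures (Tb / To / Tc): %s / %s / %s C\n",
              format(x$t_base, digits = digits), format(x$t_opt, digits = digits),
              format(x$t_ceil, digits = digits)))
  invisible(x)
}

# median base potential after the supra-optimal kT shift
.psi_b50_adj <- function(params, temperature) {
  shift <- if (is.na(params$k_t) || is.na(params$t_opt)) 0 else
    params$k_t * pmax(0, temperature - params$t_opt)
  params$psi_b50 + shift
}

#' Predicted cumulative germination fraction
#'
#' The probit percentile model: the fraction of the seed population
#' germinated by time `t` at temperature `T` and osmotic potential `psi` is
#' \deqn{g(t) = \Phi\!\left(\frac{\psi - \theta/((T - T_b)\,t) -
#'   \psi_{b}(50;T)}{\sigma_{\psi b}}\right)}
#' where \eqn{\psi_b(50;T) = \psi_b(50) + k_T \max(0, T - T_o)}. Below the
#' base temperature no thermal time accumulates and the fraction is 0.
#'
#' @param params a [halott_params] object.
#' @param temperature temperature, deg C (vectorized).
#' @param psi osmotic potential, MPa (vectorized).
#' @param time_h time since imbibition, h (> 0, vectorized).
#' @return germination fraction in `[0, 1]`, non-decreasing in `time_h`.
#' @export
predict_fraction <- function(params, temperature, psi, time_h) {
  stopifnot(inherits(params, "halott_params"))
  if (any(time_h <= 0)) stop("time_h must be > 0")
  n <- max(length(temperature), length(psi), length(time_h))
  temperature <- rep_len(temperature, n)
  psi <- rep_len(psi, n)
  time_h <- rep_len(time_h, n)
  out <- numeric(n)
  ok <- temperature > params$t_base
  if (any(ok)) {
    mu <- .psi_b50_adj(params, temperature[ok])
    x <- psi[ok] - params$theta_halott / ((temperature[ok] - params$t_base) * time_h[ok])
    if (params$sigma_psib == 0) {
      out[ok] <- as.numeric(x > mu)
    } else {
      out[ok] <- stats::pnorm((x - mu) / params$sigma_psib)
    }
  }
  pmin(pmax(out, 0), 1)
}

#' Germination rate of a percentile from a time course
#'
#' Interpolates the time `tg` at which the cumulative curve crosses the
#' percentile `g` of seeds sown and returns GR = 1/tg. Unreached
#' percentiles come back as `NA` (flagged, not an error).
#'
#' @param times_h observation times, h.
#' @param cum_counts cumulative germinated counts.
#' @param n_sown seeds sown.
#' @param g percentile as a fraction of sown (default 0.5).
#' @return list with `tg` (h), `gr` (1/h) and `defined`.
#' @export
gr_from_timecourse <- function(times_h, cum_counts, n_sown, g = 0.5) {
  tg <- time_to_fraction(times_h, cum_counts, n_total = n_sown, fraction = g)
  list(tg = tg, gr = if (is.na(tg)) NA_real_ else 1 / tg, defined = !is.na(tg))
}

#' Derived threshold-time quantities per treatment
#'
#' For each treatment of a dataset: interpolates the time `tg` to the
#' percentile `g` (averaged over the replicates where it is defined) and
#' derives the sub- and supra-optimal thermal times, the halotime and
#' halothermal time, and the germination rate GR = 1/tg. The osmotic
#' driving force is `psi - psi_b(50; T)` under `params`.
#'
#' @param data a [germination_data] object.
#' @param params a [halott_params] carrying `t_base`, `t_ceil` and the base
#'   potential distribution used for the osmotic excess.
#' @param g reference percentile, fraction of sown (default 0.5).
#' @return data.frame with one row per treatment: `tg_h`, `tt_sub`,
#'   `tt_supra`, `theta_halo`, `theta_halott`, `gr`; quantities that do not
#'   apply (e.g. `tt_supra` with unknown Tc, or any of them when `g` is
#'   never reached) are `NA`.
#' @export
derive_cells <- function(data, params, g = 0.5) {
  stopifnot(inherits(params, "halott_params"))
  data <- as_germination_data(data)
  courses <- .courses(data)
  treat <- vapply(courses, function(cs)
    paste(cs$temperature_C[1], cs$psi_MPa[1]), "")
  out <- lapply(split(courses, treat), function(css) {
    tgs <- vapply(css, function(cs)
      time_to_fraction(cs$time_h, cs$cum_germinated, cs$n_sown[1], g), 0)
    tg <- if (all(is.na(tgs))) NA_real_ else mean(tgs, na.rm = TRUE)
    Tt <- css[[1]]$temperature_C[1]
    psi <- css[[1]]$psi_MPa[1]
    dpsi <- psi - .psi_b50_adj(params, Tt)
    cell <- data.frame(temperature_C = Tt, psi_MPa = psi, tg_h = tg,
                       tt_sub = NA_real_, tt_supra = NA_real_,
                       theta_halo = NA_real_, theta_halott = NA_real_,
                       gr = NA_real_)
    if (!is.na(tg)) {
      if (Tt >= params$t_base) cell$tt_sub <- thermal_time_sub(Tt, params$t_base, tg)
      if (!is.na(params$t_ceil) && Tt <= params$t_ceil)
        cell$tt_supra <- thermal_time_supra(params$t_ceil, Tt, tg)
      if (dpsi > 0) {
        cell$theta_halo <- halotime(dpsi, tg)
        if (Tt > params$t_base)
          cell$theta_halott <- halothermal_time(dpsi, Tt, params$t_base, tg)
      }
      cell$gr <- 1 / tg
    }
    cell
  })
  out <- do.call(rbind, out)
  out <- out[order(out$temperature_C, -out$psi_MPa), ]
  rownames(out) <- NULL
  out
}
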