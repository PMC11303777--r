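# Generative simulator of the halothermal-time threshold model.
#
# Each seed i draws a base water potential psi_b_i from
# Normal(psi_b50 + kT max(0, T - To), sigma_psib). The seed germinates iff
# psi > psi_b_i and T > Tb, at
#   t_i = theta / ((psi - psi_b_i) (T - Tb)),
# and is otherwise right-censored (visible only through the counts).
# Cumulative counts are recorded on a regular observation grid. The
# threshold draw is the only stochastic element; an optional lognormal
# timing jitter exists for robustness experiments, default off.

#' Design of a simulated germination experiment
#'
#' The defaults reproduce the emulated study conditions: a 5 temperature
#' (20-40 deg C) by 5 osmotic potential (0 to -0.8 MPa) grid, 3 replicate
#' dishes of 30 seeds, scored every 24 h for 480 h, generated from the
#' default [halott_params()] truth.
#'
#' @param params generating [halott_params].
#' @param temperatures incubation temperatures, deg C.
#' @param psis osmotic potentials, MPa (all <= 0).
#' @param n_seeds seeds per dish.
#' @param n_reps replicate dishes per treatment.
#' @param obs_interval scoring interval, h.
#' @param horizon last scoring time, h.
#' @param seed root RNG seed; per-dish child seeds are derived from it by
#'   a fixed stride so replicates are independent yet reproducible.
#' @param jitter_sdlog sdlog of an optional multiplicative lognormal
#'   timing jitter (0 = the pure threshold model).
#' @return An object of class `sim_design`.
#' @export
sim_design <- function(params = halott_params(),
                       temperatures = c(20, 25, 30, 35, 40),
                       psis = c(0, -0.2, -0.4, -0.6, -0.8),
                       n_seeds = 30, n_reps = 3,
                       obs_interval = 24, horizon = 480,
                       seed = 1L, jitter_sdlog = 0) {
  stopifnot(inherits(params, "halott_params"), n_seeds >= 1, n_reps >= 1,
            obs_interval > 0, horizon >= obs_interval, all(psis <= 0),
            jitter_sdlog >= 0)
  structure(list(params = params, temperatures = temperatures, psis = psis,
                 n_seeds = as.integer(n_seeds), n_reps = as.integer(n_reps),
                 obs_interval = obs_interval, horizon = horizon,
                 seed = as.integer(seed), jitter_sdlog = jitter_sdlog),
            class = "sim_design")
}

#' @export
print.sim_design <- function(x, ...) {
  cat(sprintf(paste0("Simulated germination design: %d temperatures x %d psi",
                     " levels x %d dishes of %d seeds\n"),
              length(x$temperatures), length(x$psis), x$n_reps, x$n_seeds))
  cat(sprintf("  scored every %g h up to %g h; seed %d\n",
              x$obs_interval, x$horizon, x$seed))
  print(x$params)
  invisible(x)
}

#' Simulate a germination dataset from the threshold model
#'
#' @param design a [sim_design].
#' @return A [germination_data] object with
#'   `length(temperatures) * length(psis) * n_reps` courses. Deterministic
#'   given `design$seed`.
#' @examples
#' ds <- simulate_germination(sim_design(n_seeds = 50, seed = 3))
#' @export
simulate_germination <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  p <- design$params
  times <- seq(design$obs_interval, design$horizon, by = design$obs_interval)

  if (exists(".Random.seed", envir = globalenv()))
    old_seed <- get(".Random.seed", envir = globalenv())
  else old_seed <- NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))

  rows <- list()
  dish <- 0L
  for (Tt in design$temperatures) for (psi in design$psis) {
    mu <- .psi_b50_adj(p, Tt)
    for (rep_i in seq_len(design$n_reps)) {
      dish <- dish + 1L
      set.seed((design$seed + 104729L * dish) %% .Machine$integer.max)
      psi_b <- stats::rnorm(design$n_seeds, mu, p$sigma_psib)
      t_i <- rep(Inf, design$n_seeds)
      can <- psi > psi_b & Tt > p$t_base
      t_i[can] <- p$theta_halott / ((psi - psi_b[can]) * (Tt - p$t_base))
      if (design$jitter_sdlog > 0)
        t_i[can] <- t_i[can] * stats::rlnorm(sum(can), 0, design$jitter_sdlog)
      cum <- vapply(times, function(tt) sum(t_i <= tt), 0L)
      rows[[dish]] <- data.frame(
        temperature_C = Tt, psi_MPa = psi, replicate = rep_i,
        time_h = times, cum_germinated = cum, n_sown = design$n_seeds)
    }
  }
  germination_data(do.call(rbind, rows))
}

#' Noise-free germination-rate profile at psi = 0
#'
#' The closed-form GR(g) = 1/tg of the model across temperatures at zero
#' osmotic potential. Below `t_base` the rate is 0. Above `t_opt` two
#' parameterizations of the decline are available: `"cardinal"` (default)
#' declines linearly to zero at `t_ceil` — the classical two-segment
#' cardinal-temperature description — while `"kT"` derives the decline
#' from the shifted base potential, reaching zero where
#' `psi_b(g) + k_t (T - t_opt)` hits 0.
#'
#' @param params a [halott_params].
#' @param temperatures temperatures, deg C.
#' @param g percentile of the base-potential distribution (default 0.5).
#' @param supra supra-optimal construction, `"cardinal"` or `"kT"`.
#' @return data.frame with `temperature_C`, `psi_MPa` (0), `g`, `gr` (1/h).
#' @export
gr_profile <- function(params, temperatures, g = 0.5,
                       supra = c("cardinal", "kT")) {
  stopifnot(inherits(params, "halott_params"), g > 0, g < 1)
  supra <- match.arg(supra)
  psi_bg <- params$psi_b50 + stats::qnorm(g) * params$sigma_psib
  gr_sub <- function(Tt) {
    ifelse(Tt <= params$t_base | psi_bg >= 0, 0,
           (Tt - params$t_base) * (-psi_bg) / params$theta_halott)
  }
  gr <- numeric(length(temperatures))
  below <- is.na(params$t_opt) | temperatures <= params$t_opt
  gr[below] <- gr_sub(temperatures[below])
  if (any(!below)) {
    Ts <- temperatures[!below]
    if (supra == "cardinal") {
      if (is.na(params$t_ceil))
        stop("supra = 'cardinal' needs a finite t_ceil")
      gr_o <- gr_sub(params$t_opt)
      gr[!below] <- pmax(0, gr_o * (params$t_ceil - Ts) /
                              (params$t_ceil - params$t_opt))
    } else {
      if (is.na(params$k_t)) stop("supra = 'kT' needs a finite k_t")
      adj <- psi_bg + params$k_t * (Ts - params$t_opt)
      gr[!below] <- ifelse(adj >= 0, 0,
                           (Ts - params$t_base) * (-adj) / params$theta_halott)
    }
  }
  data.frame(temperature_C = temperatures, psi_MPa = 0, g = g, gr = gr)
}
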