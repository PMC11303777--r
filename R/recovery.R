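# Simulation-based parameter recovery: simulate the full factorial design
# from known parameters, refit, repeat.

#' Parameter-recovery experiment
#'
#' Simulates the full temperature x osmotic-potential design from a known
#' [halott_params] truth, refits the model with [halott()], and repeats.
#' The generating optimum temperature is supplied to the refit (the
#' recovery experiment measures recovery of the threshold-distribution and
#' time-constant parameters; cardinal-temperature estimation is assessed
#' separately on rate profiles, see [gr_profile()] and
#' [cardinal_temperatures()]).
#'
#' @param n_rep number of simulation replicates.
#' @param n_seeds seeds per treatment in each simulated dataset.
#' @param seed root RNG seed; each replicate draws an independent child
#'   seed from it.
#' @param params generating truth (default [halott_params()]).
#' @param temperatures,psis treatment grid (defaults as in [sim_design()]).
#' @param obs_interval,horizon scoring grid, h.
#' @return data.frame with one row per replicate: recovered `psi_b50`,
#'   `sigma_psib`, `theta_halott`, `t_base`, `k_t` and the fit `r2`.
#'   Replicates whose fit fails (none, under realistic settings) are `NA`
#'   rows.
#' @examples
#' \donttest{
#' rec <- parameter_recovery(n_rep = 3, n_seeds = 500, seed = 1)
#' apply(rec, 2, stats::median)
#' }
#' @export
parameter_recovery <- function(n_rep = 20, n_seeds = 1000, seed = 1,
                               params = halott_params(),
                               temperatures = c(20, 25, 30, 35, 40),
                               psis = c(0, -0.2, -0.4, -0.6, -0.8),
                               obs_interval = 24, horizon = 480) {
  if (exists(".Random.seed", envir = globalenv()))
    old_seed <- get(".Random.seed", envir = globalenv())
  else old_seed <- NULL
  set.seed(seed)
  child <- sample.int(.Machine$integer.max - 1L, n_rep)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  rows <- lapply(seq_len(n_rep), function(i) {
    des <- sim_design(params = params, temperatures = temperatures,
                      psis = psis, n_seeds = n_seeds, n_reps = 1,
                      obs_interval = obs_interval, horizon = horizon,
                      seed = child[i])
    fit <- tryCatch(
      suppressWarnings(halott(simulate_germination(des), t_opt = params$t_opt)),
      error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(psi_b50 = NA_real_, sigma_psib = NA_real_,
                        theta_halott = NA_real_, t_base = NA_real_,
                        k_t = NA_real_, r2 = NA_real_))
    co <- coef(fit)
    data.frame(psi_b50 = co[["psi_b50"]], sigma_psib = co[["sigma_psib"]],
               theta_halott = co[["theta_halott"]], t_base = co[["t_base"]],
               k_t = co[["k_t"]], r2 = fit$diagnostics$r2)
  })
  do.call(rbind, rows)
}
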