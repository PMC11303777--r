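# Small in-code fixtures shared across test files.

# one dish observed daily; counts given per day (cumulative)
make_course <- function(cum, temperature = 25, psi = 0, replicate = 1,
                        n_sown = 30, interval_h = 24) {
  data.frame(temperature_C = temperature, psi_MPa = psi,
             replicate = replicate,
             time_h = interval_h * seq_along(cum),
             cum_germinated = cum, n_sown = n_sown)
}

# random monotone course for property loops
random_course <- function(n_days = 8, n_sown = 30) {
  cum <- cumsum(stats::rbinom(n_days, 4, 0.5))
  cum <- pmin(cum, n_sown)
  make_course(cum, n_sown = n_sown)
}

# a small valid dataset: 2 temperatures x 2 psis x 2 reps
make_grid_dataset <- function(seed = 42) {
  des <- sim_design(temperatures = c(25, 30), psis = c(0, -0.4),
                    n_seeds = 30, n_reps = 2, seed = seed)
  simulate_germination(des)
}
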