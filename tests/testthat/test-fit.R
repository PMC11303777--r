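test_that("probit goodness of fit matches an independent least-squares route", {
  obs <- c(0.12, 0.30, 0.45, 0.61, 0.80, 0.93)
  pred <- c(0.10, 0.27, 0.50, 0.58, 0.84, 0.90)
  g <- goodness_of_fit(obs, pred)
  # oracle: lm() on the probit scale
  o <- summary(lm(qnorm(obs) ~ qnorm(pred)))
  expect_equal(g$r2, o$r.squared, tolerance = 1e-10)
  expect_equal(g$se, o$sigma, tolerance = 1e-10)
  expect_equal(g$f_stat, unname(o$fstatistic[1]), tolerance = 1e-10)

  perfect <- goodness_of_fit(obs, obs)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$se, 0)
  expect_equal(goodness_of_fit(obs, rep(0.5, 6))$r2, 0)
  expect_error(goodness_of_fit(obs, pred[-1]), "length")
})

test_that("single-temperature halotime fit recovers generating parameters", {
  # generating median/spread follow a published per-temperature estimate
  truth <- halott_params(psi_b50 = -0.96, sigma_psib = 0.29,
                         theta_halott = 560, t_base = 20)
  des <- sim_design(params = truth, temperatures = 30,
                    psis = c(0, -0.2, -0.4, -0.6, -0.8),
                    n_seeds = 1000, n_reps = 1, seed = 21)
  ds <- simulate_germination(des)
  f <- fit_halo_temperature(ds, 30)
  expect_equal(f$psi_b50, truth$psi_b50, tolerance = 0.05 / 0.96)
  expect_lt(abs(f$sigma_psib - truth$sigma_psib), 0.05)
  # per-temperature halotime constant is theta / (T - Tb)
  expect_equal(f$theta_halo, 560 / 10, tolerance = 0.1)
  expect_gt(f$diagnostics$r2, 0.97)
})

test_that("fits are invariant to replicate relabelling", {
  ds <- simulate_germination(sim_design(temperatures = 30, n_seeds = 100,
                                        n_reps = 3, seed = 4,
                                        params = halott_params(theta_halott = 500)))
  f1 <- fit_halo_temperature(ds, 30)
  shuffled <- as.data.frame(ds)
  shuffled$replicate <- c(3, 1, 2)[shuffled$replicate]
  f2 <- fit_halo_temperature(germination_data(shuffled), 30)
  expect_equal(f1$psi_b50, f2$psi_b50)
  expect_equal(f1$theta_halo, f2$theta_halo)
})

test_that("degenerate and empty inputs fail loudly", {
  zero <- make_course(rep(0L, 5), temperature = 30, psi = -0.2)
  zero2 <- make_course(rep(0L, 5), temperature = 30, psi = -0.4)
  expect_error(fit_halo_temperature(germination_data(rbind(zero, zero2)), 30),
               "too few|all-zero")
  one_psi <- make_course(c(5, 10, 15), temperature = 30, psi = -0.2)
  expect_error(fit_halo_temperature(germination_data(one_psi), 30),
               ">= 2 osmotic")
})

test_that("a cramped search grid reports its boundary with a warning", {
  ds <- simulate_germination(sim_design(temperatures = 30, n_seeds = 300,
                                        n_reps = 1, seed = 8,
                                        params = halott_params(theta_halott = 500)))
  expect_warning(f <- fit_halo_temperature(ds, 30, theta_grid = c(1, 2, 4)),
                 "boundary")
  expect_lte(f$theta_halo, 4)
})

test_that("the global fit recovers the generating truth on one dataset", {
  truth <- halott_params()
  des <- sim_design(params = truth, n_seeds = 1000, n_reps = 1, seed = 31)
  fit <- halott(simulate_germination(des), t_opt = truth$t_opt)
  co <- coef(fit)
  expect_lt(abs(co[["psi_b50"]] - truth$psi_b50), 0.08)
  expect_lt(abs(co[["sigma_psib"]] - truth$sigma_psib), 0.08)
  expect_equal(co[["theta_halott"]], truth$theta_halott, tolerance = 0.2)
  expect_gt(fit$diagnostics$r2, 0.95)
})

test_that("rescaling time from hours to days rescales theta only", {
  des <- sim_design(n_seeds = 500, n_reps = 1, seed = 13)
  ds_h <- simulate_germination(des)
  ds_d <- as.data.frame(ds_h)
  ds_d$time_h <- ds_d$time_h / 24       # now in days
  fit_h <- halott(ds_h, t_opt = 33)
  fit_d <- halott(germination_data(ds_d), t_opt = 33,
                  theta_grid = exp(seq(log(1 / 24), log(5000 / 24),
                                       length.out = 201)))
  expect_equal(coef(fit_d)[["theta_halott"]] * 24,
               coef(fit_h)[["theta_halott"]], tolerance = 1e-3)
  expect_equal(coef(fit_d)[["psi_b50"]], coef(fit_h)[["psi_b50"]],
               tolerance = 1e-3)
  expect_equal(coef(fit_d)[["t_base"]], coef(fit_h)[["t_base"]],
               tolerance = 1e-2)
})

test_that("two-segment rate regression locates cardinal temperatures", {
  # exact tent through (20, 0) and (45, 0) crossing at 33
  Tt <- c(22, 26, 30, 33, 36, 40, 44)
  tent <- function(x) ifelse(x <= 33, (x - 20) / 13, (45 - x) / 12)
  cd <- cardinal_temperatures(Tt, tent(Tt))
  expect_equal(cd$t_base, 20, tolerance = 1e-8)
  expect_equal(cd$t_opt, 33, tolerance = 1e-8)
  expect_equal(cd$t_ceil, 45, tolerance = 1e-8)
  expect_equal(cd$r2, 1, tolerance = 1e-10)

  # symmetric tent: the optimum sits at the apex
  Ts <- c(21, 25, 29, 33, 37, 41, 45)
  sym <- ifelse(Ts <= 33, Ts - 20, 46 - Ts)
  expect_equal(cardinal_temperatures(Ts, sym)$t_opt, 33, tolerance = 1e-8)

  # zero-rate points below Tb are censored and change nothing
  cd2 <- cardinal_temperatures(c(10, 15, Tt), c(0, 0, tent(Tt)))
  expect_equal(cd2$t_opt, cd$t_opt)
  expect_equal(cd2$t_base, cd$t_base)

  # monotone profile: one-sided answer, missing cardinals flagged
  expect_warning(m <- cardinal_temperatures(c(22, 26, 30, 34), (c(22, 26, 30, 34) - 20) / 13),
                 "one-sided")
  expect_equal(m$t_base, 20, tolerance = 1e-8)
  expect_true(is.na(m$t_ceil))
})
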