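# Worked examples evaluated by hand from the index definitions, then the
# structural properties of the index family.

test_that("extent and speed indices reproduce hand-computed values", {
  daily <- function(cum) make_course(cum)
  # GP bounds and interior
  expect_equal(germination_percentage(c(10, 27), 30), 90)
  expect_equal(germination_percentage(c(0, 0), 30), 0)
  expect_equal(germination_percentage(c(30, 30), 30), 100)
  expect_error(germination_percentage(c(1, 2), 0), "n_sown")

  # GE: 10 on day 1 + 10 on day 2 -> 10/1 + 10/2
  expect_equal(germination_energy(c(24), c(10)), 10)
  expect_equal(germination_energy(c(24, 48), c(10, 20)), 15)
  expect_equal(germination_energy(c(24, 48), c(0, 0)), 0)

  # GI: n1 = 5, n2 = 5 -> 10*5 + 9*5
  expect_equal(germination_index(c(24, 48), c(5, 10)), 95)
  expect_equal(germination_index(240, 7), 7)            # all on day 10
  expect_equal(germination_index(c(24, 48), c(0, 0)), 0)
  expect_warning(germination_index(c(24, 264), c(5, 8)), "weight 0")
  expect_error(germination_index(24, 5, horizon = 0), "horizon")

  # GRI: G1 = 10%, G2 = 10% -> 10 + 5
  expect_equal(germination_rate_index(24, 3, 30), 10)
  expect_equal(germination_rate_index(c(24, 48), c(3, 6), 30), 15)

  # TGI: cumulative 50, 100, 100 % over 3 days -> 250/3
  expect_equal(timson_index(c(24, 48, 72), c(15, 30, 30), 30), 250 / 3)
  expect_equal(timson_index(c(24, 48, 72), c(30, 30, 30), 30), 100)
  expect_equal(timson_index(c(24, 48, 72), c(0, 0, 0), 30), 0)
})

test_that("timing indices reproduce hand-computed values", {
  # MGT: symmetric 5@d2 + 5@d4 -> 3; all d3 -> 3; 9@d1 + 1@d11 -> 2
  expect_equal(mean_germination_time(c(48, 96), c(5, 10)), 3)
  expect_equal(mean_germination_time(72, 12), 3)
  expect_equal(mean_germination_time(c(24, 264), c(9, 10)), 2)
  expect_true(is.na(mean_germination_time(c(24, 48), c(0, 0))))

  # MGR = 1/MGT
  expect_equal(mean_germination_rate(72, 12), 1 / 3)
  expect_true(is.na(mean_germination_rate(24, 0)))

  # CVG: all day 1 -> 100 (theoretical max); all day 2 -> 50; 10@d1+10@d3 -> 50
  expect_equal(coefficient_of_velocity(24, 10), 100)
  expect_equal(coefficient_of_velocity(48, 10), 50)
  expect_equal(coefficient_of_velocity(c(24, 72), c(10, 20)), 50)

  # T50: counts 10@24h, 20@48h with N = 30 -> 36 h
  expect_equal(time_to_fraction(c(24, 48), c(10, 20), n_total = 30), 36)
  expect_equal(time_to_fraction(c(24, 48), c(15, 30), n_total = 30), 24)
  expect_true(is.na(time_to_fraction(c(24, 48), c(10, 12), n_total = 30)))
  # tied bracketing counts degenerate to the earlier time
  expect_equal(time_to_fraction(c(24, 48, 72), c(0, 15, 15), n_total = 60,
                                fraction = 0.25), 48)
})

test_that("vigour indices and assay conversions are literal products", {
  expect_equal(seed_vigor_index_i(90, 10), 900)
  expect_equal(seed_vigor_index_i(0, 4), 0)
  expect_equal(seed_vigor_index_ii(90, 2), 180)
  expect_equal(seed_vigor_index_ii(50, 0.5), 25)

  expect_equal(sod_activity(0.5, 0.5, 3, 0.1, 0.5), 0)
  expect_equal(sod_activity(0.5, 0.25, 3, 0.1, 0.5), 0.15)
  expect_equal(sod_activity(0.5, 0.25, 6, 0.1, 0.5),
               2 * sod_activity(0.5, 0.25, 3, 0.1, 0.5))
  expect_error(sod_activity(0, 0.2, 3, 0.1, 0.5), "od_control")

  expect_equal(pod_activity(0, 3, 26.6, 3, 0.1, 0.5), 0)
  expect_equal(pod_activity(0.3, 3, 26.6, 3, 0.1, 0.5), 22.556, tolerance = 1e-4)
  expect_equal(pod_activity(0.3, 3, 26.6, 3, 0.1, 0.25),
               2 * pod_activity(0.3, 3, 26.6, 3, 0.1, 0.5))
})

test_that("MGR x MGT is exactly 1 whenever both are defined", {
  set.seed(11)
  for (i in 1:20) {
    cs <- random_course()
    mgt <- mean_germination_time(cs$time_h, cs$cum_germinated)
    mgr <- mean_germination_rate(cs$time_h, cs$cum_germinated)
    if (!is.na(mgt)) expect_equal(mgr * mgt, 1, tolerance = 1e-15)
  }
})

test_that("CVG is 100 iff all germination is on day 1 and drops when delayed", {
  set.seed(12)
  for (i in 1:20) {
    cs <- random_course()
    cum <- cs$cum_germinated
    if (max(cum) == 0) next
    cvg <- coefficient_of_velocity(cs$time_h, cum)
    all_day1 <- all(cum == cum[1])
    expect_identical(cvg == 100, all_day1)
    if (!all_day1) {
      # delaying one day-1 seed by a day strictly lowers CVG
      if (cum[1] > 0) {
        delayed <- cum
        delayed[1] <- delayed[1] - 1L
        expect_lt(coefficient_of_velocity(cs$time_h, delayed), cvg)
      }
    }
  }
})

test_that("count-based indices pool over replicates as sums or weighted means", {
  a <- c(3, 8, 12)
  b <- c(5, 6, 14)
  tt <- c(24, 48, 72)
  pooled <- a + b
  expect_equal(germination_energy(tt, pooled),
               germination_energy(tt, a) + germination_energy(tt, b))
  expect_equal(germination_index(tt, pooled),
               germination_index(tt, a) + germination_index(tt, b))
  # percent-based indices pool to the sown-weighted mean
  expect_equal(germination_rate_index(tt, pooled, 60),
               (germination_rate_index(tt, a, 30) +
                  germination_rate_index(tt, b, 30)) / 2)
  expect_equal(timson_index(tt, pooled, 60),
               (timson_index(tt, a, 30) + timson_index(tt, b, 30)) / 2)
})

test_that("indices ignore redundant observation times", {
  tt <- c(24, 48, 72)
  cum <- c(4, 9, 15)
  tt2 <- c(24, 30, 48, 60, 72)   # extra times, counts unchanged
  cum2 <- c(4, 4, 9, 9, 15)
  expect_equal(germination_energy(tt2, cum2), germination_energy(tt, cum))
  expect_equal(germination_index(tt2, cum2), germination_index(tt, cum))
  expect_equal(mean_germination_time(tt2, cum2), mean_germination_time(tt, cum))
  expect_equal(coefficient_of_velocity(tt2, cum2), coefficient_of_velocity(tt, cum))
  expect_equal(time_to_fraction(tt2, cum2, 30), time_to_fraction(tt, cum, 30))
})

test_that("the per-course report matches the individual operations", {
  ds <- make_grid_dataset()
  rep1 <- germination_indices(ds)
  cs <- .subset2(split(as.data.frame(ds),
                       paste(ds$temperature_C, ds$psi_MPa, ds$replicate)), 1)
  row <- rep1[rep1$temperature_C == cs$temperature_C[1] &
                rep1$psi_MPa == cs$psi_MPa[1] &
                rep1$replicate == cs$replicate[1], ]
  expect_equal(row$gp, germination_percentage(cs$cum_germinated, cs$n_sown[1]))
  expect_equal(row$ge, germination_energy(cs$time_h, cs$cum_germinated))
  expect_equal(row$mgt, mean_germination_time(cs$time_h, cs$cum_germinated))
  expect_equal(row$cvg, coefficient_of_velocity(cs$time_h, cs$cum_germinated))
})

test_that("zero-germination courses are reported with undefined flags", {
  cs <- make_course(rep(0L, 4))
  rep0 <- germination_indices(germination_data(cs))
  expect_equal(rep0$gp, 0)
  expect_true(is.na(rep0$mgt) && is.na(rep0$t50))
  expect_match(rep0$undefined_flags, "mgt")
  expect_match(rep0$undefined_flags, "t50")
})

test_that("morphology columns switch the vigour indices on", {
  cs <- make_course(c(10, 27))
  cs$seedling_length_cm <- 10
  cs$seedling_dry_weight_mg <- 2
  r <- germination_indices(germination_data(cs))
  expect_equal(r$svi_i, 900)
  expect_equal(r$svi_ii, 180)
  r2 <- germination_indices(germination_data(make_course(c(10, 27))))
  expect_false("svi_i" %in% names(r2))
})
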