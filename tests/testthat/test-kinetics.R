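test_that("decay constants follow ln(2)/half-life for the three donors", {
  expect_equal(decay_constant(donor_spec("dea")), log(2) / 960)
  expect_equal(decay_constant(donor_spec("sper")), log(2) / 13800)
  expect_equal(decay_constant(donor_spec("deta")), log(2) / 205200)
  expect_equal(decay_constant(donor_spec("dea")), 7.22e-4, tolerance = 1e-3)
  expect_equal(decay_constant(donor_spec("sper")), 5.02e-5, tolerance = 1e-3)
  expect_equal(decay_constant(donor_spec("deta")), 3.38e-6, tolerance = 1e-3)
  expect_error(donor_spec("custom", half_life = -1, no_equivalents = 2),
               "positive")
  expect_error(donor_spec("custom", half_life = 100, no_equivalents = 0),
               "positive")
})

test_that("zero dose yields no NO and untouched O2", {
  tc <- simulate_no(donor_spec("sper"), 0, duration = 3600, output_step = 60)
  expect_true(all(tc$no_uM == 0))
  expect_true(all(tc$o2_uM == 220))
  expect_true(all(tc$no_consumed_uM == 0))
})

test_that("donor decays exactly first-order: half remains at the half-life", {
  for (name in c("dea", "sper")) {
    d <- donor_spec(name)
    tc <- simulate_no(d, 50, duration = d$half_life,
                      output_step = d$half_life / 500)
    at_half <- tc$donor_uM[which.min(abs(tc$time_s - d$half_life))]
    expect_equal(at_half, 25, tolerance = 1e-4)
  }
})

test_that("mass balance holds: released NO equals free NO plus oxidised NO", {
  set.seed(42)
  for (i in 1:5) {
    d <- donor_spec("custom", half_life = runif(1, 500, 5e4),
                    no_equivalents = sample(c(1.5, 2), 1))
    dose <- runif(1, 5, 300)
    tc <- simulate_no(d, dose, duration = 2 * 3600, output_step = 120)
    released <- d$no_equivalents * (dose - tc$donor_uM)
    expect_equal(tc$no_uM + tc$no_consumed_uM, released, tolerance = 1e-3)
    # non-negativity and donor monotone decay
    expect_true(all(tc$no_uM >= 0 & tc$o2_uM >= 0 & tc$donor_uM >= 0))
    expect_true(all(diff(tc$donor_uM) <= 1e-12))
    expect_true(all(diff(tc$no_consumed_uM) >= -1e-12))
  }
})

test_that("full donor exhaustion releases e_NO x dose in total", {
  d <- donor_spec("dea")               # 16 min half-life
  tc <- simulate_no(d, 25, duration = 3 * 3600, output_step = 30)
  n <- nrow(tc)
  expect_lt(tc$donor_uM[n], 0.001 * 25)                 # < 0.1% remains at 3 h
  expect_equal(tc$no_uM[n] + tc$no_consumed_uM[n], 1.5 * 25, tolerance = 1e-3)
})

test_that("quasi-steady-state closed form matches hand-evaluated values", {
  # sqrt(k1 D e / (s k O2)) evaluated by hand for the two slow donors
  expect_equal(quasi_steady_state_no(donor_spec("sper"), 165), 3.07,
               tolerance = 0.005)
  expect_equal(quasi_steady_state_no(donor_spec("deta"), 100), 0.62,
               tolerance = 0.005)
  expect_equal(quasi_steady_state_no(donor_spec("sper"), 0), 0)
  expect_error(
    quasi_steady_state_no(donor_spec("sper"), 10,
                          kinetic_params(o2_initial = 0)),
    "O2")
})

test_that("ODE NO tracks the analytic quasi-steady-state for slow donors", {
  for (name in c("sper", "deta")) {
    d <- donor_spec(name)
    tc <- simulate_no(d, 100, duration = 3 * 3600, output_step = 60)
    # relaxation time ~ 1/(2 s k O2 NOss); take t > 10x
    no_ss0 <- quasi_steady_state_no(d, 100)
    relax <- 1 / (2 * 4 * 2e-6 * 220 * no_ss0)
    late <- tc$time_s > 10 * relax
    qss <- quasi_steady_state_no(d, tc$donor_uM[late]) *
      sqrt(220 / tc$o2_uM[late])        # O2 depletion correction
    expect_true(all(abs(tc$no_uM[late] - qss) / qss < 0.10))
  }
})

test_that("steady-state NO responds monotonically to dose and stoichiometry", {
  d <- donor_spec("sper")
  mean_no <- function(dose, params = kinetic_params(), e = 2) {
    dd <- donor_spec("custom", half_life = d$half_life, no_equivalents = e)
    tc <- simulate_no(dd, dose, params, duration = 3600, output_step = 60)
    summarize_steady_state(tc)$mean_no_uM
  }
  doses <- c(10, 50, 150, 400)
  expect_true(all(diff(vapply(doses, mean_no, numeric(1))) > 0))
  expect_gt(mean_no(100, e = 2), mean_no(100, e = 1.5))
  expect_gt(mean_no(100, kinetic_params(no_per_o2 = 1)),
            mean_no(100, kinetic_params(no_per_o2 = 4)))
  expect_gt(mean_no(100, kinetic_params(o2_initial = 100)),
            mean_no(100, kinetic_params(o2_initial = 220)))
})

test_that("window summaries: constant NO has mean = peak; bad windows error", {
  tc <- make_no_timecourse(seq(0, 100, 10), rep(2.5, 11))
  s <- summarize_steady_state(tc, c(0, 100))
  expect_equal(s$mean_no_uM, 2.5)
  expect_equal(s$peak_no_uM, 2.5)
  expect_error(summarize_steady_state(tc, c(50, 50)), "t_start < t_end")
  expect_error(summarize_steady_state(tc, c(0, 1e6)), "span")
})

test_that("donor IC50 converts to the NO scale via simulation", {
  s <- donor_ic50_to_no_ic50(donor_spec("sper"), 165, assay_duration = 3 * 3600)
  expect_equal(s$mean_no_uM, 3, tolerance = 0.3)
  s0 <- donor_ic50_to_no_ic50(donor_spec("sper"), 0, assay_duration = 3600)
  expect_equal(s0$mean_no_uM, 0)
  expect_equal(s0$peak_no_uM, 0)
})
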