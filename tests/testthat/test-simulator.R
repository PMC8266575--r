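test_that("simulated cycles follow the mixture and the ramp distribution", {
  pr <- default_protocol()
  pol <- default_polymer()
  ns <- noise_model()

  # all-unfolded mixture: no rupture events at all
  st <- bell_state(1e-6, 1.0, step_nt = 16)
  mix0 <- state_mixture(list(st), 0, w_unfolded = 1)
  cyc0 <- simulate_cycles(mix0, pr, pol, ns, 200, seed = 1)
  expect_equal(sum(cyc0$ruptured), 0)
  expect_true(all(cyc0$state_truth == "unfolded"))

  # single state: empirical rupture-force CDF matches the closed form
  mix1 <- state_mixture(list(st), 1, 0)
  cyc1 <- simulate_cycles(mix1, pr, pol, ns, 1e5, seed = 2)
  f <- cyc1$force[cyc1$ruptured]
  grid <- seq(pr$f_start, 60, length.out = 300)
  # condition on detection below the ceiling
  p_det <- 1 - ramp_survival(60, st, pr)
  cdf <- (1 - ramp_survival(grid, st, pr)) / p_det
  expect_lt(max(abs(stats::ecdf(f)(grid) - cdf)), 0.01)

  # three-state mixture: state fractions within 3 sigma of the weights
  sc <- load_scenario("TB-1")
  cyc3 <- simulate_cycles(sc$mixture, sc$protocol, sc$polymer, ns, 20000,
                          seed = 3)
  tab <- table(cyc3$state_truth) / nrow(cyc3)
  truth <- c(sc$truth$weight, unfolded = sc$w_unfolded)
  names(truth) <- c(sc$truth$label, "unfolded")
  for (nm in names(truth)) {
    se <- sqrt(truth[[nm]] * (1 - truth[[nm]]) / nrow(cyc3))
    expect_lt(abs(tab[[nm]] - truth[[nm]]), 3 * se + 1e-9)
  }

  # reproducibility: same seed, bit-identical output
  expect_identical(simulate_cycles(sc$mixture, pr, pol, ns, 100, seed = 9),
                   simulate_cycles(sc$mixture, pr, pol, ns, 100, seed = 9))
  expect_error(state_mixture(list(), numeric(0)), "at least one")
})

test_that("censoring flags cycles whose rupture exceeds the force ceiling", {
  pr <- default_protocol()
  # a very stable state: most draws land beyond 60 pN
  st <- bell_state(k_unfold_from_modal_force(70, 1, pr), 1, step_nt = 16)
  mix <- state_mixture(list(st), 1, 0)
  cyc <- simulate_cycles(mix, pr, default_polymer(), noise_model(), 2000,
                         seed = 4)
  expect_gt(sum(cyc$censored), 1000)
  expect_true(all(is.na(cyc$force[cyc$censored])))
  expect_true(all(cyc$force[cyc$ruptured] >= pr$f_start))
  expect_true(all(cyc$force[cyc$ruptured] <= pr$f_end))
})

test_that("folding-probability series follows first-order kinetics", {
  # expected fraction at the half-time of the exponential
  t_half <- log(2) / 0.11
  ser <- simulate_pfold_series(0.94, 0.11, rep(t_half, 400), 100, seed = 5)
  expect_equal(mean(ser$n_folded / ser$n_total), 0.47, tolerance = 0.01)
  # t = 0 gives no folding; the plateau approaches p_st
  ser2 <- simulate_pfold_series(0.8, 0.5, c(1e-12, 1000), 500, seed = 6)
  expect_equal(ser2$n_folded[1], 0)
  expect_equal(ser2$n_folded[2] / 500, 0.8, tolerance = 0.06)
  expect_error(simulate_pfold_series(1.2, 0.1, 1:5, 10), "p_st")
  expect_error(simulate_pfold_series(0.5, -1, 1:5, 10), "k_fold")
})

test_that("simulated traces step by delta_x at the programmed time", {
  pr <- default_protocol()
  pol <- default_polymer()
  quiet <- noise_model(sigma_step = 0, sigma_bead = 0, trace_rate = 50)
  ev <- data.frame(ruptured = TRUE, force = 30, delta_x = 5.4)
  tr <- simulate_trace(ev, pr, pol, quiet, seed = 1)
  t_rupt <- (30 - pr$f_start) / pr$loading_rate
  before <- tr$extension_nm[tr$time_s < t_rupt]
  after <- tr$extension_nm[tr$time_s >= t_rupt]
  # the jump across the rupture sample is the programmed step plus the
  # smooth baseline increment of one sample
  jump <- after[1] - before[length(before)]
  expect_equal(jump, 5.4, tolerance = 0.05)
  # unruptured cycle: smooth baseline, no detectable step (the handle is
  # most compliant at low force, so successive samples may still differ by
  # ~1 nm early in the ramp)
  un <- data.frame(ruptured = FALSE, force = NA, delta_x = NA)
  tr0 <- simulate_trace(un, pr, pol, quiet, seed = 1)
  late <- tr0[tr0$force_pN > 10, ]
  expect_lt(max(abs(diff(late$extension_nm))), 0.2)
  tr0n <- simulate_trace(un, pr, pol, noise_model(sigma_bead = 1,
                                                  trace_rate = 50), seed = 1)
  expect_null(detect_step(tr0n, window = 25))
})

test_that("melting curves are sigmoidal between the baselines", {
  noiseless <- simulate_melting_curve(48, 3, baselines = c(0.1, 0.9),
                                      noise_sd = 0, seed = 1)
  # midpoint at tm, monotone, bounded by baselines
  y_at_tm <- noiseless$signal[noiseless$temp_C == 48]
  expect_equal(y_at_tm, 0.5, tolerance = 1e-12)
  expect_true(all(diff(noiseless$signal) > 0))
  expect_true(all(noiseless$signal > 0.1 & noiseless$signal < 0.9))
  expect_error(simulate_melting_curve(48, 0), "width")
})
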