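test_that("single-state parameters are recovered by censored MLE", {
  pr <- default_protocol()
  truth <- bell_state(1e-6, 1.0, step_nt = 16)
  mix <- state_mixture(list(truth), 1, 0)
  cyc <- simulate_cycles(mix, pr, default_polymer(), noise_model(), 5000,
                         seed = 21)
  fit <- fit_bell_mixture(cyc$force[cyc$ruptured], sum(!cyc$ruptured), pr,
                          K = 1, seed = 1)
  expect_lt(abs(log(fit$states$k_unfold) - log(1e-6)), 0.5)
  expect_lt(abs(fit$states$dx - 1.0) / 1.0, 0.10)
  expect_equal(fit$states$weight, 1, tolerance = 0.02)
})

test_that("the TB-1-like three-state ensemble is recovered from 5000 cycles", {
  fx <- scenario_fit("TB-1", K = 3)
  truth <- fx$scenario$truth
  fit <- fx$fit
  expect_equal(fit$states$modal_force, truth$peak_pN, tolerance = 2 / 22)
  expect_true(all(abs(fit$states$weight - truth$weight) < 0.05))
  expect_lt(abs(fit$w_censored_excess - fx$scenario$w_unfolded), 0.05)
  # likelihood of the best multi-start never below a single default start
  one <- fit_bell_mixture(fx$forces, fit$n_censored, fx$scenario$protocol,
                          K = 3, n_starts = 1, seed = 1)
  expect_gte(fit$log_likelihood + 1e-6, one$log_likelihood)
})

test_that("fitted mixture density integrates to one over the force axis", {
  fx <- scenario_fit("TB-1", K = 3)
  fit <- fx$fit
  dens <- function(f) {
    rowSums(vapply(seq_len(fit$K), function(i) {
      fit$states$weight_events[i] *
        ramp_pdf(f, bell_state(fit$states$k_unfold[i], fit$states$dx[i]),
                 fit$protocol) /
        (1 - ramp_survival(fit$protocol$f_end,
                           bell_state(fit$states$k_unfold[i],
                                      fit$states$dx[i]), fit$protocol))
    }, numeric(length(f))))
  }
  total <- stats::integrate(dens, fit$protocol$f_start, fit$protocol$f_end,
                            rel.tol = 1e-8)$value
  expect_equal(total, 1, tolerance = 1e-4)
})

test_that("degenerate inputs are rejected", {
  pr <- default_protocol()
  expect_error(fit_bell_mixture(numeric(0), 100, pr, K = 1), "no observed")
  expect_error(fit_bell_mixture(c(10, 20, 30), 0, pr, K = 2), "at least 5")
  expect_error(fit_bell_mixture(c(10, 20, 30, 40, 50, 70), 0, pr, K = 1),
               "within")
})

test_that("MLE peaks agree with a histogram least-squares oracle", {
  pr <- default_protocol()
  truth <- bell_state(3e-6, 0.9)
  mix <- state_mixture(list(truth), 1, 0)
  cyc <- simulate_cycles(mix, pr, default_polymer(), noise_model(), 2e4,
                         seed = 31)
  f <- cyc$force[cyc$ruptured]
  fit <- fit_bell_mixture(f, sum(!cyc$ruptured), pr, K = 1, seed = 1)
  # oracle: least squares of the ramp density against a fine histogram,
  # parameterised in (modal force, dx) so the surface is well conditioned
  h <- hist(f, breaks = seq(pr$f_start, pr$f_end, by = 1), plot = FALSE)
  ls <- stats::optim(c(h$mids[which.max(h$density)], 1.2), function(th) {
    st <- bell_state(k_unfold_from_modal_force(th[1], max(th[2], 0.05), pr),
                     max(th[2], 0.05))
    sum((h$density - ramp_pdf(h$mids, st, pr))^2)
  })
  expect_lt(abs(fit$states$modal_force - ls$par[1]), 1)
})

test_that("BIC selects the generating number of components", {
  pr <- default_protocol()
  # one state -> K = 1 in repeated replicates
  mix1 <- state_mixture(list(bell_state(1e-6, 1.0)), 1, 0)
  picks <- vapply(1:5, function(s) {
    cyc <- simulate_cycles(mix1, pr, default_polymer(), noise_model(), 1500,
                           seed = 40 + s)
    select_K(cyc$force[cyc$ruptured], sum(!cyc$ruptured), pr, K_max = 2,
             seed = 1, n_starts = 4)$K
  }, numeric(1))
  expect_true(all(picks == 1))

  # two well-separated states -> K = 2
  fx <- scenario_fit("TB-8", K = 2, n_cycles = 3000, sim_seed = 12)
  sel <- select_K(fx$forces, fx$fit$n_censored, fx$scenario$protocol,
                  K_max = 3, seed = 1, n_starts = 5)
  expect_equal(sel$K, 2)
  expect_equal(nrow(sel$K_table), 3)
})

test_that("population fractions split mixture mass at the 40 pN threshold", {
  fx <- scenario_fit("TB-1", K = 3)
  pf <- population_fractions(fx$fit, threshold = 40, forces = fx$forces)
  expect_equal(pf$below + pf$above + fx$fit$w_censored_excess, 1,
               tolerance = 1e-9)
  expect_equal(pf$below, 0.87, tolerance = 0.05)
  expect_equal(pf$below_events + pf$above_events, 1, tolerance = 1e-9)
  expect_lt(abs(pf$below_empirical - pf$below_events), 0.05)
  # a threshold below every component puts all mass above it
  pf0 <- population_fractions(fx$fit, threshold = 0)
  expect_equal(pf0$below, 0)
  expect_equal(pf0$above + fx$fit$w_censored_excess, 1, tolerance = 1e-9)
})

test_that("bootstrap intervals are reproducible and cover the truth", {
  pr <- default_protocol()
  truth <- bell_state(1e-6, 1.0)
  mix <- state_mixture(list(truth), 1, 0)
  cyc <- simulate_cycles(mix, pr, default_polymer(), noise_model(), 600,
                         seed = 51)
  f <- cyc$force[cyc$ruptured]
  fit <- fit_bell_mixture(f, sum(!cyc$ruptured), pr, K = 1, seed = 1)
  ci <- bootstrap_cis(f, sum(!cyc$ruptured), pr, fit, n_boot = 100, seed = 7)
  truth_mode <- as.numeric(modal_force(truth, pr))
  expect_lt(ci$modal_force$lower, truth_mode)
  expect_gt(ci$modal_force$upper, truth_mode)
  expect_lt(ci$log_k_unfold$lower, log(1e-6))
  expect_gt(ci$log_k_unfold$upper, log(1e-6))
  ci2 <- bootstrap_cis(f, sum(!cyc$ruptured), pr, fit, n_boot = 100, seed = 7)
  expect_identical(ci, ci2)
  expect_error(bootstrap_cis(rep(20, 50), 0, pr, fit, n_boot = 100),
               "degenerate")
})
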