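test_that("Bell hazard is log-linear in force", {
  st <- bell_state(1e-5, 1.0)
  expect_equal(bell_hazard(0, st), 1e-5)
  expect_equal(bell_hazard(41.1, st, kBT = 4.11), 1e-5 * exp(10),
               tolerance = 1e-12)
  f <- seq(0, 60, by = 5)
  lk <- log(bell_hazard(f, st, kBT = 4.11))
  slopes <- diff(lk) / diff(f)
  expect_equal(slopes, rep(1 / 4.11, length(slopes)), tolerance = 1e-10)
  expect_error(bell_hazard(-1, st), "non-negative")
})

test_that("closed-form ramp survival matches hazard quadrature", {
  pr <- ramp_protocol()
  for (st in list(bell_state(1e-6, 1.0), bell_state(1e-3, 0.5),
                  bell_state(5e-7, 1.5))) {
    expect_equal(ramp_survival(pr$f_start, st, pr), 1)
    for (f in seq(5, 60, by = 5)) {
      num <- stats::integrate(function(x) bell_hazard(x, st, pr$kBT) /
                                pr$loading_rate,
                              pr$f_start, f, rel.tol = 1e-13)$value
      expect_equal(ramp_survival(f, st, pr), exp(-num),
                   tolerance = 1e-10)
    }
  }
  # vanishing unfolding rate: survival -> 1 everywhere
  slow <- bell_state(1e-30, 1.0)
  expect_equal(ramp_survival(c(10, 40, 60), slow, ramp_protocol()),
               c(1, 1, 1), tolerance = 1e-12)
  expect_error(ramp_survival(0.5, bell_state(1e-5, 1), ramp_protocol()),
               "f_start")
})

test_that("rupture-force density normalises and peaks at the modal force", {
  pr <- ramp_protocol()
  st <- bell_state(1e-6, 1.0)
  expect_equal(ramp_pdf(pr$f_start, st, pr),
               bell_hazard(pr$f_start, st, pr$kBT) / pr$loading_rate)
  total <- stats::integrate(function(f) ramp_pdf(f, st, pr),
                            pr$f_start, 200, rel.tol = 1e-10)$value
  expect_equal(total, 1, tolerance = 1e-6)
  # mode agrees with direct maximisation of the density (coarse grid then
  # local refinement, so the search cannot stall on the flat tails)
  for (st in list(bell_state(1e-6, 1.0), bell_state(1e-4, 0.7),
                  bell_state(1e-7, 1.2))) {
    grid <- seq(pr$f_start, 120, by = 0.5)
    f0 <- grid[which.max(ramp_pdf(grid, st, pr))]
    opt <- stats::optimize(function(f) ramp_pdf(f, st, pr),
                           c(f0 - 1, f0 + 1), maximum = TRUE,
                           tol = 1e-8)$maximum
    expect_lt(abs(as.numeric(modal_force(st, pr)) - opt), 0.01)
  }
  # monotone in loading rate, antitone in k_unfold
  st <- bell_state(1e-6, 1.0)
  rates <- c(0.5, 2, 8)
  modes <- vapply(rates, function(r) {
    as.numeric(modal_force(st, ramp_protocol(loading_rate = r)))
  }, numeric(1))
  expect_true(all(diff(modes) > 0))
  ks <- c(1e-7, 1e-6, 1e-5)
  modes_k <- vapply(ks, function(k) {
    as.numeric(modal_force(bell_state(k, 1.0), pr))
  }, numeric(1))
  expect_true(all(diff(modes_k) < 0))
  # fast unfolder whose mode sits below the ramp start is flagged
  fast <- bell_state(10, 1.0)
  m <- modal_force(fast, pr)
  expect_equal(as.numeric(m), pr$f_start)
  expect_true(attr(m, "at_boundary"))
})

test_that("inverse-CDF sampling reproduces the survival function", {
  pr <- ramp_protocol()
  st <- bell_state(1e-6, 1.0)
  u <- c(1e-9, 0.25, 0.5, 0.9, 1 - 1e-9)
  f <- sample_force(u, st, pr)
  expect_equal(ramp_survival(f, st, pr), 1 - u, tolerance = 1e-9)
  expect_equal(sample_force(1e-12, st, pr), pr$f_start, tolerance = 1e-4)
  expect_error(sample_force(0, st, pr), "strictly")
  expect_error(sample_force(1, st, pr), "strictly")
  # empirical CDF of 1e5 exact samples vs closed form
  set.seed(42)
  samp <- sample_force(runif(1e5), st, pr)
  grid <- seq(pr$f_start, max(samp), length.out = 400)
  ecdf_v <- stats::ecdf(samp)(grid)
  cdf_v <- 1 - ramp_survival(grid, st, pr)
  expect_lt(max(abs(ecdf_v - cdf_v)), 0.01)
})

test_that("modal forces near 55 pN at 2 pN/s imply slow zero-force unfolding", {
  # mechanically stable G4s (peak ~55 pN) should show k_unfold in the
  # 1e-7..1e-5 1/s range for transition distances around 1 nm
  pr <- ramp_protocol()
  for (dx in c(0.8, 1.0, 1.1)) {
    k <- k_unfold_from_modal_force(55, dx, pr)
    expect_gt(k, 1e-7)
    expect_lt(k, 1e-5)
    expect_equal(as.numeric(modal_force(bell_state(k, dx), pr)), 55,
                 tolerance = 1e-9)
  }
})
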