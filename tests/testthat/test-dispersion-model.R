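test_that("field context derives the nitrogen Larmor frequency", {
  f <- field_context(600)
  expect_equal(f$nitrogen_larmor_mhz / f$proton_larmor_mhz, 0.10137,
               tolerance = 1e-3)
  expect_error(field_context(-1))
  expect_equal(ppm_to_rad_per_sec(2, field_context(850)),
               2 * 0.10137 * 850 * 2 * pi)
})

test_that("populations sum to one and the labelling convention holds", {
  p <- exchange_parameters(286, 0.942, 2, 15)
  expect_identical(p$p_a + p$p_b, 1)
  expect_error(exchange_parameters(286, 0.4, 2, 15))   # p_a < 0.5
  expect_error(exchange_parameters(-5, 0.9, 2, 15))
  expect_error(exchange_parameters(100, 0.9, 2, -1))
})

test_that("schedules enforce integer pulse counts and invert nu <-> tau", {
  sch <- cpmg_schedule()
  expect_true(all(abs(2 * 0.04 * sch$nu_cpmg_hz - sch$n_pulses) < 1e-9))
  expect_equal(sch$tau_cp_s, 1 / (2 * sch$nu_cpmg_hz))
  expect_equal(range(sch$nu_cpmg_hz), c(25, 1000))
  expect_length(sch$nu_cpmg_hz, 12)
  expect_error(cpmg_schedule(33), "commensurate")
})

test_that("no shift difference or no minor state means no exchange contribution", {
  taus <- 1 / (2 * default_nu_grid())
  f850 <- field_context(850)
  p_dd0 <- exchange_parameters(500, 0.9, 0, 12)
  expect_true(all(abs(carver_richards_r2eff(p_dd0, taus, f850) - 12) < 1e-9))
  p_pb0 <- exchange_parameters(500, 1, 3, 12)
  expect_true(all(abs(carver_richards_r2eff(p_pb0, taus, f850) - 12) < 1e-9))
  # the numerical propagation agrees on the null case exactly
  expect_equal(bloch_mcconnell_r2eff(p_dd0, taus, f850, cpmg_schedule()),
               rep(12, length(taus)), tolerance = 1e-9)
})

test_that("R2eff is symmetric under a sign flip of the shift difference", {
  taus <- 1 / (2 * default_nu_grid())
  f <- field_context(600)
  plus <- carver_richards_r2eff(exchange_parameters(300, 0.95, 2.2, 14),
                                taus, f)
  minus <- carver_richards_r2eff(exchange_parameters(300, 0.95, -2.2, 14),
                                 taus, f)
  expect_equal(plus, minus)
})

test_that("intermediates obey D+ - D- = 1 and eta >= 0 across random draws", {
  set.seed(11)
  tau <- 1 / (2 * default_nu_grid())
  for (i in 1:50) {
    p <- exchange_parameters(runif(1, 10, 5000), runif(1, 0.85, 0.99),
                             runif(1, 0.2, 6), runif(1, 5, 40))
    f <- field_context(sample(c(600, 850), 1))
    ci <- cr_intermediates(p, tau, f)
    expect_equal(ci$d_plus - ci$d_minus, 1, tolerance = 1e-12)
    expect_true(all(ci$eta_plus >= 0) && all(ci$eta_minus >= 0))
  }
})

test_that("dispersion decays monotonically with pulsing frequency", {
  # strictly non-increasing in the intermediate-to-fast regime
  # (k_ex >= delta_omega / 2); in deep slow exchange the closed form
  # carries small bounded oscillations from its cos(eta-) term, but the
  # overall decay from slow to fast pulsing remains
  nu <- seq(25, 2000, by = 12.5)
  taus <- 1 / (2 * nu)
  set.seed(21)
  for (i in 1:20) {
    p <- exchange_parameters(runif(1, 50, 3000), runif(1, 0.85, 0.99),
                             runif(1, 0.5, 4), 15)
    f <- field_context(sample(c(600, 850), 1))
    r2 <- carver_richards_r2eff(p, taus, f)
    if (p$k_ex >= ppm_to_rad_per_sec(p$delta_delta, f) / 2) {
      expect_true(all(diff(r2) <= 1e-9))
    } else {
      expect_lt(max(diff(r2)), 1.5)
      expect_gt(r2[1], r2[length(r2)])
    }
    expect_true(all(r2 >= 15 - 1e-9))  # approaches R2_0 from above
  }
})

test_that("dispersion amplitude does not shrink with field strength", {
  sch <- cpmg_schedule()
  set.seed(31)
  for (i in 1:20) {
    p <- exchange_parameters(runif(1, 50, 3000), runif(1, 0.85, 0.99),
                             runif(1, 0.5, 4), 15)
    expect_gte(rex_amplitude(p, field_context(850), sch) + 1e-9,
               rex_amplitude(p, field_context(600), sch))
  }
  # null cases give exactly zero amplitude
  expect_equal(rex_amplitude(exchange_parameters(300, 1, 2, 15),
                             field_context(850), sch), 0)
  expect_equal(rex_amplitude(exchange_parameters(300, 0.9, 0, 15),
                             field_context(850), sch), 0)
  # and the amplitude is the difference of the closed-form end points
  p <- exchange_parameters(286, 0.942, 2, 15)
  ends <- carver_richards_r2eff(p, 1 / (2 * c(25, 1000)), field_context(850))
  expect_equal(rex_amplitude(p, field_context(850), sch), ends[1] - ends[2])
})

test_that("closed form matches the numerical propagation in a typical regime", {
  p <- exchange_parameters(286, 0.942, 2.0, 15)
  f <- field_context(850)
  tau <- 1 / (2 * 50)
  cr <- carver_richards_r2eff(p, tau, f)
  bm <- bloch_mcconnell_r2eff(p, tau, f, cpmg_schedule())
  expect_equal(cr, bm, tolerance = 0.02)
})

test_that("numerical propagation reaches the fast-exchange limit", {
  # k_ex >> delta_omega: Rex at slow pulsing ~ p_a * p_b * dw^2 / k_ex
  p <- exchange_parameters(5000, 0.9, 1, 15)
  f <- field_context(600)
  dw <- ppm_to_rad_per_sec(1, f)
  rex_limit <- p$p_a * p$p_b * dw^2 / p$k_ex
  bm <- bloch_mcconnell_r2eff(p, 1 / (2 * 25), f, cpmg_schedule())
  expect_equal(bm - 15, rex_limit, tolerance = 0.05)
})

test_that("fast pulsing refocuses the exchange contribution", {
  p <- exchange_parameters(286, 0.942, 2, 15)
  f <- field_context(850)
  nu <- c(250, 500, 1000, 2000, 4000)
  bm <- bloch_mcconnell_r2eff(p, 1 / (2 * nu), f, cpmg_schedule())
  expect_true(all(diff(bm) < 0))          # monotone decay towards R2_0
  expect_true(all(bm > 15))               # from above
  expect_lt(bm[length(bm)] - 15, 0.35)    # close to the plateau
})

test_that("incommensurate pulse spacing is a schedule error", {
  p <- exchange_parameters(286, 0.942, 2, 15)
  expect_error(
    bloch_mcconnell_r2eff(p, 1 / (2 * 33), field_context(850), cpmg_schedule()),
    "commensurate")
})

test_that("extreme exchange parameters stay finite (overflow guard)", {
  p <- exchange_parameters(9e4, 0.6, 10, 50)
  r2 <- carver_richards_r2eff(p, 1 / (2 * c(25, 1000)), field_context(850))
  expect_true(all(is.finite(r2)))
  expect_true(all(r2 >= 0))
})

test_that("closed form and propagation agree over a parameter sweep", {
  # reduced version of the oracle-equivalence sweep (full 200-draw sweep
  # in the acceptance tests); known breakdown corner quarantined:
  # <= 5 refocusing pulses combined with p_b > 0.07
  set.seed(7)
  sch <- cpmg_schedule()
  for (i in 1:40) {
    p <- exchange_parameters(runif(1, 50, 3000), 1 - runif(1, 0.01, 0.15),
                             runif(1, 0.5, 4), runif(1, 12, 20))
    f <- field_context(sample(c(600, 850), 1))
    keep <- sch$n_pulses > 5 | p$p_b <= 0.07
    tau <- sch$tau_cp_s[keep]
    cr <- carver_richards_r2eff(p, tau, f)
    bm <- bloch_mcconnell_r2eff(p, tau, f, sch)
    expect_true(all(abs(cr - bm) <= pmax(0.05 * abs(bm), 0.5)))
  }
})
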