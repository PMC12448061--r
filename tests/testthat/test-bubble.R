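test_that("an undriven bubble stays at its equilibrium radius", {
  m <- medium_properties()
  # ten periods of the 2-um bubble's natural oscillation
  T0_us <- 1 / minnaert_MHz(2e-6, m)
  tr <- simulate_bubble(NULL, R0_nm = 2000, medium = m,
                        t_end_us = 10 * T0_us, dt_out_ns = 10 * T0_us)
  expect_lt(max(abs(tr$R_nm / 2000 - 1)), 1e-6)
})

test_that("small-amplitude forced oscillation matches the linear oscillator", {
  # 1 kPa drive far below resonance: quasi-static linear response
  m <- water()
  R0 <- 5e-6
  f_MHz <- 0.05
  b <- make_burst(f_MHz, 0.001, cycles = 10, prf_Hz = 10)
  tr <- simulate_bubble(b, R0_nm = 5000, medium = m, samples_per_cycle = 256)
  keep <- tr$time_us > 0.5 * max(tr$time_us)
  amp_sim <- (max(tr$R_nm[keep]) - min(tr$R_nm[keep])) / 2 / 5000

  w0_sq <- (2 * pi * minnaert_MHz(R0, m) * 1e6)^2
  w_sq <- (2 * pi * f_MHz * 1e6)^2
  beta <- 2 * m$viscosity / (m$rho * R0^2)
  amp_lin <- 1000 / (m$rho * R0^2 *
    sqrt((w0_sq - w_sq)^2 + (2 * beta * sqrt(w_sq))^2))
  expect_equal(amp_sim, amp_lin, tolerance = 0.05)
})

test_that("ringdown frequency matches Minnaert with surface tension", {
  m <- water()
  for (R0_um in c(1, 5, 10)) {
    f0 <- minnaert_MHz(R0_um * 1e-6, m)
    T0_us <- 1 / f0
    tr <- simulate_bubble(NULL, R0_nm = R0_um * 1000, medium = m,
                          t_end_us = 12 * T0_us, dt_out_ns = T0_us * 5,
                          R_init_nm = R0_um * 1020)
    expect_equal(ringdown_MHz(tr), f0, tolerance = 0.05)
  }
})

test_that("collapse of a near-empty bubble follows the Rayleigh time", {
  # negligible viscosity/surface tension/vapor; effectively incompressible
  m <- medium_properties(viscosity = 1e-6, surface_tension = 1e-9,
                         p_v = 1e-3, c0 = 1e6)
  Rmax_nm <- 1e5  # 100 um
  tc_us <- 0.915 * Rmax_nm * 1e-9 * sqrt(m$rho / m$p_inf) * 1e6
  tr <- simulate_bubble(NULL, R0_nm = Rmax_nm / 200, medium = m,
                        t_end_us = tc_us * 0.9997,
                        dt_out_ns = tc_us * 1000 / 20000,
                        R_init_nm = Rmax_nm)
  t_hit <- tr$time_us[which(tr$R_nm <= 0.05 * Rmax_nm)[1]]
  expect_equal(t_hit, tc_us, tolerance = 0.02)
})

test_that("static rectified-diffusion flux reduces to Epstein-Plesset", {
  m <- medium_properties()
  tr <- simulate_bubble(NULL, R0_nm = 100, medium = m, t_end_us = 1,
                        dt_out_ns = 2)
  fl <- mass_flux(tr, m)
  # an undriven 100-nm bubble in saturated liquid dissolves
  expect_lt(as.numeric(fl), 0)
  expect_equal(as.numeric(fl), epstein_plesset_rate(1e-7, m),
               tolerance = 1e-6)

  # no surface tension, undriven, saturated: no driving gradient
  m0 <- medium_properties(surface_tension = 1e-30)
  tr0 <- simulate_bubble(NULL, R0_nm = 100, medium = m0, t_end_us = 1,
                         dt_out_ns = 2)
  expect_equal(as.numeric(mass_flux(tr0, m0)), 0, tolerance = 1e-15)
})

test_that("a pure drive-frequency oscillation is not period-doubled", {
  t_us <- seq(0, 400, by = 0.0625)  # 100 cycles at 0.25 MHz, 64/cycle
  r <- 1 + 0.3 * sin(2 * pi * 0.25 * t_us)
  tr <- fake_trajectory(t_us, r)
  expect_lt(subharmonic_ratio(tr)$ratio, 0.01)
  # while an alternating-cycle oscillation is
  r2 <- 1 + (0.3 + 0.15 * cos(2 * pi * 0.125 * t_us)) *
    sin(2 * pi * 0.25 * t_us)
  expect_gt(subharmonic_ratio(fake_trajectory(t_us, r2))$ratio, 0.1)
})

test_that("classification refuses a non-periodic drive", {
  m <- medium_properties()
  tr <- simulate_bubble(NULL, R0_nm = 100, medium = m, t_end_us = 1,
                        dt_out_ns = 2)
  expect_error(classify_fate(tr, m), "refused")
})

test_that("fates at the reference parameter combinations", {
  m <- medium_properties()
  fate_of <- function(pnp, fl, ...) {
    d <- put_drive(pnp, fl, cycles = 100)
    classify_fate(simulate_bubble(d, 100, m, ...), m)
  }
  # 0.6 MPa + 100 mJ/cm^2: below threshold, the nucleus dissolves
  expect_identical(fate_of(0.6, 100)$fate, "DISSOLVE")
  # 0.8 MPa + 120 mJ/cm^2: explosive rectified-diffusion growth
  expect_identical(fate_of(0.8, 120)$fate, "GROW")
  # 1.0 MPa + 120 mJ/cm^2: growth into the subharmonic regime
  expect_identical(fate_of(1.0, 120)$fate, "PERIOD_DOUBLED_GROWTH")
})

test_that("fate labels are stable under tolerance refinement", {
  m <- medium_properties()
  for (case in list(c(0.6, 100), c(0.8, 120))) {
    d <- put_drive(case[1], case[2], cycles = 100)
    f1 <- classify_fate(simulate_bubble(d, 100, m, rtol = 1e-6), m,
                        check_period_doubling = FALSE)$fate
    f2 <- classify_fate(simulate_bubble(d, 100, m, rtol = 5e-7), m,
                        check_period_doubling = FALSE)$fate
    expect_identical(f1, f2)
  }
})

test_that("positivity and solver diagnostics are enforced", {
  m <- medium_properties()
  d <- put_drive(1.0, 120, cycles = 20)
  tr <- simulate_bubble(d, 100, m)
  expect_true(all(tr$R_nm > 0))
  expect_error(simulate_bubble(d, -5, m), "positive")
})
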