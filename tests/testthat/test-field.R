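test_that("burst duration and duty cycle follow from cycles and rate", {
  b <- make_burst(0.25, 1, cycles = 500, prf_Hz = 10, time_step_ns = 4)
  expect_equal(b$burst_duration_ms, 2)
  expect_equal(b$duty_cycle, 0.02)
  # amplitude contract: rarefaction reaches -PNP
  expect_equal(min(b$pressure_MPa), -1, tolerance = 1e-6)

  b2 <- make_burst(1, 0.5, cycles = 1, prf_Hz = 1)
  expect_equal(b2$burst_duration_ms, 1e-3)       # 1 us
  expect_equal(b2$duty_cycle, 1e-6)

  # duty cycle over 100%: 500 cycles at 0.25 MHz repeated at 1 kHz
  expect_error(make_burst(0.25, 1, cycles = 500, prf_Hz = 1000), "duty")
})

test_that("duty_cycle * repetition period equals the burst duration", {
  for (cfg in list(c(0.25, 500, 10), c(1, 100, 50), c(0.5, 37, 13))) {
    b <- make_burst(cfg[1], 1, cycles = cfg[2], prf_Hz = cfg[3],
                    time_step_ns = 8)
    expect_equal(b$duty_cycle / cfg[3], b$burst_duration_ms * 1e-3)
  }
})

test_that("synchronization places the PA pulse on a rarefaction peak", {
  b <- make_burst(0.25, 0.6, cycles = 10)
  pa <- pa_waveform(fluence_mJcm2 = 100)

  # zero-amplitude PA leaves the burst untouched
  d0 <- synchronize(b, pa_waveform(fluence_mJcm2 = 0))
  expect_equal(d0$pressure_MPa, b$pressure_MPa)

  # aligned negative lobe: combined PNP ~ burst PNP + PA amplitude
  d <- synchronize(b, pa)
  expect_equal(d$combined_pnp_MPa, 0.6 + pa$peak_MPa, tolerance = 0.02)

  # anti-aligned (half a period later): strictly smaller rarefaction
  half_T <- 0.5e3 / 0.25
  d_anti <- synchronize(b, pa, delay_ns = d$pa_time_ns + half_T)
  expect_lt(d_anti$combined_pnp_MPa, d$combined_pnp_MPa)
  # and the aligned delay maximizes combined PNP over a delay grid
  delays <- d$pa_time_ns + seq(-half_T, half_T, length.out = 21)
  pnps <- vapply(delays, function(dl)
    synchronize(b, pa, dl)$combined_pnp_MPa, numeric(1))
  expect_equal(max(pnps), d$combined_pnp_MPa, tolerance = 1e-6)

  expect_error(synchronize(b, pa, delay_ns = 1e9), "outside")
})

test_that("synchronize is additive in the inserted pulse", {
  b <- make_burst(0.25, 0.6, cycles = 6)
  pa1 <- pa_waveform(fluence_mJcm2 = 50)
  pa2 <- pa_waveform(fluence_mJcm2 = 150)  # 3x the amplitude
  d1 <- synchronize(b, pa1, delay_ns = 9000)
  d2 <- synchronize(b, pa2, delay_ns = 9000)
  add1 <- d1$pressure_MPa - b$pressure_MPa
  add2 <- d2$pressure_MPa - b$pressure_MPa
  expect_equal(add2, 3 * add1, tolerance = 1e-9)
})

test_that("trigger delay maps linearly to synchronization depth", {
  expect_equal(delay_to_depth(500), 0.75)
  expect_equal(delay_to_depth(1500), 2.25)
  expect_identical(delay_to_depth(0), 0)
  d <- delay_to_depth(c(100, 200, 400))
  expect_equal(d[3] / d[1], 4)
  expect_error(delay_to_depth(-5), "non-negative")
})

test_that("delay sweep schedule tiles the session and maps depths", {
  s <- sweep_schedule(0, 500, 60, 240)
  expect_equal(nrow(s), 4)
  expect_equal(s$depth_mm, c(0, 0.75, 1.5, 2.25))
  # windows tile [0, total) without gaps or overlap
  expect_equal(s$t_start_s[-1], s$t_end_s[-nrow(s)])
  expect_equal(s$t_start_s[1], 0)
  expect_equal(s$t_end_s[nrow(s)], 240)

  s0 <- sweep_schedule(100, 0, 60, 240)
  expect_true(all(s0$delay_ns == 100))

  expect_error(sweep_schedule(0, 500, 0, 240), "interval")
})
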