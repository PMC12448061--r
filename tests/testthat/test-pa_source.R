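test_that("fluence follows from pulse energy and beam area", {
  # 80 mJ over a 6 mm beam: the in vivo top-surface exposure
  expect_equal(fluence_from_energy(80, 6), 283, tolerance = 0.01)
  expect_identical(fluence_from_energy(0, 6), 0)
  # attenuated bottom-surface pulse
  expect_equal(fluence_from_energy(16, 6), 56.6, tolerance = 0.005)
  expect_error(fluence_from_energy(10, 0), "beam diameter")
  expect_error(fluence_from_energy(-1, 6), "energy")
})

test_that("initial pressure is Grueneisen * mua * fluence with unit care", {
  ab <- vessel_absorber(mua_per_cm = 10, grueneisen = 0.2)
  expect_identical(initial_pressure(0, ab), 0)
  # dimensional oracle: 0.2 * 10 cm^-1 * 100 mJ/cm^2 = 200 mJ/cm^3
  # = 200 * 1e-3 J / 1e-6 m^3 = 2e5 Pa = 0.2 MPa
  expect_equal(initial_pressure(100, ab), 0.2)
  # linear in fluence
  expect_equal(initial_pressure(2 * 57, ab), 2 * initial_pressure(57, ab))
})

test_that("photoacoustic transient is a fluence-scaled bipolar pulse", {
  ab <- vessel_absorber(diameter_mm = 0.1, sound_speed_mm_us = 1.5)
  w <- pa_waveform(ab, optical_pulse(), fluence_mJcm2 = 100)

  # transit-time width: 0.1 mm / 1.5 mm/us = 66.7 ns
  expect_equal(w$width_ns, 200 / 3, tolerance = 1e-12)
  support <- range(w$time_ns[abs(w$pressure_MPa) > 0.01 * w$peak_MPa])
  expect_gt(diff(support), 0.8 * w$width_ns)

  # peak equals the stress-confined amplitude
  expect_equal(max(abs(w$pressure_MPa)), initial_pressure(100, ab))

  # bipolar: integral is a small fraction of peak x width
  dt <- w$time_ns[2] - w$time_ns[1]
  expect_lt(abs(sum(w$pressure_MPa) * dt), 0.01 * w$peak_MPa * w$width_ns)

  # zero fluence -> silence
  w0 <- pa_waveform(ab, optical_pulse(), fluence_mJcm2 = 0)
  expect_true(all(w0$pressure_MPa == 0))

  expect_error(pa_waveform(ab, optical_pulse(), 100, time_step_ns = 20),
               "coarse")
})

test_that("peak pressure is exactly linear in fluence", {
  ab <- vessel_absorber()
  fl <- c(20, 50, 100, 200)
  peaks <- vapply(fl, function(f)
    max(abs(pa_waveform(ab, optical_pulse(), f)$pressure_MPa)), numeric(1))
  expect_equal(peaks / peaks[1], fl / fl[1], tolerance = 1e-9)
})

test_that("waveform support scales with vessel diameter", {
  widths <- vapply(c(0.05, 0.1, 0.2), function(d) {
    w <- pa_waveform(vessel_absorber(diameter_mm = d), optical_pulse(), 100,
                     time_step_ns = 0.2)
    diff(range(w$time_ns[abs(w$pressure_MPa) > 0.05 * w$peak_MPa]))
  }, numeric(1))
  # smoothing adds a constant ~ laser-pulse width; the increments scale
  expect_equal(widths[3] - widths[2], 2 * (widths[2] - widths[1]),
               tolerance = 0.15)
})

test_that("parameter objects validate their invariants", {
  expect_error(optical_pulse(energy_mJ = -1), "positive")
  expect_error(vessel_absorber(grueneisen = 1.5), "grueneisen")
  expect_error(vessel_absorber(diameter_mm = 0), "diameter")
})
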