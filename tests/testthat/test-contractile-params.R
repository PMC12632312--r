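test_that("parameter formulas match hand arithmetic", {
  expect_equal(amplitude(100, 60), 40)
  expect_equal(amplitude(100, 100), 0)
  expect_equal(amplitude(95.2, 41.7), 53.5)
  expect_equal(normalized_amplitude(100, 60, 100), 40)
  expect_equal(normalized_amplitude(90, 90, 100), 0)
  expect_equal(normalized_amplitude(96, 48, 120), 40)
  expect_equal(ejection_fraction(100, 50), 0.75)
  expect_equal(ejection_fraction(100, 100), 0)
  # strong contractions: EF above 0.8
  expect_equal(ejection_fraction(100, 40), 0.84)
  expect_equal(vessel_tone(100, 100), 0)
  expect_equal(vessel_tone(100, 85), 15)
  expect_equal(vessel_tone(110, 93.5), 15)
  expect_equal(fractional_pump_flow(0.75, 8), 6)
  expect_equal(fractional_pump_flow(0.9, 0), 0)
  expect_equal(fractional_pump_flow(0.84, 14.1), 11.844)
})

test_that("parameter domain errors and the negative-tone warning fire", {
  expect_error(amplitude(60, 100), "exceeds")
  expect_error(amplitude(100, -5), "positive")
  expect_error(normalized_amplitude(100, 60, 0), "DMAX")
  expect_error(ejection_fraction(0, 0), "positive")
  expect_error(vessel_tone(-1, 50), "DMAX")
  expect_error(fractional_pump_flow(1.2, 3), "EF")
  expect_error(fractional_pump_flow(0.5, -1), "FREQ")
  expect_warning(tn <- vessel_tone(100, 104), "negative tone")
  expect_equal(tn, -4)  # flagged, not clipped
})

test_that("step summary reproduces the worked hand example", {
  # 4 uniform events (EDD 100, ESD 60) every 30 s in a 120 s window, DMAX 110
  ev <- events_df(c(10, 40, 70, 100))
  w <- list(step_index = 1, pressure = 3, start_time = 0, end_time = 120)
  s <- summarize_step(ev, w, dmax = 110)
  expect_equal(s$freq, 2)
  expect_equal(s$amp, 40)
  expect_equal(s$norm_amp, 40 / 110 * 100)
  expect_equal(s$ef, 1 - (60 / 100)^2)   # 0.64
  expect_equal(s$tone, 10 / 110 * 100)
  expect_equal(s$fpf, 0.64 * 2)          # 1.28
  expect_equal(s$n_events, 4L)
})

test_that("zero-frequency steps omit amplitude-family parameters", {
  tr <- make_dip_trace(n_dips = 0, total = 120)
  w <- list(step_index = 1, pressure = 3, start_time = 0, end_time = 120)
  s <- summarize_step(events_df(numeric(0)), w, dmax = 100, trace = tr)
  expect_equal(s$freq, 0)
  expect_true(is.na(s$amp) && is.na(s$norm_amp) && is.na(s$ef))
  expect_equal(s$tone, 0)
  expect_equal(s$fpf, 0)
  # tone still computed for a constricted silent vessel
  s2 <- summarize_step(events_df(numeric(0)), w, dmax = 125, trace = tr)
  expect_equal(s2$tone, 20)
  expect_error(summarize_step(events_df(numeric(0)), w, dmax = 100), "trace")
})

test_that("missing passive DMAX for a pressure is a configuration error", {
  ev <- events_df(c(10, 40))
  w <- list(step_index = 1, pressure = 8, start_time = 0, end_time = 120)
  passive <- structure(data.frame(pressure = c(0.5, 3), dmax = c(90, 100)),
                       class = c("passive_diameters", "data.frame"))
  expect_error(summarize_step(ev, w, passive), "DMAX")
  expect_equal(summarize_step(events_df(c(10, 40)),
                              list(pressure = 3, start_time = 0, end_time = 120),
                              passive)$tone, 0)
})

test_that("summary identities hold on every pipeline row", {
  tr <- simulate_vessel("WT", seed = 12)
  pv <- simulate_passive("WT", seed = 13)
  passive <- passive_dmax(pv, default_protocol())
  s <- summarize_trace(tr, default_protocol(), passive)
  ok <- !is.na(s$amp)
  dm <- vapply(s$pressure, function(p) passive$dmax[passive$pressure == p],
               numeric(1))
  expect_equal(s$amp[ok], (s$edd - s$esd)[ok], tolerance = 1e-12)
  expect_equal(s$ef[ok], 1 - (s$esd[ok] / s$edd[ok])^2, tolerance = 1e-12)
  expect_equal(s$norm_amp[ok], s$amp[ok] / dm[ok] * 100, tolerance = 1e-12)
  expect_equal(s$fpf[ok], s$ef[ok] * s$freq[ok], tolerance = 1e-12)
  expect_true(all(s$ef[ok] >= 0 & s$ef[ok] < 1))
})

test_that("parameters are invariant to time-reversal of the event list", {
  ev <- events_df(c(12, 37, 70, 96))
  w <- list(pressure = 3, start_time = 0, end_time = 120)
  rev_ev <- events_df(120 - rev(ev$nadir_time))
  s1 <- summarize_step(ev, w, dmax = 110)
  s2 <- summarize_step(rev_ev, w, dmax = 110)
  expect_equal(s1$freq, s2$freq)
  expect_equal(s1$amp, s2$amp)
  expect_equal(s1$ef, s2$ef)
})

test_that("passive DMAX recovery from Ca2+-free traces", {
  # noiseless: exact plateau values
  pv0 <- simulate_passive("WT", seed = 3, noiseless = TRUE)
  d0 <- passive_dmax(pv0, default_protocol())
  expect_equal(d0$dmax, dmax_curve_at(c(80, 115, 2), d0$pressure),
               tolerance = 1e-10)
  # noisy: recovered within 0.2 um
  pv <- simulate_passive("WT", seed = 4)
  d1 <- passive_dmax(pv, default_protocol())
  expect_equal(d1$dmax, d0$dmax, tolerance = 0.2 / min(d0$dmax))
  # an active trace without the passive flag is refused
  act <- simulate_vessel("WT", seed = 5)
  expect_error(passive_dmax(act, default_protocol()), "is_passive")
  # contractions inside a nominally passive trace warn but do not fail
  contaminated <- pv0$diameter
  for (ct in seq(50, 1200, by = 60)) {
    sel <- abs(pv0$time - ct) <= 1.5
    contaminated[sel] <- contaminated[sel] -
      20 * (1 + cos(2 * pi * (pv0$time[sel] - ct) / 3))
  }
  dip <- diameter_trace(pv0$time, contaminated, pv0$pressure_in,
                        sample_rate = 30, is_passive = TRUE)
  expect_warning(passive_dmax(dip, default_protocol()), "contraction")
})
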