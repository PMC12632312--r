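test_that("frequency derivation reproduces the exact-line case", {
  f <- derive_preset_frequencies(2, 9, 2, 12)
  expect_equal(unname(f), c(2, 3, 5, 7, 11, 12, 12), tolerance = 1e-9)
})

test_that("derived profiles hit their slope and deltaF anchors", {
  f <- derive_preset_frequencies(2.8, 12.1, 2, 20)
  dat <- data.frame(pressure = preset_pressures(), freq = unname(f))
  refit <- fit_fp(dat)
  expect_equal(refit$slope, 2.8, tolerance = 1e-6)
  expect_equal(delta_f(dat), 12.1, tolerance = 1e-6)
  expect_equal(unname(f[1]), 2)
  expect_equal(unname(f[7]), 20)
  expect_true(all(diff(unname(f)[1:5]) >= -1e-9))  # monotone up to 5 cmH2O
  expect_true(all(unname(f)[5] <= unname(f)[6:7] + 1e-9))
})

test_that("infeasible anchor combinations raise explicit errors", {
  # deltaF far below what a monotone near-linear profile with this slope allows
  expect_error(derive_preset_frequencies(5, 1, 2, 20), "non-monotone")
  expect_error(derive_preset_frequencies(2, -1, 2, 20), "non-negative")
  # f(5) above the plateau anchor
  expect_error(derive_preset_frequencies(2.8, 12.6, 2, 10), "plateau")
  expect_error(derive_preset_frequencies(2, 9, -2, 20), "non-negative")
})

test_that("the registry presets are self-consistent with their anchors", {
  declared <- c(WT = 2.8, WT_Ani9 = 0.3, Ano1_smKO = 0.4, Ano1_ff = 2.8,
                Itpr1_smKO = 0.6, Itpr1_ff = 2.6, Trpv4_KO = 2.7)
  reg <- preset_registry()
  expect_setequal(names(reg), names(declared))
  for (nm in names(declared)) {
    f <- reg[[nm]]$freq_by_pressure
    refit <- fit_fp(data.frame(pressure = preset_pressures(), freq = unname(f)))
    expect_equal(refit$slope, unname(declared[nm]), tolerance = 1e-6,
                 label = paste(nm, "slope"))
  }
  # Ano1 smKO: frequency below 3 min^-1 at every pressure
  expect_lt(max(reg$Ano1_smKO$freq_by_pressure), 3)
  # WT spans the canonical 2 -> 20 min^-1 dynamic range
  expect_equal(unname(reg$WT$freq_by_pressure[c(1, 7)]), c(2, 20))
})

test_that("preset validation rejects impossible geometry", {
  expect_error(genotype_preset("bad", rep(2, 7), amp_by_pressure = 120,
                               tone_by_pressure = 10),
               "end-systolic")
  expect_error(genotype_preset("bad", rep(-1, 7), 40, 10), ">= 0")
  expect_error(genotype_preset("bad", rep(2, 7), 40, 110), "tone")
  expect_error(genotype_preset("bad", rep(2, 7), 40, 10, interval_cv = 0),
               "positive")
})

test_that("simulation is bit-reproducible under a fixed seed", {
  a <- simulate_vessel("WT_Ani9", seed = 101)
  b <- simulate_vessel("WT_Ani9", seed = 101)
  expect_identical(a$diameter, b$diameter)
  expect_identical(attr(a, "truth"), attr(b, "truth"))
  c <- simulate_vessel("WT_Ani9", seed = 102)
  expect_false(identical(a$diameter, c$diameter))
  # cohorts too
  e1 <- simulate_experiment("Ano1_smKO", 2, seed = 7)
  e2 <- simulate_experiment("Ano1_smKO", 2, seed = 7)
  expect_identical(e1$traces[[1]]$diameter, e2$traces[[1]]$diameter)
  expect_identical(e1$passive$diameter, e2$passive$diameter)
})

test_that("passive simulation follows the DMAX curve with no contractions", {
  expect_equal(dmax_curve_at(c(80, 115, 2), 4), 80 + 35 * 4 / 6)
  pv <- simulate_passive("WT", seed = 21, noiseless = TRUE)
  expect_true(attr(pv, "is_passive"))
  # piecewise-constant exactly at DMAX(P)
  prot <- default_protocol()
  w <- protocol_windows(prot, settle = 0)
  for (s in seq_len(nrow(w))) {
    sel <- pv$time >= w$start_time[s] & pv$time < w$end_time[s]
    expect_equal(unique(pv$diameter[sel]),
                 dmax_curve_at(c(80, 115, 2), w$pressure[s]),
                 tolerance = 1e-12)
  }
  ev <- detect_contractions(pv, w[8, ])
  expect_equal(nrow(ev), 0)
})

test_that("a preset with zero frequency everywhere yields a silent trace", {
  silent <- genotype_preset("silent", rep(0, 7), 40, 10)
  tr <- simulate_vessel(silent, seed = 31)
  windows <- segment_by_protocol(tr, default_protocol())
  n_ev <- sum(vapply(seq_len(nrow(windows)), function(s) {
    nrow(detect_contractions(tr, windows[s, ]))
  }, numeric(1)))
  expect_equal(n_ev, 0)
  expect_equal(nrow(attr(tr, "truth")), 0)
})

test_that("inter-contraction intervals have the prescribed mean and CV", {
  # pool intervals from many event-level draws at 5 and 10 cmH2O
  prot <- pressure_protocol(c(5, 10), c(600, 600))
  wt <- preset_registry()$WT
  ivs <- list(`5` = numeric(0), `10` = numeric(0))
  for (s in 1:10) {
    ev <- simulate_events(wt, prot, seed = 400 + s)
    for (p in c(5, 10)) {
      ivs[[as.character(p)]] <- c(ivs[[as.character(p)]],
                                  diff(ev$nadir_time[ev$pressure == p]))
    }
  }
  for (p in c(5, 10)) {
    iv <- ivs[[as.character(p)]]
    expect_gt(length(iv), 1000)
    f <- unname(wt$freq_by_pressure[as.character(p) == names(wt$freq_by_pressure)])
    m <- 60 / f
    # LLN: sample mean within 2 SEM of the preset mean interval
    expect_lt(abs(mean(iv) - m), 2 * sd(iv) / sqrt(length(iv)) + 1e-9)
    # CV within 10% of the preset value
    expect_lt(abs(sd(iv) / mean(iv) - wt$interval_cv), 0.1 * wt$interval_cv)
  }
})

test_that("count-based event rates converge to preset frequencies", {
  # 50 event-level vessels: events per analysis window at 3 and 5 cmH2O
  wt <- preset_registry()$WT
  windows <- protocol_windows(default_protocol(), settle = 20)
  rates <- sapply(1:50, function(s) {
    ev <- simulate_events(wt, seed = 900 + s)
    vapply(c(6, 8), function(i) {  # steps at 5 and 10 cmH2O
      w <- windows[i, ]
      sum(ev$step_index == i & ev$nadir_time >= w$start_time &
            ev$nadir_time < w$end_time) /
        ((w$end_time - w$start_time) / 60)
    }, numeric(1))
  })
  f5 <- unname(wt$freq_by_pressure["5"])
  f10 <- unname(wt$freq_by_pressure["10"])
  expect_lt(abs(mean(rates[1, ]) - f5), 0.05 * f5)
  expect_lt(abs(mean(rates[2, ]) - f10), 0.05 * f10)
})

test_that("the ground-truth event layer matches the rendered waveform layer", {
  # same per-vessel seed => simulate_events reproduces the trace's truth table
  seeds <- withr::with_seed(5, sample.int(.Machine$integer.max - 1L, 3L))
  tr <- simulate_vessel("WT", seed = seeds[1])
  ev <- simulate_events("WT", seed = seeds[1])
  expect_equal(ev$nadir_time, attr(tr, "truth")$nadir_time, tolerance = 1e-12)
})
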