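wt <- load_preset("wt")

test_that("gate steady states sit at the Boltzmann midpoints and saturate", {
  ss <- gate_steady_state(wt, wt$act_v_half)
  expect_equal(ss$a_inf, 0.5)
  expect_gt(gate_steady_state(wt, 200)$a_inf, 0.999)
  # availability midpoint: halfway between floor and 1 at the reference kex
  ss2 <- gate_steady_state(wt, wt$inact_v_half_ref)
  expect_equal(ss2$h_inf, wt$inact_floor + (1 - wt$inact_floor) / 2)
  # raising bath K+ destabilizes inactivation (shifts availability up)
  v <- seq(-60, 0, 5)
  h2 <- gate_steady_state(wt, v, solution_spec(kex = 2))$h_inf
  h8 <- gate_steady_state(wt, v, solution_spec(kex = 8))$h_inf
  expect_true(all(h8 >= h2))
})

test_that("a null channel with no leak or noise produces identically zero current", {
  null <- wt
  null$g0 <- 0
  ts <- simulate_protocol(null, amplitude_protocol(), noise = noise_free())
  expect_true(all(as.data.frame(ts)$current_uA == 0))
})

test_that("simulated step currents match the independent closed-form oracle", {
  segs <- list(list(v = -80, ms = 100), list(v = 50, ms = 200))
  for (name in c("wt", "e675k", "m77i_tbk1i")) {
    p <- load_preset(name)
    ts <- simulate_protocol(p, amplitude_protocol(), noise = noise_free())
    got <- ts$sweeps[[1]]$current_uA
    want <- oracle_step_current(unclass(p), segs)
    expect_equal(got, want, tolerance = 1e-6)
  }
  # multi-segment sweep with a hyperpolarized recovery gap
  rec_segs <- list(list(v = -80, ms = 100), list(v = 50, ms = 200),
                   list(v = -80, ms = 520), list(v = 50, ms = 200))
  prot <- voltage_protocol("twin", list(protocol_sweep(
    list(voltage_segment(100, -80, "hold"), voltage_segment(200, 50, "test"),
         voltage_segment(520, -80, "recovery"),
         voltage_segment(200, 50, "test2")), label_voltage = 50)),
    inter_sweep_ms = 0)
  ts <- simulate_protocol(wt, prot, noise = noise_free())
  expect_equal(ts$sweeps[[1]]$current_uA,
               oracle_step_current(unclass(wt), rec_segs), tolerance = 1e-6)
})

test_that("implied open probability stays within [0, 1] across protocols", {
  for (prot in list(iv_protocol(sampling_khz = 2), gv_protocol(8, sampling_khz = 2),
                    recovery_protocol(sampling_khz = 1))) {
    ts <- simulate_protocol(wt, prot, solution_spec(kex = 8),
                            noise = noise_free())
    po <- implied_open_prob(ts, wt)
    expect_true(all(po >= -1e-12 & po <= 1 + 1e-12))
  }
})

test_that("E675K scales wild-type peaks by 0.70 under matched settings", {
  # the conductance scale is exactly 0.7x; the measured peak ratio deviates
  # by < 0.5% because the variant's destabilized availability floor slightly
  # changes how much inactivation accrues before the peak
  ek <- load_preset("e675k")
  for (prot in list(amplitude_protocol(), iv_protocol(sampling_khz = 2))) {
    for (i in seq_along(prot$sweeps)) {
      pw <- extract_features(simulate_protocol(wt, prot, noise = noise_free()), i)$peak
      pe <- extract_features(simulate_protocol(ek, prot, noise = noise_free()), i)$peak
      if (abs(pw) > 1e-9) expect_equal(pe / pw, 0.7, tolerance = 5e-3)
    }
  }
})

test_that("preset mixtures follow independent and dominant-negative arithmetic", {
  ek <- load_preset("e675k"); dn <- load_preset("r420h")
  expect_equal(mix_presets(list(wt), 1)$g0, wt$g0)
  expect_warning(m <- mix_presets(list(wt, ek), c(0.5, 0.5), "independent"),
                 "differ beyond g0")
  expect_equal(m$g0, 0.85 * wt$g0)
  m2 <- mix_presets(list(wt, dn), c(0.5, 0.5), "binomial_dn")
  expect_equal(m2$g0, 0.0625 * wt$g0)
  expect_error(mix_presets(list(wt, ek), c(0.6, 0.5)),
               class = "kv_invalid_mixture")
})

test_that("batches are reproducible and scatter matches the requested CV", {
  prot <- amplitude_protocol(sampling_khz = 1)
  b0 <- make_batch(wt, prot, n_oocytes = 3, noise = noise_free())
  expect_identical(b0[[1]]$sweeps, b0[[2]]$sweeps)
  ns <- noise_spec(current_sd = 0.01, expression_cv = 0.2, seed = 11L)
  b1 <- make_batch(wt, prot, n_oocytes = 3, noise = ns)
  b2 <- make_batch(wt, prot, n_oocytes = 3, noise = ns)
  expect_identical(b1, b2)
  # growing the batch must not reshuffle earlier oocytes
  b3 <- make_batch(wt, prot, n_oocytes = 5, noise = ns)
  expect_identical(b1[[2]]$sweeps, b3[[2]]$sweeps)

  big <- make_batch(wt, prot, n_oocytes = 200,
                    noise = noise_spec(current_sd = 0, expression_cv = 0.3,
                                       seed = 5L))
  peaks <- vapply(big, function(ts) extract_features(ts)$peak, numeric(1))
  expect_equal(sd(peaks) / mean(peaks), 0.3, tolerance = 0.05)
})

test_that("peak outward current grows monotonically with bath K+", {
  prot <- step_protocol(40, 200, sampling_khz = 2)
  peaks <- vapply(c(1, 2, 4, 8), function(k)
    extract_features(simulate_protocol(wt, prot, solution_spec(kex = k),
                                       noise = noise_free()))$peak, numeric(1))
  expect_true(all(diff(peaks) > 0))
})

test_that("an infinitely rested train degenerates to identical pulses", {
  prot <- train_protocol(50, total_s = 0.5, sampling_khz = 10)
  prot$inter_sweep_ms <- 1e7
  prot$interval_dialect <- "gap"
  ts <- simulate_protocol(wt, prot, noise = noise_free(), carry_state = TRUE)
  res <- cumulative_inactivation(ts)
  expect_equal(res$relative_current_10s, 1, tolerance = 1e-6)
  expect_lt(diff(range(res$points$y)), 1e-6)
})
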