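wt <- load_preset("wt")

test_that("GV and inactivation curves honour their normalization contracts", {
  ts <- simulate_protocol(wt, gv_protocol(2), noise = noise_free())
  gv <- gv_curve(ts)
  expect_equal(max(gv$y), 1)
  ti <- simulate_protocol(wt, inactivation_protocol(sampling_khz = 5),
                          noise = noise_free())
  ic <- inactivation_curve(ti)
  expect_equal(max(ic$y), 1)
  # most hyperpolarized conditioning leaves the channel fully available
  expect_equal(ic$y[ic$v == -100], 1, tolerance = 1e-6)

  null <- wt; null$g0 <- 0
  tn <- simulate_protocol(null, gv_protocol(2), noise = noise_free())
  expect_error(gv_curve(tn), class = "kv_degenerate_trace")
})

test_that("noise-free GV pipeline recovers the activation midpoint", {
  ts <- simulate_protocol(wt, gv_protocol(2), noise = noise_free())
  gv <- gv_curve(ts)
  f <- fit_boltzmann(gv$v, gv$y, "activation")
  expect_lt(abs(f$v_half - wt$act_v_half), 0.5)
})

test_that("forced-short construct shifts the fitted GV by +5 mV", {
  vh <- vapply(c("wt", "m1i"), function(nm) {
    ts <- simulate_protocol(load_preset(nm), gv_protocol(2),
                            noise = noise_free())
    gv <- gv_curve(ts)
    fit_boltzmann(gv$v, gv$y, "activation")$v_half
  }, numeric(1))
  expect_lt(abs((vh[["m1i"]] - vh[["wt"]]) - 5), 0.5)
})

test_that("inactivation midpoint is recovered and shifts rightward with K+", {
  ti <- simulate_protocol(wt, inactivation_protocol(sampling_khz = 5),
                          noise = noise_free())
  ic <- inactivation_curve(ti)
  f <- fit_boltzmann(ic$v, ic$y, "inactivation")
  expect_lt(abs(f$v_half - wt$inact_v_half_ref), 1)

  ek <- load_preset("e675k")
  vh <- vapply(c(2, 8), function(k) {
    ts <- simulate_protocol(ek, inactivation_protocol(sampling_khz = 5),
                            solution_spec(kex = k), noise = noise_free())
    ic <- inactivation_curve(ts)
    fit_boltzmann(ic$v, ic$y, "inactivation")$v_half
  }, numeric(1))
  expect_gt(vh[2], vh[1])
})

test_that("recovery curves rise monotonically to 1 and recover tau_rec", {
  ts <- simulate_protocol(wt, recovery_protocol(sampling_khz = 1),
                          noise = noise_free())
  rc <- recovery_curve(ts)
  expect_true(all(diff(rc$y) > 0))
  expect_true(all(rc$y >= -0.05 & rc$y <= 1.05))
  expect_equal(rc$y[nrow(rc)], 1, tolerance = 0.01)
  f <- fit_monoexp(rc$delta_t, rc$y, "rising")
  expect_equal(f$tau1, wt$tau_rec_ref, tolerance = 0.05)
})

test_that("cumulative inactivation orders by frequency, construct and K+", {
  run_train <- function(preset, freq, kex = 2) {
    prot <- train_protocol(freq, total_s = 10, sampling_khz = 5)
    cumulative_inactivation(
      simulate_protocol(preset, prot, solution_spec(kex = kex),
                        noise = noise_free(), carry_state = TRUE))
  }
  ek <- load_preset("e675k")
  rel_wt <- vapply(c(1, 10, 50, 100), function(f)
    run_train(wt, f)$relative_current_10s, numeric(1))
  rel_ek <- vapply(c(1, 10, 50, 100), function(f)
    run_train(ek, f)$relative_current_10s, numeric(1))
  # deeper accumulation at higher frequency
  expect_true(all(diff(rel_wt) < 0))
  expect_true(all(diff(rel_ek) < 0))
  # the variant accumulates more at 10 Hz and above
  expect_true(all(rel_ek[-1] < rel_wt[-1]))
  # raising bath K+ attenuates cumulative inactivation (50 Hz)
  rel_kex <- vapply(c(1, 2, 4, 8), function(k)
    run_train(wt, 50, k)$relative_current_10s, numeric(1))
  expect_true(all(diff(rel_kex) > 0))
  # 1 Hz has too few pulses inside 2 s for a time constant
  r1 <- run_train(wt, 1)
  expect_true(is.na(r1$tau_first_2s))
  expect_true(any(grepl("not_estimable", r1$flags)))
  # self-consistency of the 2 s time constant at 50 Hz
  r50 <- run_train(wt, 50)
  w <- r50$points$t_ms <= 2000
  refit <- fit_monoexp(r50$points$t_ms[w], r50$points$y[w], "decaying")
  expect_equal(r50$tau_first_2s, refit$tau1, tolerance = 1e-9)
})

test_that("noisy replicate V1/2 estimates are unbiased within 2 sem", {
  est <- vapply(1:12, function(r) {
    batch <- make_batch(wt, gv_protocol(2, sampling_khz = 2),
                        n_oocytes = 10,
                        noise = noise_spec(current_sd = 0.05,
                                           expression_cv = 0.2,
                                           seed = 1000L + r))
    cv <- average_curves(lapply(batch, gv_curve))
    fit_boltzmann(cv$v, cv$y, "activation")$v_half
  }, numeric(1))
  sem <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - wt$act_v_half), 2 * sem + 0.1)
})
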