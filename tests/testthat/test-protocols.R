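test_that("IV protocol matches the published step family", {
  p <- iv_protocol()
  expect_length(p$sweeps, 8)
  lv <- vapply(p$sweeps, `[[`, numeric(1), "label_voltage")
  expect_equal(lv, seq(-60, 80, 20))
  for (sw in p$sweeps) {
    test_seg <- Filter(function(s) s$role == "test", sw$segments)[[1]]
    expect_equal(test_seg$ms, 500)
  }
  expect_equal(p$inter_sweep_ms, 7000)
})

test_that("GV protocol selects the K+-adjusted tail voltage", {
  expect_equal(tail_voltage_for_kex(1), -25)
  expect_equal(tail_voltage_for_kex(8), -15)
  expect_equal(tail_voltage_for_kex(98), -40)
  expect_equal(tail_voltage_for_kex(2), -40)
  expect_error(tail_voltage_for_kex(-1), class = "kv_invalid_solution")

  for (kex in c(1, 2, 8, 98)) {
    p <- gv_protocol(kex)
    expect_length(p$sweeps, 14)
    expect_equal(vapply(p$sweeps, `[[`, numeric(1), "label_voltage"),
                 seq(-70, 60, 10))
    for (sw in p$sweeps) {
      tail_seg <- Filter(function(s) s$role == "tail", sw$segments)[[1]]
      expect_equal(tail_seg$mV, tail_voltage_for_kex(kex))
      expect_equal(tail_seg$ms, 400)
      expect_equal(Filter(function(s) s$role == "test", sw$segments)[[1]]$ms, 25)
    }
  }
})

test_that("inactivation protocol uses 1 s (or 10 s) conditioning and a +50 mV test", {
  for (long in c(FALSE, TRUE)) {
    p <- inactivation_protocol(long_steps = long)
    expect_length(p$sweeps, 14)
    expect_equal(vapply(p$sweeps, `[[`, numeric(1), "label_voltage"),
                 seq(-100, 30, 10))
    for (sw in p$sweeps) {
      cond <- Filter(function(s) s$role == "cond", sw$segments)[[1]]
      test <- Filter(function(s) s$role == "test", sw$segments)[[1]]
      expect_equal(cond$ms, if (long) 10000 else 1000)
      expect_equal(test$mV, 50)
      expect_equal(test$ms, 400)
    }
    expect_equal(p$inter_sweep_ms, 10000)
  }
})

test_that("recovery protocol has 17 sweeps with 20 ms + 500 ms increments", {
  p <- recovery_protocol()
  expect_length(p$sweeps, 17)
  dts <- vapply(p$sweeps, `[[`, numeric(1), "recovery_ms")
  expect_equal(dts[1], 20)
  expect_equal(dts[17], 8020)
  expect_equal(unique(diff(dts)), 500)
  expect_equal(p$inter_sweep_ms, 30000)
  for (sw in p$sweeps) {
    pulses <- Filter(function(s) s$role %in% c("test", "test2"), sw$segments)
    expect_length(pulses, 2)
    expect_true(all(vapply(pulses, `[[`, numeric(1), "mV") == 50))
    expect_true(all(vapply(pulses, `[[`, numeric(1), "ms") == 200))
  }
})

test_that("amplitude protocol is a single 200 ms step to +50 mV", {
  p <- amplitude_protocol()
  expect_length(p$sweeps, 1)
  test <- Filter(function(s) s$role == "test", p$sweeps[[1]]$segments)[[1]]
  expect_equal(test$mV, 50)
  expect_equal(test$ms, 200)
})

test_that("train protocol period and pulse count follow the frequency", {
  p50 <- train_protocol(50, total_s = 10)
  expect_equal(p50$inter_sweep_ms, 20)
  expect_identical(p50$interval_dialect, "period")
  p10 <- train_protocol(10, total_s = 10)
  expect_length(p10$sweeps, 100)
  expect_error(train_protocol(250, 10), class = "kv_infeasible_frequency")
  # pulse count = floor(total * frequency) for any feasible frequency
  for (f in c(1, 10, 50, 100, 7)) {
    for (tot in c(2.5, 10)) {
      expect_length(train_protocol(f, tot)$sweeps, floor(tot * f))
    }
  }
})

test_that("all six builders hold at -80 mV before the first step", {
  builders <- list(iv_protocol(), gv_protocol(2), inactivation_protocol(),
                   recovery_protocol(), amplitude_protocol(),
                   train_protocol(10, 2))
  for (p in builders) {
    expect_equal(p$holding_mV, -80)
    expect_equal(p$sweeps[[1]]$segments[[1]]$mV, -80)
  }
})

test_that("protocol JSON serialization round-trips field-by-field", {
  tmp <- withr::local_tempfile(fileext = ".json")
  for (p in list(iv_protocol(), gv_protocol(8), recovery_protocol(),
                 train_protocol(50, 1))) {
    write_protocol(p, tmp)
    expect_equal(read_protocol(tmp), p)
  }
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"name": "x"}', bad)
  expect_error(read_protocol(bad), class = "kv_schema_violation")
})

test_that("segment and protocol validation rejects malformed input", {
  expect_error(voltage_segment(-1, 0), class = "kv_invalid_protocol")
  expect_error(voltage_segment(10, 200), class = "kv_invalid_protocol")
  expect_error(protocol_sweep(list(voltage_segment(10, 0)), label_voltage = 30),
               class = "kv_invalid_protocol")
  expect_error(voltage_protocol("x", list(), 0), class = "kv_invalid_protocol")
})
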