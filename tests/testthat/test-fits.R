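test_that("mono-exponential fit recovers exact generating parameters", {
  x <- seq(0, 8000, by = 40)
  f <- fit_monoexp(x, 1 - exp(-x / 800), direction = "rising")
  expect_equal(f$tau1, 800, tolerance = 1e-6)
  expect_equal(f$offset, 1, tolerance = 1e-6)

  g <- fit_monoexp(x, 0.2 + 0.8 * exp(-x / 1500), direction = "decaying")
  expect_equal(g$tau1, 1500, tolerance = 1e-6)
  expect_equal(g$offset, 0.2, tolerance = 1e-6)

  expect_error(fit_monoexp(x, rep(1, length(x))), class = "kv_fit_failure")
  expect_error(fit_monoexp(1:3, 1:3), class = "kv_fit_failure")
})

test_that("bi-exponential fit recovers reported-style generating constants", {
  x <- seq(0, 900, by = 0.5)
  # slow/fast constants and amplitude fraction of the TBK1-inhibitor fits
  y1 <- 0.3 * exp(-x / 144) + 0.7 * exp(-x / 50)
  f1 <- fit_biexp(x, y1)
  expect_equal(f1$tau1, 144, tolerance = 0.01)
  expect_equal(f1$tau2, 50, tolerance = 0.01)
  expect_equal(f1$a1_fraction, 0.3, tolerance = 0.01)

  y2 <- 0.3 * exp(-x / 136) + 0.7 * exp(-x / 43)
  f2 <- fit_biexp(x, y2)
  expect_equal(f2$tau1, 136, tolerance = 0.01)
  expect_equal(f2$tau2, 43, tolerance = 0.01)

  # with an offset
  f3 <- fit_biexp(x, 0.4 + 0.25 * exp(-x / 300) + 0.6 * exp(-x / 60))
  expect_equal(f3$tau1, 300, tolerance = 0.01)
  expect_equal(f3$tau2, 60, tolerance = 0.01)
  expect_equal(f3$offset, 0.4, tolerance = 0.01)
})

test_that("bi-exponential fit flags the degenerate mono-exponential limit", {
  x <- seq(0, 900, by = 1)
  f <- fit_biexp(x, exp(-x / 120))
  # one component must carry the full amplitude at the right time constant
  dom <- if (f$a1_fraction > 0.5) f$tau1 else f$tau2
  expect_equal(dom, 120, tolerance = 0.02)
  expect_true(length(f$flags) > 0)
})

test_that("bi-exponential fit agrees with the brute-force grid oracle", {
  x <- seq(0, 1000, by = 2)
  cases <- list(c(tau1 = 144, tau2 = 50, w = 0.3, off = 0.45),
                c(tau1 = 400, tau2 = 150, w = 0.4, off = 0.1),
                c(tau1 = 250, tau2 = 30, w = 0.6, off = 0))
  for (cs in cases) {
    y <- cs[["off"]] + cs[["w"]] * exp(-x / cs[["tau1"]]) +
      (1 - cs[["w"]]) * exp(-x / cs[["tau2"]])
    f <- fit_biexp(x, y)
    o <- oracle_biexp(x, y)
    expect_equal(f$tau1, o$tau1, tolerance = 0.01)
    expect_equal(f$tau2, o$tau2, tolerance = 0.01)
    expect_equal(f$a1_fraction, o$a1_fraction, tolerance = 0.01)
  }
})

test_that("Boltzmann fits recover exact activation and inactivation curves", {
  v <- seq(-70, 60, 10)
  f <- fit_boltzmann(v, 1 / (1 + exp((-5 - v) / 8)), "activation")
  expect_equal(f$v_half, -5, tolerance = 1e-4)
  expect_equal(f$k, 8, tolerance = 1e-4)
  # midpoint identity
  expect_equal(predict(f, f$v_half), 0.5, tolerance = 1e-9)

  vi <- seq(-100, 30, 10)
  yi <- 0.1 + 0.9 / (1 + exp((vi + 30) / 6))
  fi <- fit_boltzmann(vi, yi, "inactivation")
  expect_equal(fi$v_half, -30, tolerance = 1e-4)
  expect_equal(fi$k, 6, tolerance = 1e-4)
  expect_equal(fi$base, 0.1, tolerance = 1e-4)

  expect_error(fit_boltzmann(v, rep(0.5, length(v)), "activation"),
               class = "kv_fit_failure")
})
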