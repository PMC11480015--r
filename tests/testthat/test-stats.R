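test_that("batch normalization maps the reference mean to 1", {
  d <- data.frame(construct = c("wt", "wt", "mut"), value = c(2, 4, 1.8))
  out <- normalize_batch(d, "wt")
  expect_equal(out$normalized, c(2 / 3, 4 / 3, 0.6))
  expect_equal(mean(out$normalized[out$construct == "wt"]), 1)
  # reference-only batch averages to exactly 1
  solo <- normalize_batch(data.frame(construct = "wt", value = c(1, 5, 9)), "wt")
  expect_equal(mean(solo$normalized), 1)
  expect_error(normalize_batch(d, "absent"), class = "kv_missing_reference")

  # batch-wise: each batch normalized by its own reference mean
  d2 <- data.frame(construct = rep(c("wt", "mut"), 2), value = c(2, 1, 20, 10),
                   batch = c(1, 1, 2, 2))
  out2 <- normalize_batch(d2, "wt")
  expect_equal(out2$normalized[out2$construct == "mut"], c(0.5, 0.5))
})

test_that("pooled normalized amplitudes recover a 0.7 mutant scale", {
  wt <- load_preset("wt"); ek <- load_preset("e675k")
  prot <- amplitude_protocol(sampling_khz = 1)
  rows <- do.call(rbind, lapply(1:3, function(b) {
    ns <- noise_spec(current_sd = 0.02, expression_cv = 0.2,
                     seed = 100L * b)
    peaks_wt <- vapply(make_batch(wt, prot, n_oocytes = 20, noise = ns),
                       function(ts) extract_features(ts)$peak, numeric(1))
    ns2 <- noise_spec(current_sd = 0.02, expression_cv = 0.2,
                      seed = 100L * b + 50L)
    peaks_ek <- vapply(make_batch(ek, prot, n_oocytes = 20, noise = ns2),
                       function(ts) extract_features(ts)$peak, numeric(1))
    data.frame(construct = rep(c("wt", "e675k"), each = 20),
               value = c(peaks_wt, peaks_ek), batch = b)
  }))
  out <- normalize_batch(rows, "wt")
  expect_equal(mean(out$normalized[out$construct == "e675k"]), 0.70,
               tolerance = 0.05)
})

test_that("group summaries report mean, sem and Welch-test stars", {
  s <- summarize_groups(c(1, 1, 1, 1), c(1, 1, 1, 1))
  expect_equal(s$sem, 0)
  expect_equal(s$p_value, 1)
  expect_equal(s$stars, "n.s.")

  set.seed(3)
  a <- rnorm(10)
  s2 <- summarize_groups(a, a + 10 * sd(a))
  expect_equal(s2$stars, "***")
  expect_error(summarize_groups(1), class = "kv_insufficient_data")

  expect_equal(significance_stars(c(0.2, 0.04, 0.009, 5e-4)),
               c("n.s.", "*", "**", "***"))
})

test_that("the Welch comparison is calibrated at the nominal 5% level", {
  set.seed(42)
  rejections <- mean(vapply(1:1000, function(i) {
    x <- rnorm(8); y <- rnorm(8)
    summarize_groups(x, y)$p_value < 0.05
  }, logical(1)))
  expect_gte(rejections, 0.03)
  expect_lte(rejections, 0.07)
})
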