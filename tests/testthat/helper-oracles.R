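# Independent oracles used to cross-check the package implementation.
# These deliberately re-derive everything from first principles and share no
# code with the package internals.

# closed-form gate trajectory for a piecewise-constant voltage sequence:
# returns current samples for one sweep of `segments` = list(list(v, ms)),
# starting from steady state at the first segment's voltage
oracle_step_current <- function(par, segments, kex = 2, kin = 108.6,
                                temp = 295.15, khz = 10) {
  Fc <- 96485.332; Rg <- 8.314462
  ghk <- function(v) {
    u <- (v / 1000) * Fc / (Rg * temp)
    if (abs(u) < 1e-6) kin - kex else u * (kin - kex * exp(-u)) / (1 - exp(-u))
  }
  ivh <- par$inact_v_half_ref + par$k_shift_delta * log2(kex / 2)
  ainf <- function(v) 1 / (1 + exp((par$act_v_half - v) / par$act_k))
  hinf <- function(v) par$inact_floor + (1 - par$inact_floor) /
    (1 + exp((v - ivh) / par$inact_k))
  trec <- par$tau_rec_ref * (2 / kex)^par$k_rec_gamma
  gain <- 1 + par$k_gain_alpha * log(kex / 2)
  v0 <- segments[[1]]$v
  a <- ainf(v0); h1 <- hinf(v0); h2 <- hinf(v0)
  out <- numeric(0)
  for (sg in segments) {
    v <- sg$v
    ta <- if (v <= -40) par$tau_deact else par$tau_act
    th1 <- if (v <= -40) trec else par$tau_inact_1
    th2 <- if (v <= -40) trec else par$tau_inact_2
    tt <- (1 / khz) * seq_len(round(sg$ms * khz))
    at <- ainf(v) + (a - ainf(v)) * exp(-tt / ta)
    h1t <- hinf(v) + (h1 - hinf(v)) * exp(-tt / th1)
    h2t <- hinf(v) + (h2 - hinf(v)) * exp(-tt / th2)
    po <- at * (par$persistent_frac + (1 - par$persistent_frac) *
                  (par$a1_frac * h1t + (1 - par$a1_frac) * h2t))
    out <- c(out, par$g0 * gain * po * ghk(v))
    a <- at[length(tt)]; h1 <- h1t[length(tt)]; h2 <- h2t[length(tt)]
  }
  out
}

# printed-form GHK current-ratio, evaluated symbol by symbol
oracle_ghk_ratio <- function(c1, c2, vm, kin = 108.6, temp = 295.15) {
  Fc <- 96485.332; Rg <- 8.314462
  e <- exp(-(vm / 1000) * Fc / (Rg * temp))
  (kin - c1 * e) / (kin - c2 * e)
}

# brute-force bi-exponential fit: coarse log grid over the two time
# constants with a linear least-squares solve for offset and amplitudes,
# then one local refinement pass
oracle_biexp <- function(x, y) {
  solve_amp <- function(t1, t2) {
    X <- cbind(1, exp(-x / t1), exp(-x / t2))
    fit <- stats::lm.fit(X, y)
    list(rss = sum(fit$residuals^2), beta = fit$coefficients)
  }
  span <- diff(range(x))
  best <- NULL
  grid1 <- exp(seq(log(span / 100), log(span * 2), length.out = 40))
  for (t1 in grid1) for (t2 in grid1[grid1 < t1]) {
    s <- solve_amp(t1, t2)
    if (is.null(best) || s$rss < best$rss)
      best <- c(s, list(t1 = t1, t2 = t2))
  }
  for (pass in 1:6) {
    g1 <- best$t1 * exp(seq(-0.3, 0.3, length.out = 21) / 2^(pass - 1))
    g2 <- best$t2 * exp(seq(-0.3, 0.3, length.out = 21) / 2^(pass - 1))
    for (t1 in g1) for (t2 in g2[g2 < t1]) {
      s <- solve_amp(t1, t2)
      if (s$rss < best$rss) best <- c(s, list(t1 = t1, t2 = t2))
    }
  }
  a1 <- unname(best$beta[2]); a2 <- unname(best$beta[3])
  list(tau1 = best$t1, tau2 = best$t2,
       a1_fraction = a1 / (a1 + a2), offset = unname(best$beta[1]))
}

# preset parameters as a plain list for the oracle
preset_pars <- function(name) unclass(load_preset(name))

# implied open probability of a noise-free, leak-free trace (for gate-bound
# checks): current / (g0 * gain * expression * ghk)
implied_open_prob <- function(ts, preset) {
  sol <- ts$solution
  gain <- max(1 + preset$k_gain_alpha * log(sol$kex / 2), 0) *
    ts$metadata$expression_factor
  unlist(lapply(ts$sweeps, function(df) {
    drv <- ghk_open_channel_current(df$voltage_mV, sol)
    ok <- abs(drv) > 1e-6
    df$current_uA[ok] / (preset$g0 * gain * drv[ok])
  }))
}
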