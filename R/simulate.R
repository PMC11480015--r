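#' Steady-state activation and availability of a channel preset
#'
#' Boltzmann steady states of the Hodgkin-Huxley-style gating model. The
#' activation gate has midpoint `act_v_half` and slope `act_k`; the
#' availability (inactivation) gate has a floor `inact_floor` and a midpoint
#' that destabilizes (shifts rightward) by `k_shift_delta` mV per doubling of
#' extracellular K+ relative to the 2 mM reference:
#' \deqn{a_\infty(v) = \frac{1}{1 + e^{(V_{1/2}^{act} - v)/k_{act}}}, \qquad
#'   h_\infty(v) = floor + \frac{1 - floor}{1 + e^{(v - V_{1/2}^{inact}(K_{ex}))/k_{inact}}}.}
#'
#' @param preset a [channel_preset()].
#' @param v membrane potential (mV); vectorized.
#' @param solution a [solution_spec()].
#' @return List with numeric elements `a_inf` and `h_inf`.
#' @export
gate_steady_state <- function(preset, v, solution = solution_spec()) {
  ivh <- preset$inact_v_half_ref +
    preset$k_shift_delta * log2(solution$kex / 2)
  list(a_inf = 1 / (1 + exp((preset$act_v_half - v) / preset$act_k)),
       h_inf = preset$inact_floor + (1 - preset$inact_floor) /
         (1 + exp((v - ivh) / preset$inact_k)))
}

# recovery time constant at the given bath K+ (power-law speed-up)
.tau_rec <- function(preset, kex) preset$tau_rec_ref * (2 / kex)^preset$k_rec_gamma

# kinetic parameters at one voltage: time constants switch regime at the
# threshold (-40 mV inclusive on the hyperpolarized side, so the -40 mV tail
# step deactivates and inactivation gates recover there)
.gate_kinetics <- function(preset, v, solution) {
  ss <- gate_steady_state(preset, v, solution)
  hyper <- v <= .kv_regime_threshold
  list(a_inf = ss$a_inf, h_inf = ss$h_inf,
       tau_a = if (hyper) preset$tau_deact else preset$tau_act,
       tau_h = if (hyper) rep(.tau_rec(preset, solution$kex), 2)
               else c(preset$tau_inact_1, preset$tau_inact_2))
}

# open probability from gate values: the persistent fraction bypasses the
# inactivation gates, so persistent_frac = 1 is an exactly non-inactivating
# channel
.open_prob <- function(preset, a, h1, h2) {
  a * (preset$persistent_frac + (1 - preset$persistent_frac) *
         (preset$a1_frac * h1 + (1 - preset$a1_frac) * h2))
}

# conductance gain with bath K+ (ln-linear, clamped at zero)
.k_gain <- function(preset, kex) max(1 + preset$k_gain_alpha * log(kex / 2), 0)

# run RNG-dependent code under a local seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Simulate a voltage-clamp recording of one oocyte
#'
#' Integrates the gating model under a [voltage_protocol()] using exact
#' per-segment exponential relaxation (all rates are piecewise-constant in
#' voltage, so no ODE solver is involved and noise-free runs are deterministic
#' to machine precision). Within each constant-voltage segment the activation
#' gate relaxes to its steady state with the activation time constant
#' (deactivation time constant at or below -40 mV) and the two inactivation
#' gates relax with the slow/fast inactivation constants above -40 mV or with
#' the K+-dependent recovery constant at or below it. The membrane current is
#' \deqn{I = g_0\,(1 + \alpha \ln(K_{ex}/2))\,f_{expr}\,p_{open}\,
#'   I_{GHK}(v) + g_{leak} (v - E_{leak}) + \varepsilon,}
#' with \eqn{p_{open} = a\,[p_{pers} + (1-p_{pers})(w_1 h_1 + (1-w_1) h_2)]}.
#'
#' @param preset a [channel_preset()].
#' @param protocol a [voltage_protocol()].
#' @param solution a [solution_spec()].
#' @param noise a [noise_spec()]; use [noise_free()] for exact runs.
#' @param carry_state if `TRUE`, gate state persists across sweeps, relaxing
#'   at the holding potential for the inter-sweep rest (required for train
#'   protocols; harmless elsewhere). If `FALSE` every sweep starts from
#'   steady state at holding.
#' @param expression_factor multiplicative conductance factor of this oocyte
#'   (drawn by [make_batch()] for batches).
#' @param oocyte_id identifier recorded in the metadata.
#' @return A `trace_set`: protocol, solution, preset name, one data frame per
#'   sweep (`time_ms`, `voltage_mV`, `current_uA`, `segment`, `role`) and
#'   metadata.
#' @export
simulate_protocol <- function(preset, protocol, solution = solution_spec(),
                              noise = noise_free(), carry_state = FALSE,
                              expression_factor = 1, oocyte_id = 1L) {
  stopifnot(inherits(preset, "channel_preset"),
            inherits(protocol, "voltage_protocol"))
  dt <- 1 / protocol$sampling_khz
  hold <- protocol$holding_mV
  ss0 <- gate_steady_state(preset, hold, solution)
  gain <- .k_gain(preset, solution$kex) * expression_factor
  state <- list(a = ss0$a_inf, h = c(ss0$h_inf, ss0$h_inf))

  run_sweep <- function(sweep, state) {
    segs <- sweep$segments
    dfs <- vector("list", length(segs))
    t0 <- 0
    for (j in seq_along(segs)) {
      sg <- segs[[j]]
      kin <- .gate_kinetics(preset, sg$mV, solution)
      n <- max(1L, round(sg$ms * protocol$sampling_khz))
      tt <- dt * seq_len(n)
      a <- kin$a_inf + (state$a - kin$a_inf) * exp(-tt / kin$tau_a)
      h1 <- kin$h_inf + (state$h[1] - kin$h_inf) * exp(-tt / kin$tau_h[1])
      h2 <- kin$h_inf + (state$h[2] - kin$h_inf) * exp(-tt / kin$tau_h[2])
      i_chan <- preset$g0 * gain * .open_prob(preset, a, h1, h2) *
        ghk_open_channel_current(sg$mV, solution)
      i_leak <- noise$g_leak * (sg$mV - noise$e_leak)
      cur <- i_chan + i_leak
      if (noise$current_sd > 0)
        cur <- cur + stats::rnorm(n, sd = noise$current_sd)
      dfs[[j]] <- data.frame(time_ms = t0 + tt, voltage_mV = sg$mV,
                             current_uA = cur, segment = j, role = sg$role)
      state <- list(a = a[n], h = c(h1[n], h2[n]))
      t0 <- t0 + sg$ms
    }
    list(df = do.call(rbind, dfs), state = state)
  }

  simulate_all <- function() {
    sweeps <- vector("list", length(protocol$sweeps))
    st <- state
    for (i in seq_along(protocol$sweeps)) {
      res <- run_sweep(protocol$sweeps[[i]], st)
      sweeps[[i]] <- res$df
      if (carry_state) {
        rest <- .rest_after_sweep(protocol, i)
        kin <- .gate_kinetics(preset, hold, solution)
        st <- list(
          a = kin$a_inf + (res$state$a - kin$a_inf) * exp(-rest / kin$tau_a),
          h = kin$h_inf + (res$state$h - kin$h_inf) * exp(-rest / kin$tau_h))
      } else st <- state
    }
    sweeps
  }

  sweeps <- if (noise$current_sd > 0)
    .with_seed(noise$seed + 13L * as.integer(oocyte_id), simulate_all())
  else simulate_all()

  structure(list(protocol = protocol, solution = solution,
                 preset_name = preset$name, sweeps = sweeps,
                 metadata = list(oocyte_id = oocyte_id,
                                 expression_factor = expression_factor,
                                 carry_state = carry_state,
                                 seed = noise$seed,
                                 noise = unclass(noise)[c("current_sd",
                                                          "expression_cv",
                                                          "g_leak", "e_leak")],
                                 interval_dialect = protocol$interval_dialect)),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  n <- sum(vapply(x$sweeps, nrow, integer(1)))
  cat(sprintf("<trace_set> %s | %s | [K+]ex %g mM | %d sweeps, %d samples\n",
              x$preset_name, x$protocol$name, x$solution$kex,
              length(x$sweeps), n))
  invisible(x)
}

#' @export
as.data.frame.trace_set <- function(x, ...) {
  do.call(rbind, lapply(seq_along(x$sweeps), function(i)
    cbind(sweep_index = i, x$sweeps[[i]])))
}

#' @export
plot.trace_set <- function(x, sweeps = seq_along(x$sweeps), ...) {
  rng <- range(unlist(lapply(x$sweeps[sweeps], `[[`, "current_uA")))
  graphics::plot(NA, xlim = c(0, max(vapply(x$sweeps[sweeps], function(s)
    max(s$time_ms), numeric(1)))), ylim = rng,
    xlab = "time (ms)", ylab = expression(I ~ (mu * A)),
    main = sprintf("%s / %s", x$preset_name, x$protocol$name), ...)
  for (i in sweeps)
    graphics::lines(x$sweeps[[i]]$time_ms, x$sweeps[[i]]$current_uA,
                    col = grDevices::hcl.colors(length(x$sweeps), "Zissou 1")[i])
  invisible(x)
}

#' Simulate a batch of oocytes
#'
#' Draws one lognormal expression factor per oocyte (mean 1, coefficient of
#' variation `noise$expression_cv`) and simulates each oocyte independently.
#' Per-oocyte random streams are derived from the root seed by a counter, so
#' enlarging the batch never reshuffles earlier oocytes, and the whole batch
#' is reproducible from `noise$seed`.
#'
#' @inheritParams simulate_protocol
#' @param n_oocytes number of oocytes (>= 1).
#' @return List of `trace_set` objects.
#' @export
make_batch <- function(preset, protocol, solution = solution_spec(),
                       n_oocytes = 8, noise = noise_spec(),
                       carry_state = FALSE) {
  if (n_oocytes < 1) .kv_stop("kv_invalid_batch", "n_oocytes must be >= 1")
  cv <- noise$expression_cv
  sdlog <- sqrt(log(1 + cv^2))
  lapply(seq_len(n_oocytes), function(i) {
    oseed <- (noise$seed + 104729L * i) %% 2147483629L
    ef <- if (cv > 0)
      .with_seed(oseed, stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog))
    else 1
    simulate_protocol(preset, protocol, solution,
                      noise = noise, carry_state = carry_state,
                      expression_factor = ef, oocyte_id = i)
  })
}
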