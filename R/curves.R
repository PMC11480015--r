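#' Conductance-voltage curve from tail currents
#'
#' One point per sweep: x is the test-step voltage, y the tail-current peak
#' normalized to the largest tail-peak magnitude across sweeps (so the
#' maximum of the curve is exactly 1 on clean data). Tail peaks report the
#' open probability reached at the end of the test step because every tail is
#' recorded at the same voltage, i.e. the same driving force.
#'
#' @param ts a `trace_set` recorded with a tail-current protocol
#'   ([gv_protocol()]).
#' @param blank_ms capacitive-blank interval skipped after the jump to the
#'   tail voltage.
#' @param baseline_subtract subtract the mean holding-segment current from
#'   every sweep before measuring (a simple leak/offset correction; off by
#'   default).
#' @param smooth_ms boxcar width for the tail-peak search (see
#'   [extract_features()]); the 5 ms default is a quarter of the deactivation
#'   time constant and removes most of the noise-extremum bias.
#' @return Data frame with columns `v` (mV) and `y` (normalized tail peak).
#' @export
gv_curve <- function(ts, blank_ms = 2, baseline_subtract = FALSE,
                     smooth_ms = 5) {
  stopifnot(inherits(ts, "trace_set"))
  vals <- vapply(seq_along(ts$sweeps), function(i) {
    f <- extract_features(ts, i, blank_ms = blank_ms, smooth_ms = smooth_ms)
    if (is.na(f$tail_peak))
      .kv_stop("kv_protocol_mismatch", "protocol has no tail segment")
    base <- if (baseline_subtract) .hold_baseline(ts, i) else 0
    f$tail_peak - base
  }, numeric(1))
  vs <- vapply(ts$protocol$sweeps, `[[`, numeric(1), "label_voltage")
  mx <- max(abs(vals))
  if (mx == 0)
    .kv_stop("kv_degenerate_trace", "all tail currents are zero")
  data.frame(v = vs, y = vals / vals[which.max(abs(vals))])
}

#' Steady-state availability (inactivation) curve
#'
#' One point per sweep of an inactivation protocol: x is the conditioning
#' voltage, y the peak current of the fixed +50 mV test step, normalized to
#' the largest peak across sweeps.
#'
#' @param ts a `trace_set` recorded with [inactivation_protocol()].
#' @inheritParams gv_curve
#' @return Data frame with columns `v` (conditioning mV) and `y`.
#' @export
inactivation_curve <- function(ts, baseline_subtract = FALSE) {
  stopifnot(inherits(ts, "trace_set"))
  vals <- vapply(seq_along(ts$sweeps), function(i) {
    f <- extract_features(ts, i, role = "test")
    base <- if (baseline_subtract) .hold_baseline(ts, i) else 0
    f$peak - base
  }, numeric(1))
  vs <- vapply(ts$protocol$sweeps, `[[`, numeric(1), "label_voltage")
  mx <- max(abs(vals))
  if (mx == 0)
    .kv_stop("kv_degenerate_trace", "all test-step currents are zero")
  data.frame(v = vs, y = vals / vals[which.max(abs(vals))])
}

.hold_baseline <- function(ts, i) {
  df <- ts$sweeps[[i]]
  hold <- df$current_uA[df$role == "hold"]
  if (length(hold) == 0) 0 else mean(hold)
}

#' Recovery-from-inactivation curve
#'
#' Relative recovered current ([recovery_ratio()]) versus recovery interval,
#' one point per sweep of a twin-pulse recovery protocol.
#'
#' @param ts a `trace_set` recorded with [recovery_protocol()].
#' @param orientation passed to [recovery_ratio()].
#' @return Data frame with columns `delta_t` (ms) and `y`.
#' @export
recovery_curve <- function(ts, orientation = c("corrected", "as_printed")) {
  orientation <- match.arg(orientation)
  m <- recovery_measurements(ts)
  data.frame(delta_t = m$delta_t,
             y = vapply(seq_len(nrow(m)), function(i)
               recovery_ratio(m[i, ], orientation = orientation), numeric(1)))
}

#' Quantify cumulative inactivation under a pulse train
#'
#' End-of-pulse currents across a train, normalized to the largest pulse
#' (the first, on clean data). Returns the normalized per-pulse currents,
#' the mono-exponential time constant of the first 2 s of accumulation and
#' the relative current remaining after 10 s of pulsing. With fewer than 4
#' pulses inside the 2 s window (i.e. at 1 Hz) the time constant is reported
#' as `NA` with an explanatory flag rather than a number.
#'
#' @param ts a `trace_set` simulated with `carry_state = TRUE` under
#'   [train_protocol()].
#' @return An object of class `cumulative_result`: `frequency` (Hz), `kex`
#'   (mM), `points` (data frame `t_ms`, `y`), `tau_first_2s` (ms or `NA`),
#'   `relative_current_10s` and `flags`.
#' @export
cumulative_inactivation <- function(ts) {
  stopifnot(inherits(ts, "trace_set"))
  prot <- ts$protocol
  ends <- vapply(seq_along(ts$sweeps), function(i)
    extract_features(ts, i, role = "test")$end_of_step, numeric(1))
  # pulse start times, first pulse at 0 (the hold prefix of sweep 1 excluded)
  starts <- numeric(length(ends))
  for (i in seq_along(starts)[-1]) {
    dur <- .sweep_duration(prot$sweeps[[i - 1]])
    if (i - 1 == 1 && prot$sweeps[[1]]$segments[[1]]$role == "hold")
      dur <- dur - prot$sweeps[[1]]$segments[[1]]$ms
    starts[i] <- starts[i - 1] + dur + .rest_after_sweep(prot, i - 1)
  }
  mx <- max(abs(ends))
  if (mx == 0) .kv_stop("kv_degenerate_trace", "all pulse currents are zero")
  y <- ends / ends[which.max(abs(ends))]
  flags <- character(0)
  w2 <- starts <= 2000
  tau <- NA_real_
  if (sum(w2) >= 4) {
    tau <- tryCatch(fit_monoexp(starts[w2], y[w2], "decaying")$tau1,
                    error = function(e) {
                      flags <<- c(flags, "tau_fit_failed"); NA_real_
                    })
  } else flags <- c(flags, "tau_not_estimable_fewer_than_4_pulses_in_2s")
  w10 <- which(starts <= 10000)
  structure(list(
    frequency = if (!is.null(prot$metadata$frequency_Hz))
      prot$metadata$frequency_Hz else NA_real_,
    kex = ts$solution$kex,
    points = data.frame(t_ms = starts, y = y),
    tau_first_2s = tau,
    relative_current_10s = y[max(w10)],
    flags = flags), class = "cumulative_result")
}

#' @export
print.cumulative_result <- function(x, ...) {
  cat(sprintf("<cumulative_result> %g Hz, [K+]ex %g mM: %d pulses, tau(first 2 s) %s ms, relative current at 10 s %.3f\n",
              x$frequency, x$kex, nrow(x$points),
              if (is.na(x$tau_first_2s)) "n.e." else
                sprintf("%.0f", x$tau_first_2s),
              x$relative_current_10s))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Average curves across oocytes
#'
#' Element-wise mean of the y column of per-oocyte curves sharing the same x
#' grid (first column), as used before group-level fitting.
#'
#' @param curves list of data frames with identical first column and a `y`
#'   column.
#' @return A data frame like the inputs with y averaged.
#' @export
average_curves <- function(curves) {
  stopifnot(length(curves) >= 1)
  x0 <- curves[[1]][[1]]
  for (cv in curves)
    if (!isTRUE(all.equal(cv[[1]], x0)))
      .kv_stop("kv_protocol_mismatch", "curves are on different x grids")
  out <- curves[[1]]
  out$y <- rowMeans(do.call(cbind, lapply(curves, `[[`, "y")))
  out
}
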