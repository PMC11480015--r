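#' Extract per-sweep scalar features from a trace
#'
#' Computes the standard scalar features of one sweep of a `trace_set`: the
#' peak current of the designated test segment (the extremum in the expected
#' current direction, outward positive above the K+ reversal potential), the
#' end-of-step current (mean over the final 5% of the segment), the time of
#' the peak relative to the start of the segment, and — when the sweep has a
#' tail segment — the tail peak, searched within the first 50 ms of the tail
#' after a capacitive-blank interval.
#'
#' @param ts a `trace_set`.
#' @param sweep sweep index.
#' @param blank_ms dead time skipped after the voltage jump before the tail
#'   peak search (real rigs show capacitive transients there).
#' @param role role label of the analysed segment (`"test"` by default;
#'   `"test2"` selects the second pulse of the recovery protocol).
#' @param window optional numeric length-2 window (ms, relative to segment
#'   start) restricting the peak search; must lie inside the segment.
#' @param smooth_ms width (ms) of a boxcar filter applied before the peak
#'   searches. Smoothing is linear, so it preserves the proportionality of
#'   tail amplitudes across sweeps while suppressing the upward bias that a
#'   raw extremum search suffers on noisy traces; 0 disables it.
#' @return List with elements `peak`, `end_of_step`, `tail_peak` (`NA` when
#'   the sweep has no tail segment) and `peak_time` (ms from segment start).
#' @export
extract_features <- function(ts, sweep = 1, blank_ms = 2, role = "test",
                             window = NULL, smooth_ms = 0) {
  stopifnot(inherits(ts, "trace_set"))
  df <- ts$sweeps[[sweep]]
  seg <- df[df$role == role, ]
  if (nrow(seg) == 0)
    .kv_stop("kv_protocol_mismatch",
             sprintf("sweep %d has no segment with role '%s'", sweep, role))
  t_rel <- seg$time_ms - min(seg$time_ms)
  if (!is.null(window)) {
    if (window[1] < 0 || window[2] > max(t_rel) + 1e-9 || window[1] >= window[2])
      .kv_stop("kv_window_bounds", "window must lie inside the segment")
    keep <- t_rel >= window[1] & t_rel <= window[2]
  } else keep <- rep(TRUE, nrow(seg))
  e_k <- nernst_potential(ts$solution$kin, ts$solution$kex,
                          ts$solution$temperature)
  sgn <- function(v) if (v >= e_k) 1 else -1
  khz <- ts$protocol$sampling_khz
  s <- sgn(seg$voltage_mV[1])
  cur <- .boxcar(seg$current_uA, smooth_ms, khz)
  ip <- which.max(s * cur[keep])
  peak <- cur[keep][ip]
  peak_time <- t_rel[keep][ip]
  n_end <- max(1L, round(0.05 * nrow(seg)))
  end_of_step <- mean(utils::tail(seg$current_uA, n_end))

  tail_seg <- df[df$role == "tail", ]
  tail_peak <- NA_real_
  if (nrow(tail_seg) > 0) {
    tt <- tail_seg$time_ms - min(tail_seg$time_ms)
    w <- tt >= blank_ms & tt <= blank_ms + 50
    st <- sgn(tail_seg$voltage_mV[1])
    tcur <- .boxcar(tail_seg$current_uA, smooth_ms, khz)
    tail_peak <- tcur[w][which.max(st * tcur[w])]
  }
  list(peak = peak, end_of_step = end_of_step, tail_peak = tail_peak,
       peak_time = peak_time)
}

.boxcar <- function(x, smooth_ms, khz) {
  n <- round(smooth_ms * khz)
  if (n <= 1) return(x)
  sm <- as.numeric(stats::filter(x, rep(1 / n, n), sides = 2))
  sm[is.na(sm)] <- x[is.na(sm)]
  sm
}

#' Twin-pulse recovery measurements
#'
#' For each sweep of a recovery-protocol trace set, extracts the peak of the
#' first depolarizing step (`i1_max`), the current at its end (`i1_min`,
#' mean over the final 5%), the peak of the second step (`i2_max`) and the
#' recovery interval.
#'
#' @param ts a `trace_set` recorded with [recovery_protocol()].
#' @return Data frame with columns `delta_t`, `i1_max`, `i1_min`, `i2_max`.
#' @export
recovery_measurements <- function(ts) {
  stopifnot(inherits(ts, "trace_set"))
  rows <- lapply(seq_along(ts$sweeps), function(i) {
    sw <- ts$protocol$sweeps[[i]]
    if (is.null(sw$recovery_ms))
      .kv_stop("kv_protocol_mismatch", "sweep carries no recovery interval")
    f1 <- extract_features(ts, i, role = "test")
    f2 <- extract_features(ts, i, role = "test2")
    data.frame(delta_t = sw$recovery_ms, i1_max = f1$peak,
               i1_min = f1$end_of_step, i2_max = f2$peak)
  })
  do.call(rbind, rows)
}

#' Relative recovered current from a twin-pulse measurement
#'
#' Quantifies recovery from inactivation as the ratio of the second-pulse
#' peak to the first-pulse peak after subtracting the residual current at the
#' end of the first pulse. The default (`"corrected"`) orientation,
#' \deqn{I_{rec} = \frac{I_{2max} - I_{1min}}{I_{1max} - I_{1min}},}
#' is 0 with no recovery and rises to 1 at full recovery, matching plotted
#' recovery curves that saturate at 1. The `"as_printed"` orientation is the
#' reciprocal form \eqn{(I_{1max} - I_{1min})/(I_{2max} - I_{1min})}, kept
#' available behind an explicit flag because some write-ups state the formula
#' that way round.
#'
#' @param i1_max peak current of the first pulse, or a list/one-row data
#'   frame with fields `i1_max`, `i1_min`, `i2_max` (then the remaining
#'   arguments are ignored).
#' @param i1_min current at the end of the first pulse.
#' @param i2_max peak current of the second pulse.
#' @param orientation `"corrected"` (default) or `"as_printed"`.
#' @return The relative recovered current (a number).
#' @examples
#' recovery_ratio(10, 2, 10)  # full recovery -> 1
#' recovery_ratio(10, 2, 6)   # half recovery -> 0.5
#' @export
recovery_ratio <- function(i1_max, i1_min = NULL, i2_max = NULL,
                           orientation = c("corrected", "as_printed")) {
  orientation <- match.arg(orientation)
  if (is.list(i1_max)) {
    m <- i1_max
    i1_min <- m$i1_min; i2_max <- m$i2_max; i1_max <- m$i1_max
  }
  if (i1_max <= i1_min)
    .kv_stop("kv_degenerate_trace",
             "no inactivation to recover from (i1_max <= i1_min)")
  if (orientation == "corrected")
    (i2_max - i1_min) / (i1_max - i1_min)
  else
    (i1_max - i1_min) / (i2_max - i1_min)
}

#' Extract the inactivation decay of a depolarizing step
#'
#' Returns the test-segment current from the peak onward with time measured
#' from the peak, the form consumed by [fit_biexp()] when quantifying
#' inactivation time constants.
#'
#' @param ts a `trace_set` with a depolarizing test segment.
#' @param sweep sweep index.
#' @return Data frame with columns `t_ms` (0 at the peak) and `i` (uA).
#' @export
inactivation_decay <- function(ts, sweep = 1) {
  stopifnot(inherits(ts, "trace_set"))
  df <- ts$sweeps[[sweep]]
  seg <- df[df$role == "test", ]
  if (nrow(seg) == 0)
    .kv_stop("kv_protocol_mismatch", "sweep has no test segment")
  t_rel <- seg$time_ms - min(seg$time_ms)
  ip <- which.max(seg$current_uA)
  data.frame(t_ms = t_rel[ip:nrow(seg)] - t_rel[ip],
             i = seg$current_uA[ip:nrow(seg)])
}
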