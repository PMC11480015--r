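#' Voltage-clamp protocol objects
#'
#' A `voltage_protocol` is an ordered list of sweeps, each sweep an ordered
#' list of piecewise-constant voltage segments, plus an inter-sweep interval,
#' a holding potential and a sampling rate. Segments carry a `role`
#' (`"hold"`, `"test"`, `"tail"`, `"cond"`, `"recovery"`) so that downstream
#' feature extraction can locate the analysed windows without magic indices.
#'
#' @param duration_ms segment duration in ms, strictly positive.
#' @param voltage_mV command voltage in mV, within \[-150, 100\].
#' @param role segment role label.
#' @return `voltage_segment()` returns a list with elements `ms`, `mV`, `role`.
#' @export
voltage_segment <- function(duration_ms, voltage_mV, role = "test") {
  if (!is.numeric(duration_ms) || length(duration_ms) != 1 || duration_ms <= 0)
    .kv_stop("kv_invalid_protocol", "segment duration must be a single positive number (ms)")
  if (!is.numeric(voltage_mV) || length(voltage_mV) != 1 ||
      voltage_mV < -150 || voltage_mV > 100)
    .kv_stop("kv_invalid_protocol", "segment voltage must lie within [-150, 100] mV")
  list(ms = as.numeric(duration_ms), mV = as.numeric(voltage_mV), role = role)
}

#' @param segments ordered list of [voltage_segment()]s (at least one).
#' @param label_voltage the analysed test-step voltage of the sweep (mV); must
#'   match the voltage of exactly one designated (non-hold) segment.
#' @param recovery_ms optional recovery interval (ms), recovery protocol only.
#' @rdname voltage_segment
#' @export
protocol_sweep <- function(segments, label_voltage, recovery_ms = NULL) {
  if (length(segments) < 1)
    .kv_stop("kv_invalid_protocol", "a sweep needs at least one segment")
  volts <- vapply(segments, `[[`, numeric(1), "mV")
  roles <- vapply(segments, `[[`, character(1), "role")
  n_match <- sum(volts == label_voltage & roles != "hold")
  if (n_match < 1)
    .kv_stop("kv_invalid_protocol",
             "label_voltage must equal the voltage of a designated segment")
  list(segments = segments, label_voltage = as.numeric(label_voltage),
       recovery_ms = if (is.null(recovery_ms)) NULL else as.numeric(recovery_ms))
}

#' Construct a voltage protocol
#'
#' Low-level constructor; most users will call one of the protocol builders
#' ([iv_protocol()], [gv_protocol()], [inactivation_protocol()],
#' [recovery_protocol()], [amplitude_protocol()], [train_protocol()]).
#'
#' @param name protocol identifier.
#' @param sweeps list of sweeps as built by `protocol_sweep()`.
#' @param inter_sweep_ms inter-sweep interval in ms (non-negative). Its
#'   meaning depends on `interval_dialect`: `"gap"` is the holding time
#'   between the end of a sweep and the start of the next; `"period"` is the
#'   sweep start-to-start time (used by the train protocol).
#' @param holding_mV holding potential (mV).
#' @param sampling_khz sampling rate in kHz.
#' @param interval_dialect `"gap"` or `"period"`.
#' @param metadata free-form named list recorded verbatim (dialect flags etc.).
#' @return An object of class `voltage_protocol`.
#' @export
voltage_protocol <- function(name, sweeps, inter_sweep_ms,
                             holding_mV = -80, sampling_khz = 10,
                             interval_dialect = c("gap", "period"),
                             metadata = list()) {
  interval_dialect <- match.arg(interval_dialect)
  if (length(sweeps) < 1)
    .kv_stop("kv_invalid_protocol", "a protocol needs at least one sweep")
  if (inter_sweep_ms < 0)
    .kv_stop("kv_invalid_protocol", "inter_sweep_ms must be >= 0")
  if (sampling_khz <= 0)
    .kv_stop("kv_invalid_protocol", "sampling_khz must be > 0")
  structure(
    list(name = name, sweeps = sweeps,
         inter_sweep_ms = as.numeric(inter_sweep_ms),
         holding_mV = as.numeric(holding_mV),
         sampling_khz = as.numeric(sampling_khz),
         interval_dialect = interval_dialect,
         metadata = metadata),
    class = "voltage_protocol")
}

#' @export
print.voltage_protocol <- function(x, ...) {
  cat(sprintf("<voltage_protocol> %s\n", x$name))
  cat(sprintf("  %d sweep(s), holding %g mV, sampling %g kHz\n",
              length(x$sweeps), x$holding_mV, x$sampling_khz))
  cat(sprintf("  inter-sweep %g ms (%s dialect)\n",
              x$inter_sweep_ms, x$interval_dialect))
  lv <- vapply(x$sweeps, `[[`, numeric(1), "label_voltage")
  cat(sprintf("  test voltages: %s mV\n",
              paste(unique(lv), collapse = ", ")))
  invisible(x)
}

# hold prefix shared by the builders; configurable so the simulated gates can
# settle at holding before the test step
.hold_prefix <- function(hold_ms, holding_mV) {
  voltage_segment(hold_ms, holding_mV, role = "hold")
}

#' Standard current-voltage (IV) step protocol
#'
#' 500 ms steps from a -80 mV holding potential to -60 .. +80 mV in 20 mV
#' increments, 7 s inter-sweep interval.
#'
#' @param hold_ms duration of the leading holding segment (ms).
#' @param sampling_khz sampling rate (kHz).
#' @return A [voltage_protocol()].
#' @export
iv_protocol <- function(hold_ms = 100, sampling_khz = 10) {
  vs <- seq(-60, 80, by = 20)
  sweeps <- lapply(vs, function(v) {
    protocol_sweep(list(.hold_prefix(hold_ms, -80),
                        voltage_segment(500, v, role = "test")),
                   label_voltage = v)
  })
  voltage_protocol("iv", sweeps, inter_sweep_ms = 7000,
                   sampling_khz = sampling_khz)
}

#' Tail-step voltage for a given extracellular potassium concentration
#'
#' The conductance-voltage protocol records tail currents at -40 mV; for
#' solutions where that yields small tails the step is adjusted:
#' 1 mM K+ uses -25 mV and 8 mM K+ uses -15 mV, while 98 mM K+ (and any
#' unlisted concentration) uses the standard -40 mV.
#'
#' @param kex extracellular potassium concentration (mM), positive.
#' @return Tail voltage in mV.
#' @export
tail_voltage_for_kex <- function(kex) {
  if (!is.numeric(kex) || length(kex) != 1 || !is.finite(kex) || kex <= 0)
    .kv_stop("kv_invalid_solution", "kex must be a single positive concentration (mM)")
  if (kex == 1) return(-25)
  if (kex == 8) return(-15)
  -40
}

#' Conductance-voltage (GV) tail-current protocol
#'
#' 25 ms steps from -80 mV to -70 .. +60 mV in 10 mV increments, each followed
#' by a 400 ms tail segment at [tail_voltage_for_kex()]; 7 s inter-sweep
#' interval.
#'
#' @inheritParams iv_protocol
#' @param kex extracellular K+ (mM); selects the tail voltage.
#' @export
gv_protocol <- function(kex = 2, hold_ms = 100, sampling_khz = 10) {
  tail_mV <- tail_voltage_for_kex(kex)
  vs <- seq(-70, 60, by = 10)
  sweeps <- lapply(vs, function(v) {
    protocol_sweep(list(.hold_prefix(hold_ms, -80),
                        voltage_segment(25, v, role = "test"),
                        voltage_segment(400, tail_mV, role = "tail")),
                   label_voltage = v)
  })
  voltage_protocol("gv", sweeps, inter_sweep_ms = 7000,
                   sampling_khz = sampling_khz,
                   metadata = list(kex_mM = kex, tail_mV = tail_mV))
}

#' Voltage-dependence-of-inactivation protocol
#'
#' 1 s conditioning steps (10 s with `long_steps = TRUE`, used for
#' non-inactivating constructs) from -80 mV to -100 .. +30 mV in 10 mV
#' increments, each followed by a +50 mV / 400 ms test step; 10 s inter-sweep
#' interval.
#'
#' @inheritParams iv_protocol
#' @param long_steps use 10 s conditioning steps instead of 1 s.
#' @export
inactivation_protocol <- function(long_steps = FALSE, hold_ms = 100,
                                  sampling_khz = 10) {
  cond_ms <- if (isTRUE(long_steps)) 10000 else 1000
  vs <- seq(-100, 30, by = 10)
  sweeps <- lapply(vs, function(v) {
    protocol_sweep(list(.hold_prefix(hold_ms, -80),
                        voltage_segment(cond_ms, v, role = "cond"),
                        voltage_segment(400, 50, role = "test")),
                   label_voltage = v)
  })
  voltage_protocol("inactivation", sweeps, inter_sweep_ms = 10000,
                   sampling_khz = sampling_khz,
                   metadata = list(long_steps = isTRUE(long_steps),
                                   cond_label = "cond"))
}

#' Recovery-from-inactivation twin-pulse protocol
#'
#' 17 sweeps, each a 200 ms step to +50 mV, a recovery interval at -80 mV and
#' a second 200 ms step to +50 mV. The recovery interval starts at 20 ms and
#' grows by 500 ms per sweep (20, 520, ..., 8020 ms); the increment is applied
#' from sweep 2 onward. 30 s inter-sweep interval guarantees full recovery
#' before the next sweep.
#'
#' @inheritParams iv_protocol
#' @export
recovery_protocol <- function(hold_ms = 100, sampling_khz = 10) {
  dts <- 20 + (seq_len(17) - 1) * 500
  sweeps <- lapply(dts, function(dt) {
    protocol_sweep(list(.hold_prefix(hold_ms, -80),
                        voltage_segment(200, 50, role = "test"),
                        voltage_segment(dt, -80, role = "recovery"),
                        voltage_segment(200, 50, role = "test2")),
                   label_voltage = 50, recovery_ms = dt)
  })
  voltage_protocol("recovery", sweeps, inter_sweep_ms = 30000,
                   sampling_khz = sampling_khz,
                   metadata = list(increment_convention = "first interval 20 ms, +500 ms from sweep 2"))
}

#' Single-step amplitude protocol
#'
#' One 200 ms step from -80 mV to +50 mV, used to quantify macroscopic peak
#' current amplitudes.
#'
#' @inheritParams iv_protocol
#' @export
amplitude_protocol <- function(hold_ms = 100, sampling_khz = 10) {
  sweeps <- list(protocol_sweep(list(.hold_prefix(hold_ms, -80),
                                     voltage_segment(200, 50, role = "test")),
                                label_voltage = 50))
  voltage_protocol("amplitude", sweeps, inter_sweep_ms = 0,
                   sampling_khz = sampling_khz)
}

#' Repetitive pulse-train protocol
#'
#' 5 ms pulses from -80 mV to +40 mV repeated at a fixed frequency
#' (1 Hz = 1000 ms, 10 Hz = 100 ms, 50 Hz = 20 ms, 100 Hz = 10 ms pulse
#' start-to-start interval) until `total_s` seconds are filled. The
#' inter-sweep interval is the pulse period by default (`dialect = "period"`);
#' a `"gap"` dialect, in which the stated interval is the holding time between
#' pulses, is selectable but non-standard. Only the first pulse carries the
#' leading holding segment so the period is preserved.
#'
#' @inheritParams iv_protocol
#' @param frequency pulse frequency in Hz; the period must be at least the
#'   5 ms pulse width.
#' @param total_s total train duration in seconds.
#' @param dialect interpretation of the inter-sweep interval.
#' @export
train_protocol <- function(frequency, total_s = 10, hold_ms = 100,
                           sampling_khz = 10, dialect = c("period", "gap")) {
  dialect <- match.arg(dialect)
  if (frequency <= 0 || total_s <= 0)
    .kv_stop("kv_invalid_protocol", "frequency and total_s must be positive")
  period <- 1000 / frequency
  if (period < 5)
    .kv_stop("kv_infeasible_frequency",
             sprintf("period %g ms is shorter than the 5 ms pulse", period))
  n_pulse <- floor(total_s * frequency)
  sweeps <- lapply(seq_len(n_pulse), function(i) {
    segs <- list(voltage_segment(5, 40, role = "test"))
    if (i == 1) segs <- c(list(.hold_prefix(hold_ms, -80)), segs)
    protocol_sweep(segs, label_voltage = 40)
  })
  inter <- if (dialect == "period") period else period - 5
  voltage_protocol(sprintf("train_%gHz", frequency), sweeps,
                   inter_sweep_ms = inter, sampling_khz = sampling_khz,
                   interval_dialect = dialect,
                   metadata = list(frequency_Hz = frequency,
                                   total_s = total_s,
                                   period_ms = period))
}

# total rendered duration of one sweep (ms)
.sweep_duration <- function(sweep) {
  sum(vapply(sweep$segments, `[[`, numeric(1), "ms"))
}

# holding time between end of sweep i and start of sweep i+1 (ms)
.rest_after_sweep <- function(protocol, i) {
  if (protocol$interval_dialect == "period") {
    dur <- .sweep_duration(protocol$sweeps[[i]])
    # the leading hold prefix of sweep 1 is outside the pulse period
    if (i == 1 && length(protocol$sweeps[[i]]$segments) > 1 &&
        protocol$sweeps[[i]]$segments[[1]]$role == "hold")
      dur <- dur - protocol$sweeps[[i]]$segments[[1]]$ms
    max(protocol$inter_sweep_ms - dur, 0)
  } else {
    protocol$inter_sweep_ms
  }
}

#' Serialize / deserialize voltage protocols as JSON
#'
#' The writer is canonical (fixed key order, fixed precision) so serialized
#' protocols are diff-stable; `read_protocol(write_protocol(p))` reproduces
#' the protocol field-by-field.
#'
#' @param protocol a [voltage_protocol()].
#' @param path file path; for `write_protocol` the destination JSON file.
#' @return `write_protocol` returns `path` invisibly; `read_protocol` returns
#'   a [voltage_protocol()].
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "voltage_protocol"))
  sweeps <- lapply(protocol$sweeps, function(sw) {
    out <- list(
      segments = lapply(sw$segments, function(sg)
        list(ms = sg$ms, mV = sg$mV, role = sg$role)),
      label_mV = sw$label_voltage)
    if (!is.null(sw$recovery_ms)) out$recovery_ms <- sw$recovery_ms
    out
  })
  obj <- list(name = protocol$name,
              holding_mV = protocol$holding_mV,
              sampling_kHz = protocol$sampling_khz,
              inter_sweep_ms = protocol$inter_sweep_ms,
              interval_dialect = protocol$interval_dialect,
              metadata = protocol$metadata,
              sweeps = sweeps)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = 10,
                              pretty = TRUE), path)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  need <- c("name", "holding_mV", "sampling_kHz", "inter_sweep_ms", "sweeps")
  if (!all(need %in% names(obj)))
    .kv_stop("kv_schema_violation",
             paste("protocol JSON missing field(s):",
                   paste(setdiff(need, names(obj)), collapse = ", ")))
  sweeps <- lapply(obj$sweeps, function(sw) {
    segs <- lapply(sw$segments, function(sg)
      voltage_segment(sg$ms, sg$mV, role = sg$role))
    protocol_sweep(segs, label_voltage = sw$label_mV,
                   recovery_ms = sw$recovery_ms)
  })
  voltage_protocol(obj$name, sweeps, obj$inter_sweep_ms,
                   holding_mV = obj$holding_mV,
                   sampling_khz = obj$sampling_kHz,
                   interval_dialect = if (is.null(obj$interval_dialect)) "gap"
                                      else obj$interval_dialect,
                   metadata = if (is.null(obj$metadata)) list() else obj$metadata)
}

#' Generic single-step protocol
#'
#' One sweep: leading holding segment, then a single test step. Useful for
#' ad-hoc depolarizations such as the 1 s step used when fitting
#' inactivation time constants.
#'
#' @inheritParams iv_protocol
#' @param voltage_mV test-step voltage (mV).
#' @param duration_ms test-step duration (ms).
#' @export
step_protocol <- function(voltage_mV = 50, duration_ms = 1000, hold_ms = 100,
                          sampling_khz = 10) {
  sweeps <- list(protocol_sweep(
    list(.hold_prefix(hold_ms, -80),
         voltage_segment(duration_ms, voltage_mV, role = "test")),
    label_voltage = voltage_mV))
  voltage_protocol(sprintf("step_%gmV_%gms", voltage_mV, duration_ms),
                   sweeps, inter_sweep_ms = 0, sampling_khz = sampling_khz)
}
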