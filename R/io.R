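#' Write / read a trace set as long-format CSV plus a JSON sidecar
#'
#' The CSV holds one row per sample with columns `sweep_index`, `time_ms`,
#' `voltage_mV`, `current_uA`; the sidecar JSON carries the protocol, the
#' solution, the preset name and the metadata (seed, dialect flags), so a
#' written trace set can be re-analysed exactly like the in-memory one.
#' Segment and role annotations are reconstructed from the protocol on read.
#'
#' @param ts a `trace_set`.
#' @param prefix path prefix; `<prefix>.csv` and `<prefix>.json` are written.
#' @return `write_trace_set` returns `prefix` invisibly; `read_trace_set`
#'   returns a `trace_set`.
#' @export
write_trace_set <- function(ts, prefix) {
  stopifnot(inherits(ts, "trace_set"))
  df <- as.data.frame(ts)[, c("sweep_index", "time_ms", "voltage_mV",
                              "current_uA")]
  utils::write.csv(df, paste0(prefix, ".csv"), row.names = FALSE)
  side <- list(
    protocol = jsonlite::fromJSON(.protocol_json(ts$protocol),
                                  simplifyVector = FALSE),
    solution = unclass(ts$solution),
    preset_name = ts$preset_name,
    metadata = ts$metadata)
  writeLines(jsonlite::toJSON(side, auto_unbox = TRUE, digits = 10,
                              pretty = TRUE, null = "null"),
             paste0(prefix, ".json"))
  invisible(prefix)
}

.protocol_json <- function(protocol) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_protocol(protocol, tmp)
  paste(readLines(tmp), collapse = "\n")
}

#' @rdname write_trace_set
#' @export
read_trace_set <- function(prefix) {
  csv <- paste0(prefix, ".csv"); json <- paste0(prefix, ".json")
  if (!file.exists(csv) || !file.exists(json))
    .kv_stop("kv_malformed_input",
             sprintf("expected %s and %s", csv, json))
  df <- utils::read.csv(csv)
  need <- c("sweep_index", "time_ms", "voltage_mV", "current_uA")
  if (!all(need %in% names(df)))
    .kv_stop("kv_malformed_input",
             paste("trace CSV missing column(s):",
                   paste(setdiff(need, names(df)), collapse = ", ")))
  side <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  ptmp <- tempfile(fileext = ".json")
  on.exit(unlink(ptmp))
  writeLines(jsonlite::toJSON(side$protocol, auto_unbox = TRUE, digits = 10),
             ptmp)
  protocol <- read_protocol(ptmp)
  sol <- solution_spec(side$solution$kex, side$solution$kin,
                       side$solution$temperature)
  sweeps <- lapply(sort(unique(df$sweep_index)), function(i) {
    d <- df[df$sweep_index == i, c("time_ms", "voltage_mV", "current_uA")]
    segs <- protocol$sweeps[[i]]$segments
    ns <- vapply(segs, function(sg)
      max(1, round(sg$ms * protocol$sampling_khz)), numeric(1))
    if (sum(ns) != nrow(d))
      .kv_stop("kv_malformed_input",
               sprintf("sweep %d: %d samples but protocol implies %d",
                       i, nrow(d), sum(ns)))
    d$segment <- rep(seq_along(segs), ns)
    d$role <- rep(vapply(segs, `[[`, character(1), "role"), ns)
    rownames(d) <- NULL
    d
  })
  structure(list(protocol = protocol, solution = sol,
                 preset_name = side$preset_name, sweeps = sweeps,
                 metadata = side$metadata),
            class = "trace_set")
}
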