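#' Physical constants used throughout the package
#'
#' Faraday constant (C/mol), gas constant (J/(mol K)) and the default recording
#' temperature in kelvin (295.15 K, the midpoint of typical room-temperature
#' oocyte recordings at 20--22 degrees C).
#'
#' @format A named numeric vector with elements `faraday`, `gas` and
#'   `temperature`.
#' @export
kv_constants <- c(
  faraday = 96485.332,
  gas = 8.314462,
  temperature = 295.15
)

# Voltage (mV) separating the depolarized kinetic regime (activation /
# inactivation time constants) from the hyperpolarized one (deactivation /
# recovery). -40 mV itself belongs to the hyperpolarized regime so that the
# standard -40 mV tail step deactivates rather than activates.
.kv_regime_threshold <- -40

.kv_stop <- function(class, msg) {
  stop(errorCondition(msg, class = c(class, "kvclamp_error")))
}
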