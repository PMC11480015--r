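#' Recording-solution specification
#'
#' Holds the potassium concentrations on both sides of the membrane and the
#' recording temperature. The intracellular concentration defaults to
#' 108.6 mM, the accepted value for *Xenopus laevis* oocytes; the default
#' extracellular concentration of 2 mM corresponds to a standard ND96-type
#' bath.
#'
#' @param kex extracellular K+ concentration (mM), positive.
#' @param kin intracellular K+ concentration (mM), positive.
#' @param temperature temperature in kelvin, within (270, 320).
#' @return An object of class `solution_spec`.
#' @export
solution_spec <- function(kex = 2, kin = 108.6,
                          temperature = kv_constants[["temperature"]]) {
  if (!is.numeric(kex) || length(kex) != 1 || !is.finite(kex) || kex <= 0)
    .kv_stop("kv_invalid_solution", "kex must be a single positive concentration (mM)")
  if (!is.numeric(kin) || length(kin) != 1 || !is.finite(kin) || kin <= 0)
    .kv_stop("kv_invalid_solution", "kin must be a single positive concentration (mM)")
  if (temperature <= 270 || temperature >= 320)
    .kv_stop("kv_invalid_solution", "temperature must lie within (270, 320) K")
  structure(list(kex = as.numeric(kex), kin = as.numeric(kin),
                 temperature = as.numeric(temperature)),
            class = "solution_spec")
}

#' @export
print.solution_spec <- function(x, ...) {
  cat(sprintf("<solution_spec> [K+]ex %g mM, [K+]in %g mM, T %g K (E_K %.1f mV)\n",
              x$kex, x$kin, x$temperature,
              nernst_potential(x$kin, x$kex, x$temperature)))
  invisible(x)
}

#' Noise and variability specification for simulated recordings
#'
#' Controls the three nuisance components of a simulated oocyte recording:
#' additive Gaussian current noise, lognormal oocyte-to-oocyte expression
#' scatter, and an ohmic leak. All randomness is reproducibly determined by
#' `seed`; `noise_free()` is a convenience for exact deterministic runs.
#'
#' @param current_sd standard deviation of additive current noise (uA).
#' @param expression_cv coefficient of variation of the lognormal per-oocyte
#'   expression factor (mean 1).
#' @param g_leak leak conductance (uA/mV).
#' @param e_leak leak reversal potential (mV).
#' @param seed integer seed; one root seed deterministically drives every
#'   oocyte in a batch.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(current_sd = 0.02, expression_cv = 0.2,
                       g_leak = 0, e_leak = -20, seed = 1L) {
  if (current_sd < 0 || expression_cv < 0 || g_leak < 0)
    .kv_stop("kv_invalid_noise", "noise magnitudes must be non-negative")
  structure(list(current_sd = current_sd, expression_cv = expression_cv,
                 g_leak = g_leak, e_leak = e_leak, seed = as.integer(seed)),
            class = "noise_spec")
}

#' @rdname noise_spec
#' @export
noise_free <- function() noise_spec(current_sd = 0, expression_cv = 0,
                                    g_leak = 0, seed = 0L)
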