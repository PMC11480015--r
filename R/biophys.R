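#' Nernst reversal potential for potassium
#'
#' @param kin intracellular K+ concentration (mM).
#' @param kex extracellular K+ concentration (mM).
#' @param temperature temperature (K).
#' @return Reversal potential in mV, \eqn{(RT/F)\,\ln([K^+]_{ex}/[K^+]_{in})}.
#' @examples
#' nernst_potential(108.6, 2)    # about -101.6 mV
#' @export
nernst_potential <- function(kin, kex,
                             temperature = kv_constants[["temperature"]]) {
  if (any(kin <= 0) || any(kex <= 0))
    .kv_stop("kv_invalid_solution", "concentrations must be positive")
  1000 * kv_constants[["gas"]] * temperature / kv_constants[["faraday"]] *
    log(kex / kin)
}

#' Goldman-Hodgkin-Katz open-channel flux (per unit permeability)
#'
#' The GHK current through an open channel at membrane potential `v`,
#' up to the permeability scale:
#' \eqn{u\,( [K]_{in} - [K]_{ex} e^{-u})/(1 - e^{-u})} with
#' \eqn{u = V_m F / (R T)}. At \eqn{|u| < 10^{-6}} the analytic limit
#' \eqn{[K]_{in} - [K]_{ex}} is returned. The sign convention is outward
#' positive: the current is zero at the Nernst potential and has the sign of
#' \eqn{V_m - E_K}.
#'
#' @param v membrane potential (mV); vectorized.
#' @param solution a [solution_spec()].
#' @return Numeric vector of per-unit-permeability currents.
#' @export
ghk_open_channel_current <- function(v, solution = solution_spec()) {
  u <- (v / 1000) * kv_constants[["faraday"]] /
    (kv_constants[["gas"]] * solution$temperature)
  small <- abs(u) < 1e-6
  out <- numeric(length(u))
  out[small] <- solution$kin - solution$kex
  ub <- u[!small]
  out[!small] <- ub * (solution$kin - solution$kex * exp(-ub)) / (1 - exp(-ub))
  out
}

#' Theoretical GHK current ratio between two extracellular K+ concentrations
#'
#' Predicts the change in outward current expected purely from the change in
#' driving force when the bath K+ is switched from `c2_kex` to `c1_kex`, with
#' everything else equal:
#' \deqn{\frac{I_{C1}}{I_{C2}} =
#'   \frac{[K]_{in} - [K]_{ex}^{C1} e^{-u}}{[K]_{in} - [K]_{ex}^{C2} e^{-u}},
#'   \quad u = \frac{V_m F}{R T}.}
#' The common flux prefactor cancels because both conditions are evaluated at
#' the same membrane potential.
#'
#' @param c1_kex,c2_kex the two extracellular K+ concentrations (mM).
#' @param vm membrane potential (mV).
#' @param kin intracellular K+ concentration (mM).
#' @param temperature temperature (K).
#' @return For `ghk_ratio`, the predicted current ratio (a number). For
#'   `ghk_prediction`, a classed record holding the inputs and the ratio.
#' @examples
#' ghk_ratio(2, 98, vm = 40)   # raising K+ 2 -> 98 mM should cut outward current ~19%
#' @export
ghk_ratio <- function(c1_kex, c2_kex, vm, kin = 108.6,
                      temperature = kv_constants[["temperature"]]) {
  if (c1_kex <= 0 || c2_kex <= 0 || kin <= 0)
    .kv_stop("kv_invalid_solution", "concentrations must be positive")
  u <- (vm / 1000) * kv_constants[["faraday"]] /
    (kv_constants[["gas"]] * temperature)
  num <- kin - c1_kex * exp(-u)
  den <- kin - c2_kex * exp(-u)
  if (abs(den) < 1e-9 * kin)
    .kv_stop("kv_singular_ratio",
             "vm is at the reversal potential of the reference condition")
  num / den
}

#' @rdname ghk_ratio
#' @export
ghk_prediction <- function(c1_kex, c2_kex, vm, kin = 108.6,
                           temperature = kv_constants[["temperature"]]) {
  structure(list(c1_kex = c1_kex, c2_kex = c2_kex, kin = kin, vm = vm,
                 temperature = temperature,
                 ratio = ghk_ratio(c1_kex, c2_kex, vm, kin, temperature)),
            class = "ghk_prediction")
}

#' @export
print.ghk_prediction <- function(x, ...) {
  cat(sprintf("<ghk_prediction> I(%g mM)/I(%g mM) = %.4f at Vm %g mV ([K+]in %g mM, T %g K)\n",
              x$c1_kex, x$c2_kex, x$ratio, x$vm, x$kin, x$temperature))
  invisible(x)
}

#' Paradox index: observed vs driving-force-predicted K+ dependence
#'
#' The ratio of an observed current ratio (e.g. peak current at raised over
#' reference \[K+\]ex) to the GHK-predicted ratio for the same pair of
#' solutions. Values above 1 indicate activation by extracellular K+ beyond
#' what the change in driving force allows — the apparently paradoxical
#' K+-dependent increase in outward current.
#'
#' @param observed_ratio observed current ratio I(C1)/I(C2).
#' @param predicted a [ghk_prediction()] or the predicted ratio as a number.
#' @return The paradox index (a number).
#' @export
paradox_index <- function(observed_ratio, predicted) {
  pr <- if (inherits(predicted, "ghk_prediction")) predicted$ratio
        else as.numeric(predicted)
  if (pr <= 0)
    .kv_stop("kv_singular_ratio", "predicted ratio must be positive")
  observed_ratio / pr
}
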