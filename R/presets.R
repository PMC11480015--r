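#' Channel parameter presets
#'
#' A `channel_preset` bundles every gating and permeation parameter of one
#' channel construct: conductance scale, activation and inactivation Boltzmann
#' parameters, activation/deactivation and bi-exponential inactivation time
#' constants, the persistent (non-inactivating) open fraction, recovery
#' kinetics, and the three extracellular-K+ coupling coefficients (inactivation
#' midpoint shift per doubling of \[K+\]ex, recovery speed-up exponent, and
#' ln-linear conductance gain). Packaged presets cover the wild-type channel,
#' the E675K variant, the forced-short (M1I) and forced-long (M77I)
#' alternative-translation-initiation constructs, TBK1-inhibitor kinetic
#' presets, and the dominant-negative R420H subunit.
#'
#' @param name construct name.
#' @param g0 conductance scale (uA-producing, arbitrary units).
#' @param act_v_half,act_k activation Boltzmann midpoint (mV) and slope (mV > 0).
#' @param tau_act,tau_deact activation / deactivation time constants (ms > 0).
#' @param inact_v_half_ref inactivation midpoint (mV) at the reference 2 mM
#'   \[K+\]ex.
#' @param inact_k inactivation slope (mV > 0).
#' @param inact_floor non-zero floor of steady-state availability, in \[0, 1).
#' @param tau_inact_1,tau_inact_2 slow and fast inactivation time constants
#'   (ms); `tau_inact_1 > tau_inact_2`.
#' @param a1_frac weight of the slow inactivation component, A1/(A1+A2).
#' @param persistent_frac non-inactivating fraction of the open current.
#' @param tau_rec_ref recovery-from-inactivation time constant (ms) at 2 mM
#'   \[K+\]ex.
#' @param k_shift_delta inactivation midpoint shift (mV) per doubling of
#'   \[K+\]ex.
#' @param k_rec_gamma recovery speed-up exponent: tau_rec = tau_rec_ref *
#'   (2/kex)^k_rec_gamma.
#' @param k_gain_alpha conductance gain per ln-fold \[K+\]ex.
#' @param poisonous whether the subunit silences tetramers it enters
#'   (dominant-negative behaviour under `mix_presets(mode = "binomial_dn")`).
#' @param source optional named character map recording, per parameter, whether
#'   the value is a reported constant or a synthetic calibration.
#' @return An object of class `channel_preset`.
#' @seealso [load_preset()], [list_presets()], [mix_presets()]
#' @export
channel_preset <- function(name, g0, act_v_half, act_k, tau_act, tau_deact,
                           inact_v_half_ref, inact_k, inact_floor,
                           tau_inact_1, tau_inact_2, a1_frac, persistent_frac,
                           tau_rec_ref, k_shift_delta = 0, k_rec_gamma = 0,
                           k_gain_alpha = 0, poisonous = FALSE,
                           source = NULL) {
  taus <- c(tau_act = tau_act, tau_deact = tau_deact,
            tau_inact_1 = tau_inact_1, tau_inact_2 = tau_inact_2,
            tau_rec_ref = tau_rec_ref)
  if (any(!is.finite(taus)) || any(taus <= 0))
    .kv_stop("kv_invalid_preset", "all time constants must be positive")
  if (g0 < 0)
    .kv_stop("kv_invalid_preset", "g0 must be non-negative")
  if (act_k <= 0 || inact_k <= 0)
    .kv_stop("kv_invalid_preset", "Boltzmann slopes must be positive")
  if (a1_frac < 0 || a1_frac > 1)
    .kv_stop("kv_invalid_preset", "a1_frac must lie in [0, 1]")
  if (inact_floor < 0 || persistent_frac < 0 ||
      inact_floor + persistent_frac >= 1)
    .kv_stop("kv_invalid_preset",
             "inact_floor and persistent_frac must be non-negative with sum < 1")
  structure(list(name = name, g0 = g0, act_v_half = act_v_half, act_k = act_k,
                 tau_act = tau_act, tau_deact = tau_deact,
                 inact_v_half_ref = inact_v_half_ref, inact_k = inact_k,
                 inact_floor = inact_floor, tau_inact_1 = tau_inact_1,
                 tau_inact_2 = tau_inact_2, a1_frac = a1_frac,
                 persistent_frac = persistent_frac, tau_rec_ref = tau_rec_ref,
                 k_shift_delta = k_shift_delta, k_rec_gamma = k_rec_gamma,
                 k_gain_alpha = k_gain_alpha, poisonous = isTRUE(poisonous),
                 source = source),
            class = "channel_preset")
}

#' @export
print.channel_preset <- function(x, ...) {
  cat(sprintf("<channel_preset> %s\n", x$name))
  cat(sprintf("  g0 %g; activation V1/2 %g mV (k %g), tau_act %g / tau_deact %g ms\n",
              x$g0, x$act_v_half, x$act_k, x$tau_act, x$tau_deact))
  cat(sprintf("  inactivation V1/2 %g mV (k %g), tau1 %g / tau2 %g ms, A1 frac %g\n",
              x$inact_v_half_ref, x$inact_k, x$tau_inact_1, x$tau_inact_2,
              x$a1_frac))
  cat(sprintf("  persistent %g, floor %g, tau_rec %g ms; K+ coupling: shift %g mV/doubling, gamma %g, alpha %g\n",
              x$persistent_frac, x$inact_floor, x$tau_rec_ref,
              x$k_shift_delta, x$k_rec_gamma, x$k_gain_alpha))
  if (x$poisonous) cat("  dominant-negative (poisons heteromeric tetramers)\n")
  invisible(x)
}

.preset_dir <- function() system.file("extdata", "presets", package = "kvclamp")

#' List the packaged channel presets
#'
#' @return Character vector of preset names loadable with [load_preset()].
#' @export
list_presets <- function() {
  sort(sub("\\.json$", "", list.files(.preset_dir(), pattern = "\\.json$")))
}

#' Load a channel preset from the package library or a JSON file
#'
#' @param name a packaged preset name (see [list_presets()]) or a path to a
#'   preset JSON file.
#' @return A [channel_preset()].
#' @export
load_preset <- function(name) {
  path <- if (file.exists(name)) name
          else file.path(.preset_dir(), paste0(name, ".json"))
  if (!file.exists(path))
    .kv_stop("kv_unknown_preset",
             sprintf("unknown preset '%s' (available: %s)", name,
                     paste(list_presets(), collapse = ", ")))
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  src <- obj$source
  obj$source <- NULL
  do.call(channel_preset, c(obj, list(source = src)))
}

#' Combine channel presets into an effective co-expression preset
#'
#' Models co-injection of several subunit species. In `"independent"` mode the
#' populations conduct independently and the effective conductance is the
#' fraction-weighted sum of the component conductances (kinetics are taken
#' from the first component; a warning is issued if the components disagree in
#' any non-conductance parameter). In `"binomial_dn"` mode tetramers assemble
#' binomially from the subunit pool and any tetramer containing at least one
#' poisonous (dominant-negative) subunit is silent, so only all-clean
#' tetramers conduct.
#'
#' @param presets list of [channel_preset()]s.
#' @param fractions numeric vector of subunit fractions, summing to 1.
#' @param mode `"independent"` or `"binomial_dn"`.
#' @return A [channel_preset()] with the effective conductance.
#' @export
mix_presets <- function(presets, fractions,
                        mode = c("independent", "binomial_dn")) {
  mode <- match.arg(mode)
  if (length(presets) != length(fractions) || length(presets) < 1)
    .kv_stop("kv_invalid_mixture", "presets and fractions must have equal positive length")
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9)
    .kv_stop("kv_invalid_mixture", "fractions must be non-negative and sum to 1")
  base <- presets[[1]]
  g0s <- vapply(presets, `[[`, numeric(1), "g0")
  kin_fields <- setdiff(names(unclass(base)),
                        c("name", "g0", "source", "poisonous"))
  same <- all(vapply(presets[-1], function(p)
    isTRUE(all.equal(unclass(p)[kin_fields], unclass(base)[kin_fields])),
    logical(1)))
  if (mode == "independent") {
    if (!same)
      warning("mix_presets: components differ beyond g0; kinetics taken from '",
              base$name, "'", call. = FALSE)
    g_eff <- sum(fractions * g0s)
  } else {
    poison <- vapply(presets, `[[`, logical(1), "poisonous")
    p_clean <- sum(fractions[!poison])
    # a tetramer conducts only if all four subunits are clean; conductance of
    # conducting tetramers averages the clean pool
    g_eff <- if (p_clean == 0) 0
             else sum(fractions[!poison] * g0s[!poison]) / p_clean * p_clean^4
  }
  out <- base
  out$name <- paste0("mix(", paste(sprintf("%s:%g",
    vapply(presets, `[[`, character(1), "name"), fractions), collapse = "+"),
    ")[", mode, "]")
  out$g0 <- g_eff
  out$poisonous <- FALSE
  out$source <- NULL
  attr(out, "mixture") <- list(mode = mode, fractions = fractions,
                               components = vapply(presets, `[[`,
                                                   character(1), "name"),
                               kinetics_identical = same)
  out
}
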