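---
title: "Methods: simulating and analysing Kv3.3 voltage-clamp experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing Kv3.3 voltage-clamp experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kvclamp)
```

## Scope and rationale

`kvclamp` packages the complete analysis chain of a classical two-electrode
voltage-clamp (TEVC) characterization of the Kv3.3 potassium channel — the
fast-gating channel of cerebellar Purkinje and granule neurons whose variants
cause spinocerebellar ataxia — together with a synthetic-data generator that
stands in for oocyte recordings. The scientific focus is the contrast between
wild-type Kv3.3 and the E675K variant: a ~30% loss of peak current without
changes in voltage dependence, deeper and faster cumulative inactivation
under repetitive stimulation, slowed recovery from inactivation, and a
partial rescue of all of these by raised extracellular potassium.

Because published TEVC datasets of this kind are figure-based rather than
deposited, the simulator is a first-class, tested component: it defines the
study conditions under which every analysis routine is validated, from
Boltzmann fitting to cumulative-inactivation quantification.

## The gating model

The simulator is a Hodgkin–Huxley-style model, deliberately minimal: it is
the smallest structure that generates every phenomenon the analysis chain
must quantify.

* **Activation.** A single gate `a` with Boltzmann steady state
  $a_\infty(V) = 1/(1+e^{(V_{1/2}^{act}-V)/k_{act}})$. Using an activation
  exponent of 1 (rather than the Hodgkin–Huxley $n^4$) means a fitted GV
  curve recovers `act_v_half` directly, which keeps pipeline validation
  interpretable: a GV fit that returns the preset's midpoint is evidence the
  tail-current pipeline is unbiased, with no exponent-induced offset to
  reason away.
* **Inactivation.** Two availability gates $h_1, h_2$ (slow and fast) share
  one steady state $h_\infty(V)$ — a Boltzmann with a non-zero floor — but
  relax with distinct time constants `tau_inact_1 > tau_inact_2`. Their
  weighted sum (weights `a1_frac`, `1 − a1_frac`), plus a persistent
  fraction that bypasses inactivation entirely, composes the open
  probability
  $$p_{open} = a\,[\,p_{pers} + (1-p_{pers})(w_1 h_1 + (1-w_1) h_2)\,].$$
  This is the minimal structure producing genuinely bi-exponential decay
  with a controllable amplitude fraction, and setting $p_{pers} = 1$
  reproduces an exactly non-inactivating channel — which is how the
  forced-short (M1I) construct lacking the N-terminal inactivation ball is
  modelled.
* **Permeation.** Open-channel current follows the Goldman–Hodgkin–Katz flux
  $u\,([K]_{in} - [K]_{ex}e^{-u})/(1-e^{-u})$, $u = VF/RT$, so reversal
  potentials, tail-current driving forces and the K⁺ dependence of current
  amplitudes are thermodynamically consistent by construction. The absolute
  conductance scale `g0` is arbitrary (chosen to give µA-scale currents);
  every analysis in the package is on normalized quantities.
* **Extracellular-potassium coupling.** Three phenomenological couplings
  carry the K⁺ effects: the inactivation midpoint shifts by `k_shift_delta`
  mV per doubling of $[K^+]_{ex}$ relative to the 2 mM reference
  (destabilized inactivation), the recovery time constant scales as
  $\tau_{rec} = \tau_{rec}^{ref}(2/[K^+]_{ex})^{\gamma}$ (faster recovery in
  high K⁺), and conductance gains a factor $1 + \alpha\ln([K^+]_{ex}/2)$
  (the paradoxical activation). The functional forms are the package's own
  modelling choice — log-linear and power-law laws are the standard
  minimal parameterizations — and their coefficients live in the preset
  JSON files, not in code, flagged as synthetic calibrations in each
  preset's `source` map. They are calibrated only to reproduce the
  qualitative orderings (monotone rescue with K⁺, paradox index above 1),
  not any quantitative K⁺ dose–response.

### Integration

All rates are piecewise-constant in voltage, so each segment of a protocol
is integrated *exactly*: $x(t) = x_\infty + (x_0 - x_\infty)e^{-t/\tau}$ per
gate per segment, evaluated on the sampling grid. There is no ODE solver, no
step-size error, and noise-free runs are deterministic to machine precision —
which is what makes 1e−6-level equivalence tests against an independently
coded closed-form oracle meaningful.

The two kinetic regimes are separated at −40 mV: above it the activation
gate uses `tau_act` and the inactivation gates use `tau_inact_1/2`; at and
below it the activation gate deactivates with `tau_deact` and the
inactivation gates recover with the K⁺-dependent `tau_rec`. The boundary
voltage is a documented constant. −40 mV itself is assigned to the
hyperpolarized regime: the standard tail step sits at exactly −40 mV, and a
tail must deactivate — if −40 mV used the (sub-millisecond) activation
constant, tail currents would collapse toward their steady state within the
capacitive blank and would no longer report the open probability reached
during the test step (in practice this misplaces fitted GV midpoints by
several millivolts).

### Presets

Seven constructs ship with the package. Parameters marked `reported` in a
preset's `source` map are transcribed constants from the published
characterization this package models (the bi-exponential constants of the
TBK1-inhibitor conditions: τ₁ = 144 ms, τ₂ = 50 ms, A₁/(A₁+A₂) = 0.3 for the
forced-long channel and τ₁ = 136 ms, τ₂ = 43 ms for its E675K counterpart;
the 0.7× conductance of E675K; the +5 mV GV shift of both
alternative-translation-initiation constructs). Everything else is a
synthetic calibration chosen once at design time to be typical for Kv3.3:
activation midpoint +5 mV with an 8 mV slope, sub-millisecond activation
(τ = 0.6 ms — Kv3 channels are among the fastest-activating Kv channels),
20 ms deactivation, inactivation midpoint −25 mV (5 mV slope) with a 5%
availability floor, 400/150 ms inactivation constants for the wild type,
800 ms reference recovery, and K⁺ couplings of 6 mV per doubling, γ = 0.5
and α = 0.3. The E675K preset additionally slows recovery 1.5× and lowers
the availability floor — the mechanistic reading of its deeper cumulative
inactivation. The dominant-negative R420H subunit is non-conducting and
flagged `poisonous`; under `mix_presets(..., mode = "binomial_dn")` tetramers
assemble binomially and any tetramer containing it is silent, so a 50/50
co-injection leaves $0.5^4 = 6.25\%$ of wild-type current, against 85% for
the non-dominant-negative E675K mixture in `independent` mode.

### Noise model and reproducibility

Three nuisance components emulate real recordings: additive Gaussian current
noise (default 0.02 µA), a lognormal per-oocyte expression factor (mean 1,
CV 0.2 — moderate scatter, as after pre-selecting healthy oocytes), and an
optional ohmic leak. One root seed drives everything; per-oocyte streams are
derived by a counter so enlarging a batch never reshuffles earlier oocytes,
and `run_experiment()` additionally offsets the stream per experimental
group so constructs are simulated with independent noise (otherwise matched
seeds would make expression factors cancel exactly in normalized
comparisons, flattering the statistics).

## Analysis choices

* **Feature extraction.** Peaks are signed extrema in the expected current
  direction (outward above $E_K$); the end-of-step current is the mean over
  the final 5% of the segment (the protocol text this mirrors says only "at
  the end of the step", and a short mean is robust to noise); tail peaks are
  searched in the first 50 ms of the tail after a 2 ms capacitive blank.
  Peak searches accept a boxcar pre-filter (`smooth_ms`): a raw extremum is
  an upward-biased statistic on noisy traces, and because smoothing is
  linear it preserves the cross-sweep proportionality on which tail analysis
  rests. `gv_curve()` defaults to a 5 ms boxcar — a quarter of the
  deactivation time constant — which removes essentially all of the bias at
  the default noise level while leaving noise-free results unchanged to
  within the fitting tolerances.
* **The recovery statistic.** The relative recovered current is
  $(I_{2max} - I_{1min})/(I_{1max} - I_{1min})$: 0 with no recovery, rising
  to 1 at full recovery, matching recovery curves that saturate at 1. The
  reciprocal orientation $(I_{1max} - I_{1min})/(I_{2max} - I_{1min})$,
  which some write-ups print, exceeds 1 for partial recovery and *falls*
  toward 1 with the interval; it is available behind
  `orientation = "as_printed"` and the flag is recorded in outputs.
* **Exponential fits.** Bounded Levenberg–Marquardt (`minpack.lm::nlsLM`)
  with log-linear peeling initialization: the offset and slow component are
  estimated from the late part of the decay on a log scale, the fast
  component from the early residual, followed by a small grid of scaled
  restarts. τ₁ > τ₂ is enforced by a post-fit swap; near-equal constants
  (ratio < 1.5) or a vanishing component set identifiability flags instead
  of failing. The test suite cross-checks the fitter against a brute-force
  grid-plus-refinement oracle that shares no code with it.
* **Boltzmann fits.** Activation fixes the asymptote at 1 (curves are
  max-normalized); inactivation frees a base parameter for the
  non-inactivating floor. Flat curves raise an unidentifiability error
  rather than returning arbitrary midpoints.
* **Cumulative inactivation.** End-of-pulse currents normalized to the
  largest pulse (the first, on clean data); τ from a mono-exponential fit to
  pulses starting within 2 s — reported as `NA` with a flag when fewer than
  4 pulses fall in the window (the 1 Hz case), since a three-parameter fit
  on 3 points is meaningless; the relative current after 10 s is the last
  pulse at or before 10 s.
* **Train timing.** The "inter-sweep interval" of the pulse train is the
  pulse start-to-start period (the `period` dialect): the conventional
  frequency listing (100 Hz = 10 ms) is only consistent with a 5 ms pulse
  if the interval is the period, not the gap. A `gap` dialect is selectable,
  and the flag travels with every protocol and report.
* **Recovery-interval convention.** The first twin-pulse interval is 20 ms
  and the 500 ms increment applies from sweep 2 (Δt = 20, 520, …, 8020 ms);
  the convention is recorded in the protocol metadata.
* **Statistics.** Mean ± s.e.m.; two-group comparisons use Welch's
  unequal-variance t-test — group variances genuinely differ when
  conductance scales differ — with the conventional star mapping. The suite
  verifies the test's type-I error at the nominal 5% level by simulation.
* **Holding settle.** Every sweep is prefixed with a 100 ms holding segment
  so gates settle before the step (only the first pulse of a train, so the
  period is preserved); the duration is configurable.

## What the generator does and does not emulate

It emulates: voltage-step currents of a fast-activating, bi-exponentially
inactivating Kv channel; seconds-scale recovery; oocyte-to-oocyte expression
scatter; leak and recording noise; K⁺-dependent amplitude gain, inactivation
destabilization and recovery speed-up; and state carry-over across 1–100 Hz
pulse trains with analytic inter-sweep relaxation.

It does not emulate: capacitive transients (the analysis blanks them anyway,
and the blank is configurable so injected transients could be handled);
series-resistance and space-clamp errors; temperature (Q10) effects;
single-channel stochasticity; drift, endogenous currents, or run-down; or
any biochemistry of the TBK1/Hax-1 modulation pathway — the TBK1-inhibitor
conditions are purely kinetic presets. Passing tests therefore demonstrate
that the analysis chain is correct and unbiased *under the model's
assumptions*; they cannot certify behaviour against artefacts the model
does not contain.

## Numerical and test-scale choices

Sampling defaults to 10 kHz (typical for TEVC; not part of the protocol
definitions, so it is configurable per builder). Long-running validation
simulations in the test suite use reduced rates — 5 kHz for 10 s pulse
trains and inactivation families, 2 kHz for GV batches, 1 kHz for the
recovery protocol, whose slowest time constants are hundreds of
milliseconds — chosen so that discretization contributes errors well below
the tolerances being asserted. Bias checks of the noisy GV pipeline use 12
seeded replicates of 10 oocytes. Degenerate inputs (zero-conductance
channels, flat curves, missing reference constructs, windows outside a
segment, infeasible train frequencies) raise classed errors
(`kv_degenerate_trace`, `kv_fit_failure`, `kv_missing_reference`,
`kv_window_bounds`, `kv_infeasible_frequency`) rather than silently
returning numbers.

## Known limitations

The K⁺-coupling laws are calibrated to orderings, not dose–response values;
quantitative K⁺ titration outputs should be read as model predictions, not
reconstructions. The shared steady state of the two inactivation gates means
the model cannot represent constructs whose slow and fast components have
different voltage dependence. Tail-peak extraction assumes the tail's decay
shape is sweep-independent (true in the model, approximate in real data with
voltage-dependent deactivation). And because the conductance scale is
arbitrary, absolute current amplitudes carry no information — only
normalized comparisons are meaningful.
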