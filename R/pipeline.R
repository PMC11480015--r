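#' Run a figure-style end-to-end experiment
#'
#' Composes the simulator and the analysis stages into the standard
#' experiment recipes:
#'
#' * `amplitude_comparison` — peak current amplitudes of several constructs
#'   under the 200 ms amplitude protocol, batch-normalized to the first
#'   (reference) preset, with Welch-test comparisons.
#' * `coinjection` — heterozygous-state models: a 50/50 wild-type + variant
#'   mix combined in `independent` mode and a 50/50 wild-type +
#'   dominant-negative mix in `binomial_dn` mode, against pure wild-type.
#' * `gv_family` — tail-current GV curves and activation Boltzmann fits per
#'   preset.
#' * `inactivation_family` — availability curves and inactivation Boltzmann
#'   fits (10 s conditioning steps are chosen automatically for essentially
#'   non-inactivating presets).
#' * `recovery` — twin-pulse recovery curves and mono-exponential recovery
#'   time constants.
#' * `kex_titration` — K+ dependence: peak current at +40 mV, GV midpoint
#'   (with the K+-adjusted tail step), inactivation midpoint and recovery
#'   time constant across bath K+ concentrations, plus GHK-predicted current
#'   ratios and paradox indices relative to 2 mM.
#' * `train_family` — cumulative inactivation over a frequency x \[K+\]ex
#'   grid: per-pulse relative currents, the time constant of the first 2 s
#'   and the relative current after 10 s of pulsing.
#'
#' @param experiment recipe name (see above).
#' @param presets character vector of preset names (defaults depend on the
#'   recipe).
#' @param kex extracellular K+ concentration(s), mM.
#' @param frequencies train frequencies (Hz), `train_family` only.
#' @param n_oocytes oocytes per group.
#' @param noise a [noise_spec()]; [noise_free()] gives exact deterministic
#'   runs.
#' @param eq1_orientation orientation flag for [recovery_ratio()].
#' @param train_dialect inter-sweep-interval dialect for [train_protocol()].
#' @param sampling_khz sampling rate used for all simulated protocols.
#' @param train_total_s train duration in seconds (`train_family`).
#' @return An object of class `experiment_report`: the echoed configuration,
#'   seed, package version and the recipe's result tables.
#' @export
run_experiment <- function(experiment = c("amplitude_comparison", "coinjection",
                                          "gv_family", "inactivation_family",
                                          "recovery", "kex_titration",
                                          "train_family"),
                           presets = NULL, kex = 2,
                           frequencies = c(1, 10, 50, 100),
                           n_oocytes = 8, noise = noise_spec(),
                           eq1_orientation = c("corrected", "as_printed"),
                           train_dialect = c("period", "gap"),
                           sampling_khz = 10, train_total_s = 10) {
  experiment <- match.arg(experiment)
  eq1_orientation <- match.arg(eq1_orientation)
  train_dialect <- match.arg(train_dialect)
  if (n_oocytes < 1) .kv_stop("kv_invalid_batch", "n_oocytes must be >= 1")
  if (is.null(presets))
    presets <- switch(experiment,
                      amplitude_comparison = c("wt", "e675k"),
                      coinjection = c("wt", "e675k", "r420h"),
                      train_family = c("wt", "e675k"),
                      kex_titration = c("wt", "e675k"),
                      c("wt", "e675k", "m1i", "m77i"))
  loaded <- lapply(presets, load_preset)
  names(loaded) <- presets
  config <- list(experiment = experiment, presets = presets, kex = kex,
                 frequencies = frequencies, n_oocytes = n_oocytes,
                 noise = unclass(noise), eq1_orientation = eq1_orientation,
                 train_dialect = train_dialect, sampling_khz = sampling_khz)
  sol <- function(k) solution_spec(kex = k)
  # distinct random stream per experimental group so noise and expression
  # scatter are independent between constructs / conditions
  grp <- local({
    counter <- 0L
    function() {
      counter <<- counter + 1L
      ns <- noise
      ns$seed <- (noise$seed + 7919L * (counter - 1L)) %% 2147483629L
      ns
    }
  })

  group_peaks <- function(preset, protocol, solution) {
    batch <- make_batch(preset, protocol, solution, n_oocytes, grp())
    vapply(batch, function(ts) extract_features(ts, smooth_ms = 2)$peak,
           numeric(1))
  }
  group_curve_fit <- function(preset, protocol, solution, curve_fun, direction) {
    batch <- make_batch(preset, protocol, solution, n_oocytes, grp())
    cv <- average_curves(lapply(batch, curve_fun))
    fit_boltzmann(cv[[1]], cv$y, direction)
  }

  results <- switch(experiment,
    amplitude_comparison = {
      prot <- amplitude_protocol(sampling_khz = sampling_khz)
      peaks <- lapply(loaded, group_peaks, protocol = prot,
                      solution = sol(kex[1]))
      tab <- normalize_batch(
        data.frame(construct = rep(presets, lengths(peaks)),
                   value = unlist(peaks)), reference = presets[1])
      means <- tapply(tab$normalized, tab$construct, mean)[presets]
      stats <- if (n_oocytes >= 2 && length(presets) >= 2)
        lapply(presets[-1], function(p)
          summarize_groups(peaks[[presets[1]]], peaks[[p]]))
      else NULL
      list(amplitudes = tab,
           normalized_means = data.frame(construct = presets,
                                         normalized_mean = as.numeric(means)),
           percent_reduction = 100 * (1 - as.numeric(means)),
           comparisons = stats)
    },
    coinjection = {
      prot <- amplitude_protocol(sampling_khz = sampling_khz)
      wt <- loaded[[1]]
      mixes <- list(
        wt = wt,
        het_independent = suppressWarnings(
          mix_presets(list(wt, loaded[[2]]), c(0.5, 0.5), "independent")),
        het_dominant_negative =
          mix_presets(list(wt, loaded[[3]]), c(0.5, 0.5), "binomial_dn"))
      peaks <- lapply(mixes, group_peaks, protocol = prot,
                      solution = sol(kex[1]))
      tab <- normalize_batch(
        data.frame(construct = rep(names(mixes), lengths(peaks)),
                   value = unlist(peaks)), reference = "wt")
      means <- tapply(tab$normalized, tab$construct, mean)[names(mixes)]
      list(amplitudes = tab,
           normalized_means = data.frame(construct = names(mixes),
                                         normalized_mean = as.numeric(means)))
    },
    gv_family = {
      fits <- lapply(loaded, function(p)
        group_curve_fit(p, gv_protocol(kex[1], sampling_khz = sampling_khz),
                        sol(kex[1]), gv_curve, "activation"))
      list(fits = fits,
           table = data.frame(construct = presets,
                              v_half = vapply(fits, `[[`, numeric(1), "v_half"),
                              k = vapply(fits, `[[`, numeric(1), "k")))
    },
    inactivation_family = {
      fits <- lapply(loaded, function(p) {
        long <- p$persistent_frac > 0.5
        group_curve_fit(p,
                        inactivation_protocol(long_steps = long,
                                              sampling_khz = sampling_khz),
                        sol(kex[1]), inactivation_curve, "inactivation")
      })
      list(fits = fits,
           table = data.frame(construct = presets,
                              v_half = vapply(fits, `[[`, numeric(1), "v_half"),
                              k = vapply(fits, `[[`, numeric(1), "k")))
    },
    recovery = {
      out <- lapply(loaded, function(p) {
        batch <- make_batch(p, recovery_protocol(sampling_khz = sampling_khz),
                            sol(kex[1]), n_oocytes, grp())
        cv <- average_curves(lapply(batch, recovery_curve,
                                    orientation = eq1_orientation))
        fit <- fit_monoexp(cv$delta_t, cv$y, "rising")
        list(curve = cv, fit = fit, tau_rec = fit$tau1)
      })
      list(per_preset = out,
           table = data.frame(construct = presets,
                              tau_rec = vapply(out, function(o) o$tau_rec,
                                               numeric(1))))
    },
    kex_titration = {
      ref_kex <- 2
      per_preset <- lapply(loaded, function(p) {
        rows <- lapply(kex, function(k) {
          s <- sol(k)
          step40 <- voltage_protocol(
            "step40",
            list(protocol_sweep(list(.hold_prefix(100, -80),
                                     voltage_segment(200, 40, "test")),
                                label_voltage = 40)),
            inter_sweep_ms = 7000, sampling_khz = sampling_khz)
          pk <- mean(group_peaks(p, step40, s))
          gvf <- group_curve_fit(p, gv_protocol(k, sampling_khz = sampling_khz),
                                 s, gv_curve, "activation")
          inf <- group_curve_fit(p,
                                 inactivation_protocol(sampling_khz = sampling_khz),
                                 s, inactivation_curve, "inactivation")
          batch <- make_batch(p, recovery_protocol(sampling_khz = sampling_khz),
                              s, n_oocytes, grp())
          rcv <- average_curves(lapply(batch, recovery_curve,
                                       orientation = eq1_orientation))
          data.frame(kex = k, peak_40mV = pk, gv_v_half = gvf$v_half,
                     inact_v_half = inf$v_half,
                     tau_rec = fit_monoexp(rcv$delta_t, rcv$y, "rising")$tau1)
        })
        tab <- do.call(rbind, rows)
        ref_peak <- tab$peak_40mV[tab$kex == ref_kex]
        if (length(ref_peak) == 1) {
          tab$observed_ratio <- tab$peak_40mV / ref_peak
          tab$ghk_predicted_ratio <- vapply(tab$kex, function(k)
            ghk_ratio(k, ref_kex, vm = 40), numeric(1))
          tab$paradox_index <- tab$observed_ratio / tab$ghk_predicted_ratio
        }
        tab
      })
      list(per_preset = per_preset, reference_kex = ref_kex)
    },
    train_family = {
      grid <- expand.grid(preset = presets, frequency = frequencies,
                          kex = kex, stringsAsFactors = FALSE)
      res <- lapply(seq_len(nrow(grid)), function(i) {
        p <- loaded[[grid$preset[i]]]
        prot <- train_protocol(grid$frequency[i], total_s = train_total_s,
                               sampling_khz = sampling_khz,
                               dialect = train_dialect)
        ts <- simulate_protocol(p, prot, sol(grid$kex[i]), noise = grp(),
                                carry_state = TRUE)
        cumulative_inactivation(ts)
      })
      grid$tau_first_2s <- vapply(res, `[[`, numeric(1), "tau_first_2s")
      grid$relative_current_10s <- vapply(res, `[[`, numeric(1),
                                          "relative_current_10s")
      list(results = res, table = grid)
    })

  structure(list(experiment = experiment, config = config,
                 seed = noise$seed,
                 version = as.character(utils::packageVersion("kvclamp")),
                 results = results),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %s (kvclamp %s, seed %d)\n",
              x$experiment, x$version, x$seed))
  cat(sprintf("  presets: %s | [K+]ex: %s mM | n = %d per group\n",
              paste(x$config$presets, collapse = ", "),
              paste(x$config$kex, collapse = ", "), x$config$n_oocytes))
  tab <- x$results$table
  if (is.null(tab)) tab <- x$results$normalized_means
  if (!is.null(tab)) { cat("\n"); print(tab, row.names = FALSE) }
  invisible(x)
}

#' Write an experiment report to a directory
#'
#' Serializes the report as a JSON file (configuration, seed, version, scalar
#' results) plus tidy CSV tables for the tabular results.
#'
#' @param report an `experiment_report`.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "experiment_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scalars <- report$results[!vapply(report$results, is.data.frame, logical(1))]
  drop <- vapply(scalars, function(x)
    is.list(x) && any(vapply(x, function(e)
      inherits(e, c("exp_fit", "boltzmann_fit", "cumulative_result", "list")),
      logical(1))), logical(1))
  json <- list(experiment = report$experiment, config = report$config,
               seed = report$seed, version = report$version,
               results = scalars[!drop])
  writeLines(jsonlite::toJSON(json, auto_unbox = TRUE, digits = 10,
                              pretty = TRUE, null = "null", force = TRUE),
             file.path(dir, "report.json"))
  for (nm in names(report$results)) {
    if (is.data.frame(report$results[[nm]]))
      utils::write.csv(report$results[[nm]],
                       file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  invisible(dir)
}
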