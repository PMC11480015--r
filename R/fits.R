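#' Exponential time-constant fits
#'
#' `fit_monoexp()` fits \eqn{y = c + A e^{-x/\tau}} (decaying) or
#' \eqn{y = c - A e^{-x/\tau}} (rising, the form of recovery curves);
#' `fit_biexp()` fits \eqn{y = c + A_1 e^{-x/\tau_1} + A_2 e^{-x/\tau_2}}
#' with the ordering convention \eqn{\tau_1 > \tau_2} (slow component first)
#' and reports the slow-component amplitude fraction
#' \eqn{A_1/(A_1+A_2)}. Fitting is bounded Levenberg-Marquardt least squares
#' (via \pkg{minpack.lm}), initialized by log-linear peeling: the offset and
#' slow component are estimated from the late part of the curve on a log
#' scale, then the fast component from the early residual; a small grid of
#' scaled restarts guards against bad starts. Near-equal time constants set
#' an identifiability flag instead of failing.
#'
#' @param x,y numeric vectors; `x` strictly increasing (ms for time fits).
#' @param direction `"decaying"` or `"rising"`.
#' @return An object of class `exp_fit` with fields `tau1`, `tau2` (`NA` for
#'   mono-exponential), `a1`, `a2`, `a1_fraction`, `offset`, `rss`,
#'   `n_points`, `converged` and `flags`.
#' @examples
#' x <- seq(0, 4000, by = 25)
#' f <- fit_monoexp(x, 1 - exp(-x / 800), direction = "rising")
#' coef(f)[["tau1"]]   # 800
#' @export
fit_monoexp <- function(x, y, direction = c("decaying", "rising")) {
  direction <- match.arg(direction)
  .check_fit_input(x, y, 4)
  if (stats::sd(y) < 1e-12 * (abs(mean(y)) + 1e-12))
    .kv_stop("kv_fit_failure", "constant data: time constant unidentifiable")
  s <- if (direction == "decaying") 1 else -1
  yy <- s * y                       # decaying in both cases
  off0 <- mean(utils::tail(yy, max(2L, round(0.05 * length(yy)))))
  amp0 <- max(yy[1] - off0, 1e-8 * max(abs(yy)))
  pos <- yy - off0 > amp0 * 0.02
  tau0 <- if (sum(pos) >= 2)
    -1 / stats::coef(stats::lm(log(yy[pos] - off0) ~ x[pos]))[[2]]
  else diff(range(x)) / 3
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- diff(range(x)) / 3
  best <- NULL
  for (f in c(1, 0.3, 3, 0.1, 10)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(yy ~ off + A * exp(-x / tau),
                        start = list(off = off0, A = amp0, tau = tau0 * f),
                        lower = c(-Inf, 0, 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    .kv_stop("kv_fit_failure", "mono-exponential fit did not converge")
  co <- stats::coef(best$fit)
  .exp_fit(tau1 = co[["tau"]], tau2 = NA_real_,
           a1 = s * co[["A"]], a2 = NA_real_, a1_fraction = 1,
           offset = s * co[["off"]], rss = best$rss, n = length(x),
           flags = character(0), x = x, y = y,
           model = paste0("monoexp_", direction))
}

#' @rdname fit_monoexp
#' @export
fit_biexp <- function(x, y) {
  .check_fit_input(x, y, 8)
  n <- length(x)
  off0 <- mean(utils::tail(y, max(2L, round(0.02 * n))))
  # peel the slow component from the late half of the decay
  late <- x > stats::median(x) & (y - off0) > 0
  tau1_0 <- if (sum(late) >= 2)
    -1 / stats::coef(stats::lm(log(y[late] - off0) ~ x[late]))[[2]]
  else diff(range(x)) / 3
  if (!is.finite(tau1_0) || tau1_0 <= 0) tau1_0 <- diff(range(x)) / 3
  a1_0 <- max((y - off0)[which.max(x >= min(x))] * 0.4, 1e-8)
  resid0 <- y - off0 - a1_0 * exp(-x / tau1_0)
  early <- x < stats::median(x) & resid0 > 0
  tau2_0 <- if (sum(early) >= 2)
    -1 / stats::coef(stats::lm(log(resid0[early]) ~ x[early]))[[2]]
  else tau1_0 / 5
  if (!is.finite(tau2_0) || tau2_0 <= 0) tau2_0 <- tau1_0 / 5
  a2_0 <- max(y[1] - off0 - a1_0, 1e-8)

  starts <- expand.grid(f1 = c(1, 0.5, 2, 4), f2 = c(1, 0.3))
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ off + A1 * exp(-x / t1) + A2 * exp(-x / t2),
        start = list(off = off0, A1 = a1_0, t1 = tau1_0 * starts$f1[k],
                     A2 = a2_0, t2 = tau2_0 * starts$f2[k]),
        lower = c(-Inf, 0, 1e-6, 0, 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    .kv_stop("kv_fit_failure", "bi-exponential fit did not converge")
  co <- stats::coef(best$fit)
  t1 <- co[["t1"]]; t2 <- co[["t2"]]; a1 <- co[["A1"]]; a2 <- co[["A2"]]
  if (t2 > t1) { tmp <- t1; t1 <- t2; t2 <- tmp; tmp <- a1; a1 <- a2; a2 <- tmp }
  flags <- character(0)
  if (t1 / t2 < 1.5)
    flags <- c(flags, "near_equal_time_constants")
  if (a2 < 1e-3 * (a1 + a2) || a1 < 1e-3 * (a1 + a2))
    flags <- c(flags, "effectively_monoexponential")
  .exp_fit(tau1 = t1, tau2 = t2, a1 = a1, a2 = a2,
           a1_fraction = a1 / (a1 + a2), offset = co[["off"]],
           rss = best$rss, n = n, flags = flags, x = x, y = y,
           model = "biexp")
}

.check_fit_input <- function(x, y, nmin) {
  if (length(x) != length(y) || length(x) < nmin)
    .kv_stop("kv_fit_failure",
             sprintf("need at least %d (x, y) points", nmin))
  if (any(diff(x) <= 0))
    .kv_stop("kv_fit_failure", "x must be strictly increasing")
}

.exp_fit <- function(tau1, tau2, a1, a2, a1_fraction, offset, rss, n,
                     flags, x, y, model) {
  structure(list(tau1 = tau1, tau2 = tau2, a1 = a1, a2 = a2,
                 a1_fraction = a1_fraction, offset = offset, rss = rss,
                 n_points = n, converged = TRUE, flags = flags,
                 model = model, data = list(x = x, y = y)),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  if (is.na(x$tau2)) {
    cat(sprintf("<exp_fit> %s: tau = %.4g ms, amplitude %.4g, offset %.4g (rss %.3g, n %d)\n",
                x$model, x$tau1, x$a1, x$offset, x$rss, x$n_points))
  } else {
    cat(sprintf("<exp_fit> biexp: tau1 = %.4g ms, tau2 = %.4g ms, A1/(A1+A2) = %.3f, offset %.4g (rss %.3g, n %d)\n",
                x$tau1, x$tau2, x$a1_fraction, x$offset, x$rss, x$n_points))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.exp_fit <- function(object, ...) {
  c(tau1 = object$tau1, tau2 = object$tau2, a1 = object$a1, a2 = object$a2,
    a1_fraction = object$a1_fraction, offset = object$offset)
}

#' @export
predict.exp_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x
       else if (is.list(newdata)) newdata$x else newdata
  if (is.na(object$tau2)) {
    if (object$model == "monoexp_rising")
      object$offset + object$a1 * exp(-x / object$tau1)  # a1 carries the sign
    else object$offset + object$a1 * exp(-x / object$tau1)
  } else {
    object$offset + object$a1 * exp(-x / object$tau1) +
      object$a2 * exp(-x / object$tau2)
  }
}

#' @export
plot.exp_fit <- function(x, ...) {
  graphics::plot(x$data$x, x$data$y, pch = 16, cex = 0.5,
                 xlab = "x", ylab = "y", ...)
  xs <- seq(min(x$data$x), max(x$data$x), length.out = 300)
  graphics::lines(xs, predict(x, xs), col = "red3", lwd = 2)
  invisible(x)
}

#' Boltzmann fit of a conductance-voltage or availability curve
#'
#' Activation fits \eqn{y = 1/(1 + e^{(V_{1/2} - V)/k})}; inactivation fits
#' \eqn{y = base + (1 - base)/(1 + e^{(V - V_{1/2})/k})} with a free
#' non-inactivating base. Both return the half-maximal voltage \eqn{V_{1/2}}
#' and the slope factor \eqn{k} (mV, positive by convention).
#'
#' @param v test voltages (mV), strictly increasing.
#' @param y normalized responses on a \[0, 1\] scale.
#' @param direction `"activation"` or `"inactivation"`.
#' @return An object of class `boltzmann_fit` with fields `v_half`, `k`,
#'   `base` (inactivation only), `direction`, `rss`, `n_points`.
#' @examples
#' v <- seq(-70, 60, 10)
#' f <- fit_boltzmann(v, 1 / (1 + exp((-5 - v) / 8)), "activation")
#' coef(f)   # v_half -5, k 8
#' @export
fit_boltzmann <- function(v, y, direction = c("activation", "inactivation")) {
  direction <- match.arg(direction)
  .check_fit_input(v, y, 4)
  if (max(y) - min(y) < 1e-6)
    .kv_stop("kv_fit_failure", "flat curve: Boltzmann parameters unidentifiable")
  vh0 <- v[which.min(abs(y - (max(y) + min(y)) / 2))]
  k0 <- max(diff(range(v)) / 8, 1)
  fit <- NULL
  for (f in c(1, 0.5, 2)) {
    fit <- tryCatch({
      if (direction == "activation")
        minpack.lm::nlsLM(y ~ 1 / (1 + exp((vh - v) / k)),
                          start = list(vh = vh0, k = k0 * f),
                          lower = c(-150, 0.1),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      else
        minpack.lm::nlsLM(y ~ base + (1 - base) / (1 + exp((v - vh) / k)),
                          start = list(base = max(min(y), 0), vh = vh0,
                                       k = k0 * f),
                          lower = c(0, -150, 0.1), upper = c(0.99, 100, 100),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
    }, error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    .kv_stop("kv_fit_failure", "Boltzmann fit did not converge")
  co <- stats::coef(fit)
  structure(list(v_half = co[["vh"]], k = co[["k"]],
                 base = if (direction == "inactivation") co[["base"]] else 0,
                 direction = direction, rss = sum(stats::resid(fit)^2),
                 n_points = length(v), converged = TRUE,
                 data = list(v = v, y = y)),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("<boltzmann_fit> %s: V1/2 = %.2f mV, k = %.2f mV%s (rss %.3g, n %d)\n",
              x$direction, x$v_half, x$k,
              if (x$direction == "inactivation")
                sprintf(", base = %.3f", x$base) else "",
              x$rss, x$n_points))
  invisible(x)
}

#' @export
coef.boltzmann_fit <- function(object, ...) {
  c(v_half = object$v_half, k = object$k, base = object$base)
}

#' @export
predict.boltzmann_fit <- function(object, newdata = NULL, ...) {
  v <- if (is.null(newdata)) object$data$v
       else if (is.list(newdata)) newdata$v else newdata
  if (object$direction == "activation")
    1 / (1 + exp((object$v_half - v) / object$k))
  else
    object$base + (1 - object$base) /
      (1 + exp((v - object$v_half) / object$k))
}

#' @export
plot.boltzmann_fit <- function(x, ...) {
  graphics::plot(x$data$v, x$data$y, pch = 16,
                 xlab = "V (mV)", ylab = "normalized response", ...)
  vs <- seq(min(x$data$v), max(x$data$v), length.out = 300)
  graphics::lines(vs, predict(x, vs), col = "red3", lwd = 2)
  graphics::abline(v = x$v_half, lty = 3)
  invisible(x)
}
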