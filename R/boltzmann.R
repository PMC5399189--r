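#' Fit a single Boltzmann activation curve
#'
#' Least-squares fit of `G(V) = G_max / (1 + exp(-(V - V_half) / k))` to a
#' (normalized) conductance-voltage relation, the standard description of
#' voltage-dependent channel opening. Fitting is by Levenberg-Marquardt from
#' multiple starts on a coarse `(V_half, k)` grid (for each start `G_max`
#' is initialized from the largest conductance), keeping the best
#' converged solution; with `k > 0` the curve rises with depolarization.
#'
#' @param voltages test potentials (mV), at least 4 spanning the rising
#'   phase.
#' @param g_norm conductances at `voltages` (normalized or in nS).
#' @param v_half_grid,k_grid multi-start grids for the two shape parameters.
#' @return an object of class `boltzmann_fit` with elements `coefficients`
#'   (`g_max`, `v_half`, `slope_k`), `residual_norm`, `converged`,
#'   `fitted`, `data`.
#' @examples
#' V <- seq(-40, 60, 10)
#' g <- 1 / (1 + exp(-(V - 8) / 12))
#' coef(boltzmann_fit(V, g))
#' @export
boltzmann_fit <- function(voltages, g_norm,
                          v_half_grid = seq(-40, 40, 10),
                          k_grid = c(5, 10, 15, 25)) {
  if (length(voltages) != length(g_norm))
    stop_param("voltages and g_norm must have equal length")
  ok <- is.finite(voltages) & is.finite(g_norm)
  voltages <- voltages[ok]; g_norm <- g_norm[ok]
  if (length(voltages) < 4) stop_param("need >= 4 finite points to fit")

  dat <- data.frame(V = voltages, g = g_norm)
  gm0 <- max(g_norm)
  best <- NULL
  for (vh0 in v_half_grid) {
    for (k0 in k_grid) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          g ~ gm / (1 + exp(-(V - vh) / k)),
          data = dat,
          start = list(gm = gm0, vh = vh0, k = k0),
          lower = c(gm = 0, vh = -200, k = 1e-3),
          upper = c(gm = Inf, vh = 200, k = 200),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(fit)) next
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    return(structure(list(
      coefficients = c(g_max = NA_real_, v_half = NA_real_, slope_k = NA_real_),
      residual_norm = Inf, converged = FALSE,
      fitted = rep(NA_real_, length(voltages)),
      data = dat
    ), class = "boltzmann_fit"))
  }
  cf <- stats::coef(best$fit)
  structure(list(
    coefficients = c(g_max = unname(cf["gm"]), v_half = unname(cf["vh"]),
                     slope_k = unname(cf["k"])),
    residual_norm = sqrt(best$rss),
    converged = best$fit$convInfo$isConv %||% TRUE,
    fitted = stats::fitted(best$fit),
    data = dat
  ), class = "boltzmann_fit")
}

#' @export
coef.boltzmann_fit <- function(object, ...) object$coefficients

#' @export
predict.boltzmann_fit <- function(object, newdata = NULL, ...) {
  V <- if (is.null(newdata)) object$data$V else
    (if (is.data.frame(newdata)) newdata$V else newdata)
  cf <- object$coefficients
  cf[["g_max"]] / (1 + exp(-(V - cf[["v_half"]]) / cf[["slope_k"]]))
}

#' @export
residuals.boltzmann_fit <- function(object, ...) {
  object$data$g - predict(object)
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cf <- x$coefficients
  cat("Boltzmann activation fit: G(V) = G_max / (1 + exp(-(V - V_half)/k))\n")
  cat(sprintf("  G_max = %.4g   V_half = %.3f mV   k = %.3f mV\n",
              cf[["g_max"]], cf[["v_half"]], cf[["slope_k"]]))
  cat(sprintf("  residual norm %.4g; converged: %s\n",
              x$residual_norm, x$converged))
  invisible(x)
}

#' @export
plot.boltzmann_fit <- function(x, ...) {
  graphics::plot(x$data$V, x$data$g, xlab = "test potential (mV)",
                 ylab = "normalized conductance", ...)
  V <- seq(min(x$data$V), max(x$data$V), length.out = 200)
  graphics::lines(V, predict(x, V))
  invisible(x)
}

#' Full activation-curve analysis of one recording
#'
#' Convenience wrapper running the standard chain on a single recording:
#' P/N leak subtraction, steady-state I-V, current density, chord
#' conductance and Boltzmann fit.
#'
#' @param rec a `vclamp_recording`.
#' @param e_k K+ reversal potential (mV).
#' @param fallback passed to [pn_leak_subtract()].
#' @return list with `iv` (complete `iv_result`) and `fit`
#'   (`boltzmann_fit`).
#' @export
analyze_vclamp <- function(rec, e_k = -79.4, fallback = TRUE) {
  sub <- pn_leak_subtract(rec, fallback = fallback)
  iv <- steady_state_iv(sub)
  iv <- current_density(iv)
  iv <- chord_conductance(iv, e_k = e_k)
  fit <- boltzmann_fit(iv$voltage_mV, iv$g_norm)
  list(iv = iv, fit = fit)
}
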