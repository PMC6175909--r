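#' Voltage-clamp current trace
#'
#' Uniformly sampled holding-current series with light-epoch markers — the
#' substrate of photocurrent kinetics, light-sensitivity and EPSC
#' quantification.
#'
#' @param t time base, s (uniform, starting at 0).
#' @param i current, pA.
#' @param sample_rate sampling rate, Hz.
#' @param v_hold holding potential, mV.
#' @param light_epochs data.frame (on, off, lpd, wavelength); epochs must lie
#'   within the trace.
#' @return a `current_trace` object.
#' @export
current_trace <- function(t, i, sample_rate, v_hold = -35,
                          light_epochs = NULL) {
  stop_if_not(length(t) == length(i) && length(t) >= 2,
              "t and i must have equal length >= 2")
  stop_if_not(sample_rate > 0, "sample rate must be positive")
  dt <- diff(t)
  stop_if_not(max(abs(dt - 1 / sample_rate)) < 1e-9 / sample_rate + 1e-12,
              "sampling must be uniform at sample_rate")
  if (!is.null(light_epochs)) {
    stop_if_not(all(light_epochs$on >= t[1] & light_epochs$off <= t[length(t)]),
                "light epochs must lie within the trace")
  }
  structure(list(t = t, i = i, sample_rate = sample_rate, v_hold = v_hold,
                 light_epochs = light_epochs),
            class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("current trace: %d samples @ %g kHz, V_hold = %g mV, %d epoch(s)\n",
              length(x$t), x$sample_rate / 1000, x$v_hold,
              if (is.null(x$light_epochs)) 0L else nrow(x$light_epochs)))
  invisible(x)
}

trace_epoch <- function(trace, epoch) {
  stop_if_not(!is.null(trace$light_epochs) &&
                epoch >= 1 && epoch <= nrow(trace$light_epochs),
              "no such light epoch")
  trace$light_epochs[epoch, ]
}

baseline_mean <- function(trace, before_t, window_s = 0.05) {
  sel <- trace$t < before_t & trace$t >= before_t - window_s
  if (!any(sel)) sel <- trace$t < before_t
  stop_if_not(any(sel), "no pre-epoch samples for the baseline")
  mean(trace$i[sel])
}

#' Stationary photocurrent of a light epoch
#'
#' The photocurrent remaining at the end of a long light pulse: the mean
#' baseline-subtracted current over the final `avg_window_s` (default 10 ms)
#' of the epoch. The baseline is the pre-pulse mean, so the measure is
#' invariant under additive holding-current offsets.
#'
#' @param trace a [current_trace()].
#' @param epoch light-epoch index (row of `light_epochs`).
#' @param avg_window_s averaging window at the end of the pulse, s.
#' @return stationary current, pA.
#' @export
stationary_current <- function(trace, epoch = 1, avg_window_s = 0.010) {
  ep <- trace_epoch(trace, epoch)
  stop_if_not(ep$off - ep$on >= avg_window_s,
              "epoch shorter than the averaging window")
  sel <- trace$t >= ep$off - avg_window_s & trace$t < ep$off
  mean(trace$i[sel]) - baseline_mean(trace, ep$on)
}

#' Peak photocurrent of a light epoch
#'
#' Extremum of the baseline-subtracted current within the epoch; the signed
#' value with the largest magnitude is returned, preserving the conductance
#' direction (outward photocurrents are positive at V_hold = -35 mV).
#'
#' @inheritParams stationary_current
#' @return peak current, pA (signed).
#' @export
peak_current <- function(trace, epoch = 1) {
  ep <- trace_epoch(trace, epoch)
  b <- baseline_mean(trace, ep$on)
  seg <- trace$i[trace$t >= ep$on & trace$t < ep$off] - b
  stop_if_not(length(seg) > 0, "empty epoch")
  seg[which.max(abs(seg))]
}

#' Fit mono-exponential channel-closing kinetics (tau_off)
#'
#' Nonlinear least-squares fit of I(t) = I0 exp(-(t - t_off)/tau_off) + C to
#' the post-offset decay. Initialization: C from the trace tail, I0 from the
#' offset-to-tail drop, tau from the observed time to 1/e decay. The fit
#' never throws on noisy data; failures (including monotonically rising
#' post-offset segments) return `converged = FALSE`.
#'
#' @param trace a [current_trace()].
#' @param offset_t light-offset time, s (default: `off` of the first epoch).
#' @param fit_window_s length of post-offset data used (default: to trace end).
#' @return a `kinetics_fit` list: I0 (pA), tau_off (s), C (pA),
#'   `residual_norm`, `converged`, `degenerate`.
#' @export
fit_tau_off <- function(trace, offset_t = NULL, fit_window_s = NULL) {
  stopifnot(inherits(trace, "current_trace"))
  offset_t <- offset_t %||% trace$light_epochs$off[1]
  stop_if_not(!is.null(offset_t), "offset_t required when trace has no epochs")
  sel <- trace$t >= offset_t
  if (!is.null(fit_window_s)) sel <- sel & trace$t < offset_t + fit_window_s
  tt <- trace$t[sel] - offset_t
  ii <- trace$i[sel]
  stop_if_not(length(tt) >= 5, "too few post-offset samples")
  tail_n <- max(1L, round(length(ii) * 0.05))
  c0 <- mean(ii[(length(ii) - tail_n + 1):length(ii)])
  i0 <- ii[1] - c0
  if (abs(i0) < .Machine$double.eps^0.5 * max(1, abs(c0))) {
    return(structure(list(I0 = 0, tau_off = NA_real_, C = c0,
                          residual_norm = sqrt(sum((ii - c0)^2)),
                          converged = FALSE, degenerate = TRUE),
                     class = "kinetics_fit"))
  }
  drop_idx <- which(abs(ii - c0) <= abs(i0) / exp(1))
  tau0 <- if (length(drop_idx)) max(tt[drop_idx[1]], tt[2]) else max(tt) / 5
  fit <- tryCatch(
    minpack.lm::nlsLM(ii ~ C + I0 * exp(-tt / tau),
                      start = list(C = c0, I0 = i0, tau = tau0),
                      lower = c(-Inf, -Inf, 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(I0 = i0, tau_off = NA_real_, C = c0,
                          residual_norm = NA_real_, converged = FALSE,
                          degenerate = FALSE),
                     class = "kinetics_fit"))
  }
  cf <- stats::coef(fit)
  structure(list(I0 = unname(cf["I0"]), tau_off = unname(cf["tau"]),
                 C = unname(cf["C"]),
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 converged = TRUE, degenerate = FALSE),
            class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("tau_off fit: tau = %.4g ms, I0 = %.4g pA, C = %.4g pA\n",
                x$tau_off * 1000, x$I0, x$C))
  } else cat("tau_off fit: not converged",
             if (x$degenerate) "(degenerate input)" else "", "\n")
  invisible(x)
}

#' Fit the light-power saturation curve (EPD50)
#'
#' Least-squares fit of the saturation law I(LPD) = I_max LPD / (EPD50 + LPD)
#' to per-cell stationary photocurrents, with the effective light power
#' density for half-maximal photocurrent (EPD50) free. By construction the
#' fitted curve returns I_max / 2 at LPD = EPD50.
#'
#' @param points data.frame with columns `lpd` (mW mm^-2) and `i` (pA);
#'   at least 3 distinct LPDs.
#' @return a `saturation_fit` list: I_max (pA), EPD50 (mW mm^-2),
#'   `residual_norm`, `converged`, `poor_fit` (TRUE when residuals are large
#'   relative to the dynamic range, e.g. for non-monotone data).
#' @export
fit_epd50 <- function(points) {
  stop_if_not(is.data.frame(points) && all(c("lpd", "i") %in% names(points)),
              "points must have columns lpd and i")
  stop_if_not(length(unique(points$lpd)) >= 3, "need >= 3 distinct LPDs")
  stop_if_not(all(points$lpd > 0), "LPDs must be positive")
  imax0 <- max(points$i) * 1.1
  half <- imax0 / 2
  ord <- order(points$lpd)
  ep0 <- tryCatch(approx(points$i[ord], points$lpd[ord], xout = half,
                         ties = mean)$y, warning = function(w) NA,
                  error = function(e) NA)
  if (!is.finite(ep0) || ep0 <= 0) ep0 <- median(points$lpd)
  fit <- tryCatch(
    minpack.lm::nlsLM(i ~ imax * lpd / (epd50 + lpd), data = points,
                      start = list(imax = imax0, epd50 = ep0),
                      lower = c(1e-9, 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(I_max = NA_real_, EPD50 = NA_real_,
                          residual_norm = NA_real_, converged = FALSE,
                          poor_fit = TRUE), class = "saturation_fit"))
  }
  cf <- stats::coef(fit)
  rn <- sqrt(sum(stats::resid(fit)^2))
  span <- max(abs(points$i), 1e-12)
  structure(list(I_max = unname(cf["imax"]), EPD50 = unname(cf["epd50"]),
                 residual_norm = rn, converged = TRUE,
                 poor_fit = rn / sqrt(nrow(points)) > 0.25 * span),
            class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("saturation fit: I_max = %.4g pA, EPD50 = %.4g mW mm^-2%s\n",
                x$I_max, x$EPD50, if (x$poor_fit) " (poor fit)" else ""))
  } else cat("saturation fit: not converged\n")
  invisible(x)
}

#' Welch-weighted Savitzky-Golay smoothing
#'
#' Local polynomial least-squares smoothing with Welch (parabolic) window
#' weights w_k = 1 - (k / ((m + 1)/2))^2 over an m-sample window (default 11
#' points, order 2). Equivalent to fitting a weighted quadratic around every
#' sample and evaluating it at the center, so polynomial signals up to the
#' fit order are reproduced exactly. Edge samples use truncated windows.
#'
#' @param x numeric signal.
#' @param width odd window length (default 11).
#' @param order polynomial order (default 2).
#' @return smoothed signal of the same length.
#' @export
sg_welch_filter <- function(x, width = 11L, order = 2L) {
  stop_if_not(width %% 2 == 1 && width >= order + 1,
              "width must be odd and exceed the polynomial order")
  half <- (width - 1L) %/% 2L
  k <- -half:half
  w <- 1 - (k / ((width + 1) / 2))^2
  n <- length(x)
  # interior: one weighted LS solve gives a convolution coefficient vector
  X <- outer(k, 0:order, `^`)
  WX <- w * X
  coef_center <- solve(crossprod(X, WX), t(WX))[1, ]
  out <- numeric(n)
  if (n >= width) {
    for (j in seq_along(k)) {
      idx <- (half + 1):(n - half)
      out[idx] <- out[idx] + coef_center[j] * x[idx + k[j]]
    }
  }
  edge_idx <- if (n >= width) c(seq_len(half), (n - half + 1):n) else seq_len(n)
  for (i in edge_idx) {
    kk <- k[i + k >= 1 & i + k <= n]
    Xe <- outer(kk, 0:order, `^`)
    we <- 1 - (kk / ((width + 1) / 2))^2
    beta <- solve(crossprod(Xe, we * Xe), crossprod(we * Xe, x[i + kk]))
    out[i] <- beta[1]
  }
  out
}

#' Light-evoked EPSC amplitude
#'
#' The trace is smoothed with the Welch-weighted 11-point second-order
#' Savitzky-Golay filter; the amplitude is the maximal absolute deviation of
#' the smoothed current from the pre-light smoothed baseline within
#' `window_s` (default 20 ms) after light delivery, reported as a magnitude
#' in pA.
#'
#' @param trace a [current_trace()].
#' @param light_t light-delivery time, s (default: `on` of the first epoch).
#' @param window_s search window after light delivery, s.
#' @param baseline_s pre-light span used for the baseline mean, s.
#' @return EPSC amplitude, pA (non-negative).
#' @export
epsc_amplitude <- function(trace, light_t = NULL, window_s = 0.020,
                           baseline_s = 0.05) {
  stopifnot(inherits(trace, "current_trace"))
  light_t <- light_t %||% trace$light_epochs$on[1]
  stop_if_not(!is.null(light_t), "light_t required when trace has no epochs")
  stop_if_not(light_t + window_s <= trace$t[length(trace$t)] + 1e-12,
              "search window exceeds the trace")
  sm <- sg_welch_filter(trace$i)
  base_sel <- trace$t < light_t & trace$t >= light_t - baseline_s
  if (!any(base_sel)) base_sel <- trace$t < light_t
  stop_if_not(any(base_sel), "no pre-light samples for the baseline")
  base <- mean(sm[base_sel])
  win <- trace$t >= light_t & trace$t <= light_t + window_s
  max(abs(sm[win] - base))
}
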