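# FRAP: normalize fluorescence recovery traces and fit the single-exponential
# recovery model for the time constant and mobile fraction.

#' Normalize a FRAP intensity trace
#'
#' Background-subtracted intensities are divided by the mean prebleach level
#' so the prebleach mean is exactly 1 and the fit becomes invariant to the
#' raw trace's absolute scale:
#' `I_norm(t) = (raw - background) / mean(prebleach - background)`.
#'
#' @param raw raw intensity trace.
#' @param background background level: scalar or per-frame vector.
#' @param n_prebleach frames acquired before the bleach (the bleach happens
#'   between frames `n_prebleach` and `n_prebleach + 1`).
#' @param times acquisition times (s), or `NULL` to build them from
#'   `frame_interval`.
#' @param frame_interval frame spacing (s) when `times` is absent.
#' @return a `frap_trace`: data.frame `t`, `raw`, `normalized` with
#'   attributes `n_prebleach` and `bleach_index` (0-based index of the first
#'   post-bleach frame).
#' @export
normalize_trace <- function(raw, background = 0, n_prebleach = 3L,
                            times = NULL, frame_interval = 1.5) {
  n <- length(raw)
  if (n < n_prebleach + 2L) {
    stop("trace too short: need at least n_prebleach + 2 frames")
  }
  if (is.null(times)) times <- (seq_len(n) - 1L) * frame_interval
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  bg <- rep(background, length.out = n)
  pre <- mean(raw[seq_len(n_prebleach)] - bg[seq_len(n_prebleach)])
  if (pre <= 0) {
    stop("prebleach mean does not exceed background; cannot normalize")
  }
  structure(data.frame(t = times, raw = raw,
                       normalized = (raw - bg) / pre),
            n_prebleach = as.integer(n_prebleach),
            bleach_index = as.integer(n_prebleach),
            class = c("frap_trace", "data.frame"))
}

#' Fit the recovery of a normalized FRAP trace
#'
#' Least-squares fit of the single-exponential recovery model
#' `I(t) = I0 + MF * (1 - I0) * (1 - exp(-(t - t_bleach)/tau))`
#' on the post-bleach points, where `I0` is the immediate post-bleach floor,
#' `MF` the mobile fraction and `tau` the recovery time constant. `MF` is
#' clipped into \[0, 1\] with a warning if the unconstrained optimum falls
#' outside. Degenerate flat traces (already fully recovered, or no recovery
#' at all) are resolved analytically with `tau = NA`.
#'
#' @param trace a `frap_trace` from [normalize_trace()].
#' @return a `frap_fit`: `tau` (s), `mobile_fraction`, `I0`, `residual`
#'   (RMS), `converged`, plus the trace for plotting.
#' @export
fit_recovery <- function(trace) {
  bleach <- attr(trace, "bleach_index")
  post <- trace[(bleach + 1L):nrow(trace), , drop = FALSE]
  if (nrow(post) < 5L) stop("need at least 5 post-bleach points")
  tt <- post$t - post$t[1L]
  yy <- post$normalized
  finish <- function(tau, mf, i0, pred, converged) {
    if (mf < -1e-9 || mf > 1 + 1e-9) {
      warning(sprintf("mobile fraction %.3f outside [0, 1]; clipped", mf))
      mf <- min(max(mf, 0), 1)
    }
    structure(list(tau = tau, mobile_fraction = mf, I0 = i0,
                   residual = sqrt(mean((yy - pred)^2)),
                   converged = converged, trace = trace),
              class = "frap_fit")
  }
  if (stats::sd(yy) < 1e-10) {
    # flat post-bleach trace: no time constant is identifiable
    i0 <- mean(yy)
    mf <- if (abs(i0 - 1) < 1e-8) 1 else 0
    return(finish(NA_real_, mf, i0, rep(i0, length(yy)), TRUE))
  }
  i0_start <- max(min(yy[1L], 0.99), 0)
  plateau <- mean(utils::tail(yy, max(3L, length(yy) %/% 10L)))
  mf_start <- min(max((plateau - i0_start) / max(1 - i0_start, 1e-6), 0.05),
                  1)
  half <- i0_start + 0.5 * (plateau - i0_start)
  k <- which(yy >= half)[1L]
  tau_start <- if (!is.na(k) && tt[k] > 0) tt[k] / log(2) else
    max(tt[length(tt)] / 5, 1e-3)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      yy ~ I0 + MF * (1 - I0) * (1 - exp(-tt / tau)),
      start = list(I0 = i0_start, MF = mf_start, tau = tau_start),
      lower = c(I0 = 0, MF = 0, tau = 1e-6),
      upper = c(I0 = 1, MF = 2, tau = 1e6),
      control = minpack.lm::nls.lm.control(maxiter = 200L)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("FRAP recovery fit did not converge")
    return(finish(NA_real_, mf_start, i0_start, rep(mean(yy), length(yy)),
                  FALSE))
  }
  cf <- stats::coef(fit)
  finish(cf[["tau"]], cf[["MF"]], cf[["I0"]], stats::fitted(fit), TRUE)
}

#' @export
print.frap_fit <- function(x, ...) {
  cat("FRAP recovery fit (single exponential):\n")
  cat(sprintf("  tau = %s s, mobile fraction = %.3f, I0 = %.3f (RMS %.4f)%s\n",
              if (is.na(x$tau)) "NA" else sprintf("%.2f", x$tau),
              x$mobile_fraction, x$I0, x$residual,
              if (x$converged) "" else " [NOT converged]"))
  invisible(x)
}

#' @export
coef.frap_fit <- function(object, ...) {
  c(tau = object$tau, mobile_fraction = object$mobile_fraction,
    I0 = object$I0)
}

#' @export
predict.frap_fit <- function(object, t = NULL, ...) {
  trace <- object$trace
  bleach <- attr(trace, "bleach_index")
  t_bleach <- trace$t[bleach + 1L]
  if (is.null(t)) t <- trace$t
  ifelse(t < t_bleach, 1,
         object$I0 + object$mobile_fraction * (1 - object$I0) *
           (1 - exp(-(t - t_bleach) / object$tau)))
}

#' @export
residuals.frap_fit <- function(object, ...) {
  object$trace$normalized - predict(object)
}

#' @export
plot.frap_fit <- function(x, ...) {
  trace <- x$trace
  graphics::plot(trace$t, trace$normalized, pch = 1, xlab = "time (s)",
                 ylab = "normalized intensity", ylim = c(0, 1.1), ...)
  if (!is.na(x$tau)) {
    tt <- seq(min(trace$t), max(trace$t), length.out = 300L)
    graphics::lines(tt, predict(x, tt), col = "firebrick3")
  }
  graphics::abline(v = trace$t[attr(trace, "bleach_index") + 1L], lty = 3)
  invisible(x)
}
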