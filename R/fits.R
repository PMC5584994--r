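# Exponential model fitting.
#
# All nonlinear fits use a separable (variable-projection) grid search for
# initial values — for fixed decay rates the amplitudes are a linear
# least-squares solve — followed by a Levenberg-Marquardt polish
# (minpack.lm::nlsLM). This makes the fits robust to the usual
# multi-decade uncertainty in exponential time constants without manual
# starting values.

# Linear amplitude solve for fixed decay rates; columns e^{-t/tau_i} (+ 1).
vp_solve <- function(tt, yy, taus, offset = TRUE) {
  X <- vapply(taus, function(tau) exp(-tt / tau), numeric(length(tt)))
  X <- matrix(X, nrow = length(tt))
  if (offset) X <- cbind(X, 1)
  fit <- tryCatch(stats::lm.fit(X, yy), error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- unname(fit$coefficients)
  if (any(is.na(cf))) return(NULL)
  resid <- yy - X %*% fit$coefficients
  list(coef = cf, sse = sum(resid^2))
}

r_squared <- function(yy, fitted) {
  ss_tot <- sum((yy - mean(yy))^2)
  if (ss_tot == 0) return(if (all(abs(yy - fitted) < 1e-12)) 1 else 0)
  max(0, min(1, 1 - sum((yy - fitted)^2) / ss_tot))
}

log_grid <- function(lo, hi, n) exp(seq(log(lo), log(hi), length.out = n))

# Single exponential plus offset: y ~ a exp(-t/tau) + c.
fit_exp_offset <- function(tt, yy) {
  t0 <- tt[1]
  ts <- tt - t0
  span <- max(ts)
  taus <- log_grid(span / 50, span * 20, 25)
  best <- NULL
  for (tau in taus) {
    s <- vp_solve(ts, yy, tau, offset = TRUE)
    if (!is.null(s) && (is.null(best) || s$sse < best$sse)) {
      best <- list(sse = s$sse, tau = tau, a = s$coef[1], c = s$coef[2])
    }
  }
  if (is.null(best)) stop("bleach fit failed: singular design")
  df <- data.frame(ts = ts, yy = yy)
  polish <- tryCatch(
    minpack.lm::nlsLM(yy ~ a * exp(-ts / tau) + c, data = df,
                      start = list(a = best$a, tau = best$tau, c = best$c),
                      lower = c(-Inf, span / 1e4, -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(polish)) {
    cf <- stats::coef(polish)
    best$a <- cf[["a"]]; best$tau <- cf[["tau"]]; best$c <- cf[["c"]]
  }
  pred <- function(t) best$a * exp(-(t - t0) / best$tau) + best$c
  list(a = best$a, tau = best$tau, c = best$c,
       r2 = r_squared(yy, pred(tt)), predict = pred)
}

# Double exponential decay with non-negative rates: y ~ a e^{-b t}+ c e^{-d t}.
# Rates may converge to ~0, absorbing any constant level.
fit_double_exp_decay <- function(tt, yy) {
  t0 <- tt[1]
  ts <- tt - t0
  span <- max(ts)
  taus <- log_grid(span / 100, span * 100, 14)
  best <- NULL
  for (i in seq_along(taus)) {
    for (j in seq_len(i - 1)) {
      s <- vp_solve(ts, yy, taus[c(j, i)], offset = FALSE)
      if (!is.null(s) && (is.null(best) || s$sse < best$sse)) {
        best <- list(sse = s$sse, tau1 = taus[j], tau2 = taus[i],
                     a = s$coef[1], c = s$coef[2])
      }
    }
  }
  if (is.null(best)) stop("double-exponential fit failed: singular design")
  df <- data.frame(ts = ts, yy = yy)
  polish <- tryCatch(
    minpack.lm::nlsLM(yy ~ a * exp(-b * ts) + c * exp(-d * ts), data = df,
                      start = list(a = best$a, b = 1 / best$tau1,
                                   c = best$c, d = 1 / best$tau2),
                      lower = c(-Inf, 0, -Inf, 0),
                      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (!is.null(polish)) {
    cf <- stats::coef(polish)
    par <- list(a = cf[["a"]], b = cf[["b"]], c = cf[["c"]], d = cf[["d"]])
  } else {
    par <- list(a = best$a, b = 1 / best$tau1, c = best$c, d = 1 / best$tau2)
  }
  pred <- function(t) {
    par$a * exp(-par$b * (t - t0)) + par$c * exp(-par$d * (t - t0))
  }
  c(par, list(r2 = r_squared(yy, pred(tt)), predict = pred))
}

#' Fit a weighted sum of two exponentials
#'
#' Least-squares fit of `a * exp(-b*t) + c * exp(-d*t)` (plus an optional
#' constant offset, needed when the segment relaxes toward a nonzero steady
#' state) to an isolated rising or falling portion of a trace. Initial
#' values come from a grid over time-constant pairs with linearly solved
#' amplitudes, polished by Levenberg-Marquardt. Reports the fast/slow time
#' constants in ms (`tau_fast <= tau_slow` by convention), the fast
#' amplitude fraction, and r-squared; near-equal rates are flagged
#' degenerate.
#'
#' @param segment A [gevi_trace()] or list with `times` (s) and `values`
#'   (or `dff`).
#' @param offset Include a constant term (default TRUE).
#' @return A `biexp_fit` list: `a`, `b`, `c`, `d`, `offset`, `tau_fast_ms`,
#'   `tau_slow_ms`, `fraction_fast`, `r2`, `degenerate`.
#' @export
fit_biexponential <- function(segment, offset = TRUE) {
  tt <- segment$times
  yy <- if (!is.null(segment$values)) segment$values else segment$dff
  if (length(tt) < 6) stop("segment too short for a bi-exponential fit")
  t0 <- tt[1]
  ts <- tt - t0
  span <- max(ts)
  dt <- stats::median(diff(ts))
  taus <- log_grid(max(dt, span / 2000), span * 4, 16)
  best <- NULL
  for (i in seq_along(taus)) {
    for (j in seq_len(i - 1)) {
      s <- vp_solve(ts, yy, taus[c(j, i)], offset = offset)
      if (!is.null(s) && (is.null(best) || s$sse < best$sse)) {
        best <- list(sse = s$sse, tau1 = taus[j], tau2 = taus[i],
                     a = s$coef[1], c = s$coef[2],
                     e = if (offset) s$coef[3] else 0)
      }
    }
  }
  if (is.null(best)) stop("bi-exponential fit failed: singular design")
  df <- data.frame(ts = ts, yy = yy)
  polish <- tryCatch({
    if (offset) {
      minpack.lm::nlsLM(yy ~ a * exp(-b * ts) + c * exp(-d * ts) + e,
                        data = df,
                        start = list(a = best$a, b = 1 / best$tau1,
                                     c = best$c, d = 1 / best$tau2,
                                     e = best$e),
                        lower = c(-Inf, 0, -Inf, 0, -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    } else {
      minpack.lm::nlsLM(yy ~ a * exp(-b * ts) + c * exp(-d * ts), data = df,
                        start = list(a = best$a, b = 1 / best$tau1,
                                     c = best$c, d = 1 / best$tau2),
                        lower = c(-Inf, 0, -Inf, 0),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    }
  }, error = function(e) NULL)
  if (!is.null(polish)) {
    cf <- stats::coef(polish)
    a <- cf[["a"]]; b <- cf[["b"]]; c_ <- cf[["c"]]; d <- cf[["d"]]
    e <- if (offset) cf[["e"]] else 0
  } else {
    a <- best$a; b <- 1 / best$tau1; c_ <- best$c; d <- 1 / best$tau2
    e <- best$e
  }
  # order: fast term = larger rate
  if (b < d) {
    tmp <- a; a <- c_; c_ <- tmp
    tmp <- b; b <- d; d <- tmp
  }
  fitted <- a * exp(-b * ts) + c_ * exp(-d * ts) + e
  amp_sum <- abs(a) + abs(c_)
  degenerate <- (d > 0 && b / d < 1.05) || amp_sum == 0 ||
    abs(a) / amp_sum < 1e-6 || abs(c_) / amp_sum < 1e-6
  structure(list(a = a, b = b, c = c_, d = d, offset = e,
                 tau_fast_ms = 1000 / b,
                 tau_slow_ms = if (d > 0) 1000 / d else Inf,
                 fraction_fast = if (amp_sum > 0) abs(a) / amp_sum else NA_real_,
                 r2 = r_squared(yy, fitted), degenerate = degenerate),
            class = "biexp_fit")
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat(sprintf(
    "Bi-exponential fit: tau_fast %.4g ms, tau_slow %.4g ms, %%fast %.1f, r2 %.4f%s\n",
    x$tau_fast_ms, x$tau_slow_ms, 100 * x$fraction_fast, x$r2,
    if (x$degenerate) " [degenerate: effectively single-exponential]" else ""))
  invisible(x)
}

#' Fit a single-exponential decay from a response peak
#'
#' Fits `A * exp(-(t - t_peak)/tau)` to the decay phase of a transient
#' (peak to baseline), the standard way optical spike decays are
#' summarized. Initialization is a log-linear regression; the fit is
#' polished by Levenberg-Marquardt.
#'
#' @param trace dff-kind [gevi_trace()] (or any list with `times` and
#'   `values`).
#' @param peak_time Start of the decay segment (s).
#' @param end_time Optional end of the segment (s); defaults to the end of
#'   the trace.
#' @param polarity Sign of the transient (default -1, negative-going).
#' @return List with `tau` (s), `amplitude` (signed), `r2`.
#' @export
fit_monoexponential_decay <- function(trace, peak_time, end_time = NULL,
                                      polarity = -1) {
  tt <- trace$times
  yy <- if (!is.null(trace$values)) trace$values else trace$dff
  sel <- tt >= peak_time & (if (is.null(end_time)) TRUE else tt <= end_time)
  if (sum(sel) < 5) {
    stop("insufficient data: decay segment has fewer than 5 points")
  }
  ts <- tt[sel] - peak_time
  z <- yy[sel] * sign(polarity)  # flip so the decay starts positive
  if (max(abs(z)) < .Machine$double.eps * 100) {
    stop("flat decay segment: nothing to fit")
  }
  pos <- z > max(z) * 1e-3
  if (sum(pos) < 3) stop("decay segment does not stay on the response side")
  lf <- stats::lm(log(z[pos]) ~ ts[pos])
  slope <- stats::coef(lf)[2]
  if (!is.finite(slope) || slope >= 0) {
    stop("non-decaying segment: effective tau is infinite")
  }
  start <- list(A = exp(unname(stats::coef(lf)[1])), tau = unname(-1 / slope))
  df <- data.frame(ts = ts, z = z)
  polish <- tryCatch(
    minpack.lm::nlsLM(z ~ A * exp(-ts / tau), data = df, start = start,
                      lower = c(0, .Machine$double.eps),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(polish)) {
    cf <- stats::coef(polish)
    A <- cf[["A"]]; tau <- cf[["tau"]]
  } else {
    A <- start$A; tau <- start$tau
  }
  fitted <- A * exp(-ts / tau)
  list(tau = tau, amplitude = A * sign(polarity), r2 = r_squared(z, fitted))
}
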