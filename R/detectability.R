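#' Spike detectability index d'
#'
#' The shot-noise-limited discriminability of a single spike on a stable
#' baseline: `d' = |dF/F| * sqrt(F0 * tau / 2)`, where F0 is the resting
#' photon count per frame and tau the decay time constant of the optical
#' transient expressed in frames, so that `F0 * tau` is the photon budget
#' of one spike. Units matter: F0 must be an actual photon count per
#' sampling period, not a relative intensity, and tau must be in sample
#' periods.
#'
#' @param dff_peak Peak |dF/F| of the spike response (dimensionless).
#' @param f0 Resting photons per frame.
#' @param tau_frames Decay constant in frames.
#' @return d' (dimensionless), monotone non-decreasing in each argument.
#' @examples
#' dprime(0.15, 40, 15)  # 0.15 * sqrt(300) ~ 2.598
#' @export
dprime <- function(dff_peak, f0, tau_frames) {
  if (any(dff_peak < 0) || any(f0 < 0) || any(tau_frames < 0)) {
    stop("dprime inputs must be non-negative")
  }
  dff_peak * sqrt(f0 * tau_frames / 2)
}

#' d' of a single spike measured from a photon-count trace
#'
#' Measures the three d' ingredients from a bleach-corrected counts trace:
#' F0 as the mean count over the pre-trigger baseline window, dF/F as the
#' peak deviation from F0 (in the indicator's polarity) divided by F0, and
#' tau from a single-exponential fit of the decay from the peak. tau is
#' converted to frames at the trace's frame rate before applying the d'
#' formula.
#'
#' @param trace Counts-kind [gevi_trace()], already corrected for
#'   photobleaching (see [bleach_correct_additive()]).
#' @param spike_time Spike trigger time (s); defaults to the first
#'   `spike_trigger` event.
#' @param baseline_window Baseline window in ms before the trigger,
#'   default `c(110, 10)`.
#' @param search_window_s How far after the trigger to search for the peak
#'   (default to the end of the trace).
#' @return List with `dprime`, `dff_peak`, `f0`, `tau_s`, `tau_frames`,
#'   `fit_r2`, `included` (FALSE when the decay fit fails, with `dprime`
#'   NA).
#' @export
dprime_single <- function(trace, spike_time = NULL,
                          baseline_window = c(110, 10),
                          search_window_s = NULL) {
  stopifnot(inherits(trace, "gevi_trace"))
  if (trace$kind != "counts") {
    stop("dprime_single expects a counts-kind trace (photon counts)")
  }
  spike_time <- resolve_event(trace, spike_time, "spike_trigger",
                              "spike time")
  dff_tr <- compute_dff(trace, trigger = spike_time,
                        baseline_window = baseline_window)
  f0 <- attr(dff_tr, "f0")
  t_end <- if (is.null(search_window_s)) max(trace$times) else
    spike_time + search_window_s
  sel <- dff_tr$times >= spike_time & dff_tr$times <= t_end
  if (sum(sel) < 3) stop("no samples after the spike time")
  yy <- dff_tr$values[sel] * sign(trace$polarity)
  tt <- dff_tr$times[sel]
  ip <- which.max(yy)
  dff_peak <- max(yy[ip], 0)
  t_peak <- tt[ip]
  if (dff_peak == 0) {
    # no response excursion in the indicator's polarity: nothing to detect
    return(list(dprime = 0, dff_peak = 0, f0 = f0, tau_s = NA_real_,
                tau_frames = NA_real_, fit_r2 = NA_real_,
                included = FALSE))
  }
  fit <- tryCatch(
    fit_monoexponential_decay(list(times = dff_tr$times,
                                   values = dff_tr$values),
                              peak_time = t_peak, end_time = t_end,
                              polarity = trace$polarity),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(dprime = NA_real_, dff_peak = dff_peak, f0 = f0,
                tau_s = NA_real_, tau_frames = NA_real_, fit_r2 = NA_real_,
                included = FALSE))
  }
  tau_frames <- fit$tau * trace$frame_rate
  list(dprime = dprime(dff_peak, f0, tau_frames), dff_peak = dff_peak,
       f0 = f0, tau_s = fit$tau, tau_frames = tau_frames, fit_r2 = fit$r2,
       included = TRUE)
}

#' d' of a spike train with frequency-dependent baseline rules
#'
#' Extends the single-spike d' to trains by recomputing F0 and tau per
#' spike. For trains at 30 Hz and below, fluorescence recovers between
#' spikes, so a shared F0 is used: the average of the maximal fluorescence
#' in each inter-spike gap. For faster trains (above `shared_f0_max_freq`,
#' default 30 Hz) the baseline shifts during the train, so each spike gets
#' its own F0, the maximal fluorescence over its following inter-spike
#' interval. Peaks that cannot be located or whose decay cannot be fitted
#' are excluded, and the inclusion fraction is reported; the train d' is
#' the arithmetic mean of the included per-spike d' values.
#'
#' @param trace Bleach-corrected counts-kind [gevi_trace()].
#' @param spike_times Sorted spike trigger times (s).
#' @param train_freq Nominal train frequency in Hz; determines the F0 rule.
#' @param shared_f0_max_freq Highest frequency using the shared-F0 rule
#'   (default 30).
#' @return A `detection_report` list: `dprime` (train mean), `per_spike`
#'   data.frame, `inclusion_fraction`, `f0_rule`.
#' @export
dprime_train <- function(trace, spike_times, train_freq,
                         shared_f0_max_freq = 30) {
  stopifnot(inherits(trace, "gevi_trace"), trace$kind == "counts")
  spike_times <- sort(spike_times)
  n <- length(spike_times)
  if (n == 0) stop("empty report: no spikes given")
  if (n == 1) {
    one <- dprime_single(trace, spike_times)
    return(structure(list(
      dprime = one$dprime,
      per_spike = data.frame(spike_index = 1L, f0_used = one$f0,
                             tau_frames = one$tau_frames,
                             dff_peak = one$dff_peak, dprime = one$dprime,
                             included = one$included),
      inclusion_fraction = as.numeric(one$included), f0_rule = "single"),
      class = "detection_report"))
  }
  isi <- 1 / train_freq
  pol <- sign(trace$polarity)
  # interval of spike i: [spike_i, spike_{i+1}) (last: one ISI long)
  ends <- c(spike_times[-1], spike_times[n] + isi)
  # maximal fluorescence (baseline side) in each inter-spike gap
  gap_max <- vapply(seq_len(n - 1), function(i) {
    sel <- trace$times > spike_times[i] & trace$times < spike_times[i + 1]
    if (!any(sel)) return(NA_real_)
    max(trace$values[sel] * -pol) * -pol  # extremum opposite the response
  }, numeric(1))
  shared <- train_freq <= shared_f0_max_freq
  per <- lapply(seq_len(n), function(i) {
    f0 <- if (shared) mean(gap_max, na.rm = TRUE) else {
      sel <- trace$times > spike_times[i] & trace$times < ends[i]
      if (!any(sel)) NA_real_ else max(trace$values[sel] * -pol) * -pol
    }
    sel <- trace$times >= spike_times[i] & trace$times < ends[i]
    if (!any(sel) || !is.finite(f0) || f0 <= 0) {
      return(data.frame(spike_index = i, f0_used = f0,
                        tau_frames = NA_real_, dff_peak = NA_real_,
                        dprime = NA_real_, included = FALSE))
    }
    tt <- trace$times[sel]
    yy <- (trace$values[sel] - f0) / f0
    ip <- which.max(yy * pol)
    dff_peak <- max(yy[ip] * pol, 0)
    locatable <- ip < length(yy) && dff_peak > 0
    fit <- if (locatable) tryCatch(
      fit_monoexponential_decay(list(times = tt, values = yy),
                                peak_time = tt[ip], polarity = pol),
      error = function(e) NULL) else NULL
    if (is.null(fit)) {
      return(data.frame(spike_index = i, f0_used = f0,
                        tau_frames = NA_real_, dff_peak = dff_peak,
                        dprime = NA_real_, included = FALSE))
    }
    tau_frames <- fit$tau * trace$frame_rate
    data.frame(spike_index = i, f0_used = f0, tau_frames = tau_frames,
               dff_peak = dff_peak,
               dprime = dprime(dff_peak, f0, tau_frames), included = TRUE)
  })
  per <- do.call(rbind, per)
  if (!any(per$included)) stop("empty report: no locatable, fittable peaks")
  structure(list(dprime = mean(per$dprime[per$included]),
                 per_spike = per,
                 inclusion_fraction = mean(per$included),
                 f0_rule = if (shared) "shared" else "per_spike"),
            class = "detection_report")
}

#' Monte-Carlo ROC for spike detection by log-likelihood thresholding
#'
#' Simulates a photon-noise-normalized sample stream: `n_samples` draws in
#' which every `spike_period`-th sample comes from the signal distribution
#' Normal(1 + d', 1) and all others from the noise distribution
#' Normal(1, 1). Each sample's spike log-likelihood is
#' `L(i) = f(i) * log(Sn/B) - Sn + B` with Sn = 1 + d', B = 1 (single-sample
#' spikes, N = 1). A threshold is swept over the observed L values and the
#' one maximizing (true positives - false positives) is selected, ties
#' broken toward the lowest threshold; detection and false-positive rates
#' are the fractions of signal and noise samples above it.
#'
#' @param dprime d' value (> 0; L is constant otherwise).
#' @param n_samples Stream length (default 1e6).
#' @param spike_period Every `spike_period`-th sample is a spike
#'   (default 10).
#' @param seed Integer seed.
#' @return A `detection_report` list: `dprime`, `threshold_L`,
#'   `threshold_f` (the equivalent raw-sample threshold via L's affine
#'   form), `tp_rate`, `fp_rate`, `n_signal`, `n_noise`.
#' @examples
#' roc_simulate(4.1, seed = 1)  # tp ~ 0.94, fp ~ 0.005
#' @export
roc_simulate <- function(dprime, n_samples = 1e6, spike_period = 10,
                         seed = 1) {
  if (dprime <= 0) {
    stop("degenerate likelihood: d' must be positive for thresholding")
  }
  if (spike_period < 2) stop("spike_period must be at least 2")
  B <- 1
  Sn <- 1 + dprime
  is_spike <- (seq_len(n_samples) %% spike_period) == 0
  f <- with_preserved_seed(seed, {
    x <- stats::rnorm(n_samples, mean = B, sd = 1)
    x[is_spike] <- stats::rnorm(sum(is_spike), mean = Sn, sd = 1)
    x
  })
  L <- f * log(Sn / B) - Sn + B
  # Sweep thresholds at the observed L values (detected: L >= threshold).
  # In descending order, TP and FP at threshold L[k] are cumulative counts.
  o <- order(L, decreasing = TRUE)
  sig_sorted <- is_spike[o]
  tp <- cumsum(sig_sorted)
  fp <- seq_along(tp) - tp
  objective <- tp - fp
  best <- max(objective)
  k <- max(which(objective == best))  # lowest threshold achieving the max
  thr_L <- L[o][k]
  n_signal <- sum(is_spike)
  n_noise <- n_samples - n_signal
  structure(list(dprime = dprime, threshold_L = thr_L,
                 threshold_f = (thr_L + Sn - B) / log(Sn / B),
                 tp_rate = tp[k] / n_signal, fp_rate = fp[k] / n_noise,
                 n_signal = n_signal, n_noise = n_noise),
            class = "detection_report")
}

#' Closed-form ROC rates for the log-likelihood threshold procedure
#'
#' Because L is affine and increasing in the raw sample f (for d' > 0),
#' thresholding L is equivalent to thresholding f, and the threshold that
#' maximizes expected (TP - FP) counts equates the two class densities
#' weighted by prevalence: with spike fraction p, the optimal threshold
#' `u` above the noise mean solves `p * phi(u - d') = (1 - p) * phi(u)`,
#' giving `u = d'/2 + log((1-p)/p) / d'`. Then the detection rate is
#' `Phi(d' - u)` and the false-positive rate `Phi(-u)`. This is the exact
#' large-sample limit of [roc_simulate()].
#'
#' @param dprime d' value (> 0).
#' @param spike_fraction Spike prevalence p in (0, 1) (default 0.1).
#' @return List with `threshold_u` (above the noise mean), `threshold_f`
#'   (raw-sample scale), `tp_rate`, `fp_rate`.
#' @examples
#' roc_analytic(4.1)   # tp ~ 0.935, fp ~ 0.0049
#' roc_analytic(17.5)  # tp > 0.99, fp < 1e-8
#' @export
roc_analytic <- function(dprime, spike_fraction = 0.1) {
  if (dprime <= 0) stop("degenerate: d' must be positive")
  p <- spike_fraction
  if (p <= 0 || p >= 1) stop("spike_fraction must lie in (0, 1)")
  u <- dprime / 2 + log((1 - p) / p) / dprime
  list(threshold_u = u, threshold_f = 1 + u,
       tp_rate = stats::pnorm(dprime - u), fp_rate = stats::pnorm(-u))
}

#' @export
print.detection_report <- function(x, ...) {
  cat("Detection report\n")
  cat(sprintf("  d': %.4g\n", x$dprime))
  if (!is.null(x$tp_rate)) {
    cat(sprintf("  detection rate: %.4g  false-positive rate: %.3g\n",
                x$tp_rate, x$fp_rate))
  }
  if (!is.null(x$inclusion_fraction)) {
    cat(sprintf("  spikes included: %.0f%% (F0 rule: %s)\n",
                100 * x$inclusion_fraction, x$f0_rule))
  }
  invisible(x)
}
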