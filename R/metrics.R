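#' Fractional fluorescence change relative to a pre-trigger baseline
#'
#' F0 is the mean photon count over a window preceding the trigger (default
#' 110 ms to 10 ms before), and the output is (F - F0) / F0. The baseline is
#' stored on the result so the transform can be inverted exactly.
#'
#' @param trace Counts-kind [gevi_trace()].
#' @param trigger Trigger time in seconds; defaults to the trace's first
#'   `spike_trigger` event.
#' @param baseline_window Numeric length-2: window edges in ms *before* the
#'   trigger, default `c(110, 10)`.
#' @return A dff-kind [gevi_trace()] with attribute `f0`.
#' @export
compute_dff <- function(trace, trigger = NULL, baseline_window = c(110, 10)) {
  stopifnot(inherits(trace, "gevi_trace"))
  if (trace$kind != "counts") stop("compute_dff expects a counts-kind trace")
  trigger <- resolve_event(trace, trigger, "spike_trigger", "trigger")
  w <- sort(trigger - baseline_window / 1000)
  sel <- trace$times >= w[1] & trace$times <= w[2]
  if (!any(sel)) stop("baseline window [", w[1], ", ", w[2],
                      "] s contains no samples")
  f0 <- mean(trace$values[sel])
  if (f0 <= 0) stop("invalid trace: baseline F0 is not positive (", f0, ")")
  out <- trace
  out$values <- (trace$values - f0) / f0
  out$kind <- "dff"
  attr(out, "f0") <- f0
  attr(out, "baseline_window") <- baseline_window
  out
}

#' Baseline noise of a dF/F trace
#'
#' Sample standard deviation over a window (default 200 ms) ending at the
#' stimulus onset.
#'
#' @param trace dff-kind [gevi_trace()].
#' @param stimulus_onset Onset time in seconds; defaults to the first
#'   `stimulus_onset` event.
#' @param window_s Window length in seconds before the onset (default 0.2).
#' @return Standard deviation (dimensionless).
#' @export
baseline_noise <- function(trace, stimulus_onset = NULL, window_s = 0.2) {
  stopifnot(inherits(trace, "gevi_trace"))
  onset <- resolve_event(trace, stimulus_onset, "stimulus_onset",
                         "stimulus onset")
  avail <- onset - trace$times[1]
  if (avail < window_s - 0.5 / trace$frame_rate) {
    stop(sprintf(
      "insufficient pre-stimulus data: %.3g s available, %.3g s required (short by %.3g s)",
      avail, window_s, window_s - avail))
  }
  sel <- trace$times >= onset - window_s & trace$times < onset
  stats::sd(trace$values[sel])
}

#' Signal-to-noise ratio of a response
#'
#' Peak |dF/F| after the trigger divided by the pre-stimulus baseline noise.
#'
#' @param trace dff-kind [gevi_trace()].
#' @param trigger,stimulus_onset Times in seconds; default to the trace's
#'   events.
#' @param window_s Noise window, see [baseline_noise()].
#' @return Dimensionless SNR.
#' @export
snr <- function(trace, trigger = NULL, stimulus_onset = NULL, window_s = 0.2) {
  trigger <- resolve_event(trace, trigger, "spike_trigger", "trigger")
  noise <- baseline_noise(trace, stimulus_onset, window_s)
  if (noise == 0) stop("undefined SNR: baseline noise is zero")
  sel <- trace$times >= trigger
  peak <- peak_value(trace$values[sel], trace$polarity)
  abs(peak) / noise
}

# Signed extremum in the expected polarity.
peak_value <- function(values, polarity = -1) {
  if (polarity < 0) min(values) else max(values)
}

#' Additive photobleaching correction
#'
#' Fits a single exponential (plus offset) to the sections of the trace
#' identified as resting fluorescence, then subtracts the fitted bleach
#' curve and adds back its value at a reference time (the start of the first
#' spike). This keeps the resting photon count constant across the trace at
#' its pre-spike level while leaving the absolute height of transients
#' unchanged — the form the d-prime statistic requires, since it needs
#' actual photon counts on a stable baseline.
#'
#' @param trace Counts-kind [gevi_trace()].
#' @param rest_segments List (or 2-column matrix/data.frame) of
#'   `(start, end)` times in seconds marking resting sections.
#' @param reference_time Time (s) whose fitted bleach value becomes the
#'   corrected resting level; typically the start of the first spike.
#' @return A corrected counts-kind [gevi_trace()]; the fit is attached as
#'   attribute `"bleach_fit"`.
#' @export
bleach_correct_additive <- function(trace, rest_segments, reference_time) {
  stopifnot(inherits(trace, "gevi_trace"))
  segs <- rest_segments
  if (is.data.frame(segs) || is.matrix(segs)) {
    segs <- lapply(seq_len(nrow(segs)), function(i) as.numeric(segs[i, 1:2]))
  }
  if (length(segs) == 0) stop("rest_segments must be non-empty")
  if (reference_time < trace$times[1] ||
      reference_time > trace$times[length(trace$times)]) {
    stop("reference_time must lie within the trace")
  }
  sel <- Reduce(`|`, lapply(segs, function(s) {
    trace$times >= s[1] & trace$times <= s[2]
  }))
  if (sum(sel) < 5) stop("rest segments contain too few samples to fit")
  fit <- fit_exp_offset(trace$times[sel], trace$values[sel])
  g <- fit$predict(trace$times)
  out <- trace
  out$values <- trace$values - g + fit$predict(reference_time)
  attr(out, "bleach_fit") <- fit[c("a", "tau", "c", "r2")]
  out
}

#' Divisive photobleaching correction
#'
#' Fits the whole trace with the sum of two exponentials g2(t) and returns
#' dF/F(t) = (F(t) - g2(t)) / g2(t), i.e. the bleach fit itself serves as
#' the time-varying baseline F0. Used for slow recordings where bleaching
#' dominates the trend (e.g. in-vivo ROI time series).
#'
#' @param trace Counts-kind [gevi_trace()].
#' @return A dff-kind [gevi_trace()]; the fit parameters are attached as
#'   attribute `"bleach_fit"`.
#' @export
bleach_correct_divisive <- function(trace) {
  stopifnot(inherits(trace, "gevi_trace"))
  fit <- fit_double_exp_decay(trace$times, trace$values)
  g2 <- fit$predict(trace$times)
  if (any(g2 <= 0)) stop("invalid fit: fitted baseline crosses zero")
  out <- trace
  out$values <- (trace$values - g2) / g2
  out$kind <- "dff"
  attr(out, "bleach_fit") <- fit[c("a", "b", "c", "d", "r2")]
  out
}

#' Bin adjacent time points
#'
#' Sums photon counts (or averages dF/F values) over `k` adjacent frames,
#' trading temporal resolution for photons per time point: binning by 4 at a
#' 50 us dwell is equivalent to a 200 us dwell. A trailing partial bin is
#' dropped so counts remain exact Poisson sums.
#'
#' @param trace A [gevi_trace()].
#' @param k Bin size (>= 1).
#' @return A [gevi_trace()] with `frame_rate / k`.
#' @export
bin_timepoints <- function(trace, k) {
  stopifnot(inherits(trace, "gevi_trace"))
  if (k < 1 || k != round(k)) stop("k must be a positive integer")
  k <- as.integer(k)
  if (k == 1L) return(trace)
  n <- (length(trace$values) %/% k) * k
  idx <- rep(seq_len(n %/% k), each = k)
  vals <- trace$values[seq_len(n)]
  agg <- if (trace$kind == "counts") {
    as.numeric(rowsum(vals, idx))
  } else {
    as.numeric(rowsum(vals, idx)) / k
  }
  t_binned <- as.numeric(rowsum(trace$times[seq_len(n)], idx)) / k
  out <- trace
  out$times <- t_binned
  out$values <- agg
  out$frame_rate <- trace$frame_rate / k
  if (!is.null(attr(trace, "schedule"))) {
    sch <- attr(trace, "schedule")
    sch$dwell_time <- sch$dwell_time * k
    attr(out, "schedule") <- sch
  }
  out
}

#' Peak-shape metrics of a dF/F response
#'
#' Measures the response extremum after a trigger: amplitude `a_max`
#' (|dF/F|), absolute peak time, time from trigger to peak, full width at
#' half maximum by linear interpolation at the half-height crossings
#' (outermost crossings at plateaus; absent when the response never returns
#' below half height), and the decay time constant from a single-exponential
#' fit of the decay phase.
#'
#' @param trace dff-kind [gevi_trace()].
#' @param trigger Trigger time (s); defaults to the first `spike_trigger`
#'   event.
#' @param polarity Response sign; defaults to the trace's polarity.
#' @param fit_decay Fit tau_decay (default TRUE).
#' @return A `response_metrics` list: `a_max`, `t_peak`, `time_to_peak`,
#'   `fwhm`, `tau_decay`, `fit_r2` (NA where not measurable, with
#'   `fwhm_flag` explaining an absent FWHM).
#' @export
peak_metrics <- function(trace, trigger = NULL, polarity = NULL,
                         fit_decay = TRUE) {
  stopifnot(inherits(trace, "gevi_trace"))
  trigger <- resolve_event(trace, trigger, "spike_trigger", "trigger")
  if (is.null(polarity)) polarity <- trace$polarity
  sel <- which(trace$times >= trigger)
  if (length(sel) < 3) stop("no response region after the trigger")
  tt <- trace$times[sel]
  yy <- trace$values[sel] * sign(polarity)  # flip so the peak is a maximum
  ip <- which.max(yy)
  a_max <- yy[ip]
  t_peak <- tt[ip]

  half <- a_max / 2
  fwhm <- NA_real_
  fwhm_flag <- NULL
  if (ip == length(yy)) {
    fwhm_flag <- "peak at last sample"
  } else {
    above <- yy >= half
    # outermost crossings bracketing the peak
    left_idx <- which(!above[seq_len(ip)])
    right_idx <- which(!above[ip:length(yy)])
    if (length(right_idx) == 0) {
      fwhm_flag <- "no return below half height"
    } else {
      i_r <- ip + right_idx[1] - 1
      t_right <- stats::approx(yy[c(i_r - 1, i_r)], tt[c(i_r - 1, i_r)],
                               xout = half)$y
      if (length(left_idx) == 0) {
        t_left <- tt[1]
        fwhm_flag <- "left crossing outside trace"
      } else {
        i_l <- left_idx[length(left_idx)]
        t_left <- stats::approx(yy[c(i_l, i_l + 1)], tt[c(i_l, i_l + 1)],
                                xout = half)$y
      }
      fwhm <- t_right - t_left
    }
  }

  tau_decay <- NA_real_
  fit_r2 <- NA_real_
  if (fit_decay && ip < length(yy) - 4) {
    fit <- tryCatch(
      fit_monoexponential_decay(trace, peak_time = t_peak,
                                polarity = polarity),
      error = function(e) NULL)
    if (!is.null(fit)) {
      tau_decay <- fit$tau
      fit_r2 <- fit$r2
    }
  }
  structure(list(a_max = a_max, t_peak = t_peak,
                 time_to_peak = t_peak - trigger, fwhm = fwhm,
                 tau_decay = tau_decay, fit_r2 = fit_r2,
                 fwhm_flag = fwhm_flag),
            class = "response_metrics")
}

#' @export
print.response_metrics <- function(x, ...) {
  cat(sprintf(
    "Response: a_max %.4g, time-to-peak %.4g ms, FWHM %s ms, tau_decay %s ms\n",
    x$a_max, 1000 * x$time_to_peak,
    if (is.na(x$fwhm)) "NA" else sprintf("%.4g", 1000 * x$fwhm),
    if (is.na(x$tau_decay)) "NA" else sprintf("%.4g", 1000 * x$tau_decay)))
  invisible(x)
}

#' Conduction velocity from peak-time delays along a dendrite
#'
#' Least-squares slope of distance against peak delay, constrained through
#' the soma reference (distance 0), plus per-location pairwise velocities.
#'
#' @param peak_times data.frame with columns `distance_um` and `t_peak`
#'   (s), containing a distance-0 soma reference.
#' @return List with `velocity_mps`, `pairwise` (data.frame of per-location
#'   velocities), and `soma_time`.
#' @examples
#' conduction_velocity(data.frame(distance_um = c(0, 150),
#'                                t_peak = c(0.010, 0.0111)))
#' @export
conduction_velocity <- function(peak_times) {
  pt <- as.data.frame(peak_times)
  stopifnot(all(c("distance_um", "t_peak") %in% names(pt)))
  if (nrow(pt) < 2) stop("need at least two locations")
  soma <- pt$distance_um == 0
  if (!any(soma)) stop("a distance-0 soma reference is required")
  t0 <- mean(pt$t_peak[soma])
  rest <- pt[!soma, , drop = FALSE]
  delay <- rest$t_peak - t0
  if (all(abs(delay) < .Machine$double.eps)) {
    stop("undefined velocity: no spread in peak delays")
  }
  d_m <- rest$distance_um * 1e-6
  v <- sum(d_m * delay) / sum(delay^2)  # regression through the origin
  pairwise <- data.frame(distance_um = rest$distance_um, delay_s = delay,
                         velocity_mps = ifelse(delay == 0, NA_real_,
                                               d_m / delay))
  list(velocity_mps = v, pairwise = pairwise, soma_time = t0)
}

#' Amplitude attenuation profile along a dendrite
#'
#' Percent reduction of response amplitude relative to the soma, and
#' (optionally) the correlation of amplitude with resting fluorescence —
#' expected to be absent if amplitudes at different brightnesses are
#' comparable.
#'
#' @param metrics data.frame with columns `distance_um` and `a_max`
#'   (optionally `rest_f`), containing a distance-0 soma reference.
#' @return data.frame with `distance_um`, `a_max`, `percent_reduction`;
#'   attribute `"rest_f_correlation"` (Pearson r and p) when `rest_f` is
#'   supplied.
#' @export
attenuation_profile <- function(metrics) {
  m <- as.data.frame(metrics)
  stopifnot(all(c("distance_um", "a_max") %in% names(m)))
  soma <- m$distance_um == 0
  if (!any(soma)) stop("a distance-0 soma reference is required")
  a0 <- mean(m$a_max[soma])
  if (a0 == 0) stop("invalid reference: soma amplitude is zero")
  out <- data.frame(distance_um = m$distance_um, a_max = m$a_max,
                    percent_reduction = (1 - m$a_max / a0) * 100)
  if ("rest_f" %in% names(m) && nrow(m) >= 3) {
    ct <- stats::cor.test(m$a_max, m$rest_f)
    attr(out, "rest_f_correlation") <- c(r = unname(ct$estimate),
                                         p = ct$p.value)
  }
  out
}

#' Average traces sample-by-sample
#'
#' @param traces List of [gevi_trace()] objects on identical time grids.
#' @return A [gevi_trace()] whose values are the pointwise mean.
#' @export
average_traces <- function(traces) {
  stopifnot(length(traces) >= 1)
  tt <- traces[[1]]$times
  for (tr in traces) {
    if (length(tr$times) != length(tt) || max(abs(tr$times - tt)) > 1e-9) {
      stop("traces must share an identical time grid")
    }
  }
  out <- traces[[1]]
  out$values <- Reduce(`+`, lapply(traces, `[[`, "values")) / length(traces)
  out$trial_id <- "average"
  out
}
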