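#' Stimulus protocol for alternating-flash experiments
#'
#' Describes a periodic visual stimulus of alternating dark and light
#' flashes and the stimulus-locked averaging grid used to summarize ROI
#' responses.
#'
#' @param flash_duration_ms Duration of each flash (default 300 ms); one
#'   cycle is dark + light, i.e. twice this.
#' @param frame_rate Imaging frame rate in Hz (default 38.9).
#' @param average_window_ms Moving-average window (default 25 ms).
#' @param average_shift_ms Grid spacing of the moving average (default
#'   8.33 ms, i.e. 120 Hz).
#' @param first_transition_s Time of the first dark-to-light cycle start
#'   (default 0).
#' @param timing_shift_ms Fixed acquisition-timing offset subtracted from
#'   frame times before re-timing (hardware-specific; default 0).
#' @return A `stimulus_protocol`.
#' @export
stimulus_protocol <- function(flash_duration_ms = 300, frame_rate = 38.9,
                              average_window_ms = 25,
                              average_shift_ms = 25 / 3,
                              first_transition_s = 0, timing_shift_ms = 0) {
  if (average_shift_ms > average_window_ms) {
    stop("average shift must not exceed the averaging window")
  }
  structure(list(flash_duration_ms = flash_duration_ms,
                 frame_rate = frame_rate,
                 average_window_ms = average_window_ms,
                 average_shift_ms = average_shift_ms,
                 first_transition_s = first_transition_s,
                 timing_shift_ms = timing_shift_ms,
                 cycle_s = 2 * flash_duration_ms / 1000),
            class = "stimulus_protocol")
}

#' Stimulus-locked moving-average response
#'
#' Reassigns each imaging frame a time relative to the start of its
#' stimulus cycle, pools frames across cycles, and computes a simple moving
#' average: at each grid point (spaced by the configured shift) the mean of
#' all samples whose re-timed position falls within the centered averaging
#' window. Per-point sample counts are retained; empty windows are returned
#' as NA and flagged rather than interpolated.
#'
#' @param trace dff-kind [gevi_trace()] (one ROI, one or more cycles).
#' @param protocol A [stimulus_protocol()].
#' @return data.frame with `time_s` (position within the cycle), `mean_dff`,
#'   `n_samples`; attribute `"gaps"` lists empty grid points.
#' @export
stimulus_locked_average <- function(trace, protocol) {
  stopifnot(inherits(trace, "gevi_trace"),
            inherits(protocol, "stimulus_protocol"))
  cyc <- protocol$cycle_s
  t_rel0 <- trace$times - protocol$first_transition_s -
    protocol$timing_shift_ms / 1000
  keep <- t_rel0 >= 0
  if (sum(keep) < 2 || max(t_rel0) < 2 * cyc) {
    stop("need at least two stimulus cycles after the first transition")
  }
  t_rel <- t_rel0[keep] %% cyc
  vals <- trace$values[keep]
  shift <- protocol$average_shift_ms / 1000
  win <- protocol$average_window_ms / 1000
  grid <- seq(0, cyc - shift / 2, by = shift)
  mean_dff <- numeric(length(grid))
  n_samples <- integer(length(grid))
  half <- win / 2
  for (i in seq_along(grid)) {
    # centered window, wrapped around the cycle boundary
    d <- abs(t_rel - grid[i])
    sel <- pmin(d, cyc - d) <= half
    n_samples[i] <- sum(sel)
    mean_dff[i] <- if (n_samples[i] > 0) mean(vals[sel]) else NA_real_
  }
  out <- data.frame(time_s = grid, mean_dff = mean_dff,
                    n_samples = n_samples)
  attr(out, "gaps") <- grid[n_samples == 0]
  attr(out, "protocol") <- protocol
  out
}

#' Responding-ROI criterion
#'
#' An ROI counts as responding when its responses at time-matched grid
#' points during the dark flash and the light flash differ significantly
#' (two-sample t-test, p < 0.01) for at least three consecutive points.
#'
#' @param dark_responses,light_responses Numeric matrices, trials x
#'   time-matched grid points.
#' @param alpha Per-point significance level (default 0.01).
#' @param min_run Required run of consecutive significant points
#'   (default 3).
#' @param var_equal Use the equal-variance t statistic (default TRUE; set
#'   FALSE for Welch).
#' @return List with `responding` (logical), `p_values`, `max_run`.
#' @export
responding_roi_test <- function(dark_responses, light_responses,
                                alpha = 0.01, min_run = 3,
                                var_equal = TRUE) {
  dark <- as.matrix(dark_responses)
  light <- as.matrix(light_responses)
  if (ncol(dark) != ncol(light)) {
    stop("dark and light responses must share the same time grid")
  }
  if (nrow(dark) < 2 || nrow(light) < 2) {
    stop("insufficient trials: at least 2 per phase are required")
  }
  p <- vapply(seq_len(ncol(dark)), function(j) {
    d <- dark[, j]; l <- light[, j]
    if (stats::sd(d) == 0 && stats::sd(l) == 0) {
      return(if (mean(d) == mean(l)) 1 else 0)
    }
    stats::t.test(d, l, var.equal = var_equal)$p.value
  }, numeric(1))
  sig <- p < alpha
  runs <- rle(sig)
  max_run <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  list(responding = max_run >= min_run, p_values = p, max_run = max_run)
}

#' Quantify a phase of the stimulus-locked response
#'
#' From the averaged response restricted to one stimulus phase
#' (depolarizing or hyperpolarizing flash): the peak amplitude `a_max`
#' (largest |dF/F|), the time of the peak relative to the flash start, and
#' the decay time constant from a single-exponential fit of the decay from
#' the peak — reported only when the fit's r-squared exceeds
#' `r2_threshold` (default 0.5), since noisier decays cannot be fitted
#' meaningfully.
#'
#' @param avg_response data.frame from [stimulus_locked_average()].
#' @param phase_window Length-2 numeric, `(start, end)` of the phase in
#'   seconds within the cycle.
#' @param r2_threshold Minimum r-squared for reporting tau_decay
#'   (default 0.5).
#' @return A `response_metrics` list: `a_max`, `t_peak` (relative to the
#'   phase start), `tau_decay` (s or NA), `fit_r2`.
#' @export
quantify_phase_response <- function(avg_response, phase_window,
                                    r2_threshold = 0.5) {
  stopifnot(length(phase_window) == 2)
  sel <- avg_response$time_s >= phase_window[1] &
    avg_response$time_s < phase_window[2] &
    !is.na(avg_response$mean_dff)
  if (sum(sel) < 3) stop("phase window contains too few grid points")
  tt <- avg_response$time_s[sel]
  yy <- avg_response$mean_dff[sel]
  ip <- which.max(abs(yy))
  a_max <- abs(yy[ip])
  t_peak <- tt[ip] - phase_window[1]
  tau_decay <- NA_real_
  fit_r2 <- NA_real_
  if (ip <= length(yy) - 5) {
    fit <- tryCatch(
      fit_monoexponential_decay(list(times = tt, values = yy),
                                peak_time = tt[ip],
                                polarity = sign(yy[ip])),
      error = function(e) NULL)
    if (!is.null(fit)) {
      fit_r2 <- fit$r2
      if (fit$r2 > r2_threshold) tau_decay <- fit$tau
    }
  }
  structure(list(a_max = a_max, t_peak = t_peak,
                 time_to_peak = t_peak, fwhm = NA_real_,
                 tau_decay = tau_decay, fit_r2 = fit_r2, fwhm_flag = NULL),
            class = "response_metrics")
}
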