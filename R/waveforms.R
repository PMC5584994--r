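#' Action-potential surrogate waveform
#'
#' Builds a smooth unimodal voltage transient — a Gaussian bump on the
#' resting potential — parameterized by its full width at half maximum and
#' peak amplitude. AP surrogates of this form (4.0 ms FWHM, 100 mV peak
#' amplitude by default) drive the forward model when no recorded AP
#' waveform is available.
#'
#' @param fwhm Full width at half maximum in ms (default 4.0).
#' @param peak_amplitude Peak amplitude above rest in mV (default 100).
#' @param rest Resting potential in mV (default -70).
#' @param duration Total duration in ms; must be at least `3 * fwhm`
#'   (default `10 * fwhm`). The peak sits at `duration / 2`.
#' @param dt Sample interval in ms; must be finer than `fwhm / 4`
#'   (default 0.1).
#' @return A `voltage_waveform`: list with `times` (s, starting at 0) and
#'   `voltages` (mV).
#' @export
make_ap_waveform <- function(fwhm = 4.0, peak_amplitude = 100, rest = -70,
                             duration = 10 * fwhm, dt = 0.1) {
  if (fwhm <= 0) stop("fwhm must be positive")
  if (duration < 3 * fwhm) stop("duration must be at least 3 * fwhm")
  if (dt >= fwhm / 4) stop("dt must be finer than fwhm / 4")
  t_ms <- seq(0, duration, by = dt)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  v <- rest + peak_amplitude * exp(-((t_ms - duration / 2)^2) / (2 * sigma^2))
  voltage_waveform(t_ms / 1000, v)
}

#' Train of action-potential surrogates
#'
#' Superposes `n_spikes` copies of the Gaussian AP surrogate with peaks
#' spaced `1/freq` apart. The inter-spike interval must exceed the FWHM so
#' individual spikes remain resolvable.
#'
#' @param freq Spike frequency in Hz.
#' @param n_spikes Number of spikes.
#' @param fwhm,peak_amplitude,rest,dt As in [make_ap_waveform()].
#' @return A `voltage_waveform`. With `n_spikes = 1` the output is identical
#'   to `make_ap_waveform(fwhm, peak_amplitude, rest, 10 * fwhm, dt)`.
#' @export
make_spike_train <- function(freq, n_spikes, fwhm = 4.0, peak_amplitude = 100,
                             rest = -70, dt = 0.1) {
  if (freq <= 0) stop("freq must be positive")
  if (n_spikes < 1) stop("n_spikes must be at least 1")
  isi_ms <- 1000 / freq
  if (n_spikes > 1 && isi_ms <= fwhm) {
    stop("inter-spike interval (", isi_ms, " ms) must exceed fwhm (",
         fwhm, " ms); spikes would merge")
  }
  base_dur <- 10 * fwhm
  duration <- base_dur + (n_spikes - 1) * isi_ms
  t_ms <- seq(0, duration, by = dt)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  centers <- base_dur / 2 + (seq_len(n_spikes) - 1) * isi_ms
  v <- rep(rest, length(t_ms))
  for (ctr in centers) {
    v <- v + peak_amplitude * exp(-((t_ms - ctr)^2) / (2 * sigma^2))
  }
  wf <- voltage_waveform(t_ms / 1000, v)
  attr(wf, "spike_times") <- centers / 1000
  wf
}

#' Voltage step waveform
#'
#' A piecewise-constant command: rest until `step_time`, `step_to` until
#' `step_time + step_duration`, then rest again (if the trace extends
#' further). Used to probe steady-state responses and step-response kinetics.
#'
#' @param step_to Step level in mV.
#' @param rest Resting level in mV (default -70).
#' @param step_time Step onset in ms (default 10).
#' @param step_duration Time held at `step_to` in ms (default 1000).
#' @param duration Total duration in ms (default
#'   `step_time + step_duration`).
#' @param dt Sample interval in ms (default 0.1).
#' @return A `voltage_waveform`.
#' @export
make_step_waveform <- function(step_to, rest = -70, step_time = 10,
                               step_duration = 1000,
                               duration = step_time + step_duration,
                               dt = 0.1) {
  if (duration < step_time) stop("duration must cover the step onset")
  t_ms <- seq(0, duration, by = dt)
  v <- ifelse(t_ms >= step_time & t_ms < step_time + step_duration,
              step_to, rest)
  voltage_waveform(t_ms / 1000, v)
}

#' Construct a voltage waveform
#'
#' @param times Sample times in seconds, strictly increasing, starting at 0.
#' @param voltages Membrane voltage in mV, same length as `times`.
#' @return A `voltage_waveform` object.
#' @export
voltage_waveform <- function(times, voltages) {
  if (length(times) != length(voltages)) {
    stop("times and voltages must have equal length")
  }
  if (length(times) < 2 || any(diff(times) <= 0)) {
    stop("times must be strictly increasing with at least two samples")
  }
  if (abs(times[1]) > 1e-12) stop("times must start at 0")
  structure(list(times = as.numeric(times), voltages = as.numeric(voltages)),
            class = "voltage_waveform")
}

#' @export
print.voltage_waveform <- function(x, ...) {
  cat(sprintf(
    "Voltage waveform: %d samples over %.4g s, range [%.1f, %.1f] mV\n",
    length(x$times), max(x$times), min(x$voltages), max(x$voltages)))
  invisible(x)
}

# Measured full width at half maximum of a sampled unimodal bump (used in
# tests and peak metrics share the crossing logic in metrics.R).
waveform_fwhm <- function(times, values, baseline = min(values)) {
  dev <- values - baseline
  half <- max(dev) / 2
  above <- which(dev >= half)
  if (length(above) == 0) return(NA_real_)
  i1 <- above[1]; i2 <- above[length(above)]
  left <- if (i1 > 1) {
    stats::approx(dev[c(i1 - 1, i1)], times[c(i1 - 1, i1)], xout = half)$y
  } else times[i1]
  right <- if (i2 < length(times)) {
    stats::approx(dev[c(i2 + 1, i2)], times[c(i2 + 1, i2)], xout = half)$y
  } else times[i2]
  right - left
}
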