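#' Indicator kinetics model
#'
#' A GEVI's response to a voltage step is well described by a weighted sum of
#' two exponentials whose time constants depend on the direction of the step:
#' depolarization from rest, repolarization back from a depolarized level,
#' hyperpolarization from rest, and repolarization back from a hyperpolarized
#' level each have their own (tau_fast, tau_slow, fraction_fast) triplet.
#' Together with a steady-state fluorescence-voltage (F-V) curve this fully
#' parameterizes the forward model used by [simulate_dff()].
#'
#' @param name Indicator label.
#' @param transitions Named list with elements `depolarization`,
#'   `repolarization_from_depolarized`, `hyperpolarization`,
#'   `repolarization_from_hyperpolarized`; each a list or named numeric with
#'   `tau_fast` (ms), `tau_slow` (ms) and `fraction_fast` (in \[0, 1\]).
#' @param fv_curve Two-column data.frame (`voltage` in mV,
#'   `steady_state_dff` dimensionless) of anchor points for the steady-state
#'   F-V relation. Must be strictly monotone in voltage and pass through
#'   `(holding_potential, 0)`.
#' @param holding_potential Resting membrane potential in mV (default -70).
#'
#' @return An object of class `indicator_kinetics`.
#' @seealso [indicator_preset()] for the packaged ASAP1, ASAP2s and ArcLight
#'   parameter sets.
#' @export
indicator_kinetics <- function(name, transitions, fv_curve,
                               holding_potential = -70) {
  regimes <- c("depolarization", "repolarization_from_depolarized",
               "hyperpolarization", "repolarization_from_hyperpolarized")
  if (!all(regimes %in% names(transitions))) {
    stop("transitions must contain all four regimes: ",
         paste(setdiff(regimes, names(transitions)), collapse = ", "))
  }
  transitions <- lapply(transitions[regimes], function(tr) {
    tr <- as.list(tr)
    stopifnot(all(c("tau_fast", "tau_slow", "fraction_fast") %in% names(tr)))
    if (tr$tau_fast <= 0) stop("tau_fast must be positive")
    if (tr$tau_slow < tr$tau_fast) stop("tau_slow must be >= tau_fast")
    if (tr$fraction_fast < 0 || tr$fraction_fast > 1) {
      stop("fraction_fast must lie in [0, 1]")
    }
    tr[c("tau_fast", "tau_slow", "fraction_fast")]
  })
  fv_curve <- as.data.frame(fv_curve)
  stopifnot(all(c("voltage", "steady_state_dff") %in% names(fv_curve)))
  fv_curve <- fv_curve[order(fv_curve$voltage), , drop = FALSE]
  dv <- diff(fv_curve$voltage)
  ds <- diff(fv_curve$steady_state_dff)
  if (any(dv <= 0)) stop("fv_curve voltages must be strictly increasing")
  if (!(all(ds > 0) || all(ds < 0))) {
    stop("fv_curve must be strictly monotone in voltage")
  }
  at_rest <- stats::approx(fv_curve$voltage, fv_curve$steady_state_dff,
                           xout = holding_potential, rule = 2)$y
  if (abs(at_rest) > 1e-9) {
    stop("fv_curve must pass through (holding_potential, 0)")
  }
  structure(list(name = name, transitions = transitions, fv_curve = fv_curve,
                 holding_potential = holding_potential),
            class = "indicator_kinetics")
}

#' Packaged indicator parameter sets
#'
#' Bi-exponential step-response kinetics (HEK293A cells, 22 degrees C) and
#' steady-state F-V anchors for the ASAP-family indicators and ArcLight Q239.
#' The F-V curve is piecewise linear through three anchors: the response to a
#' 100 mV depolarizing step (-70 to +30 mV; -38.7% for ASAP2s, -23.3% for
#' ASAP1), zero at the -70 mV holding potential, and a linear extension to
#' -100 mV. The ArcLight steady-state anchor is a configuration default
#' (-35% per 100 mV); its kinetics triplets are measured values.
#'
#' @param name One of `"ASAP1"`, `"ASAP2s"`, `"ArcLight"` (case-insensitive).
#' @return An [indicator_kinetics()] object.
#' @examples
#' k <- indicator_preset("ASAP2s")
#' k$transitions$depolarization$tau_fast  # 5.2 ms
#' @export
indicator_preset <- function(name = c("ASAP2s", "ASAP1", "ArcLight")) {
  key <- tolower(if (is.character(name)) name[1] else name)
  tab <- list(
    asap1 = list(
      ss100 = -0.233,
      depolarization                     = list(tau_fast = 2.9, tau_slow = 161, fraction_fast = 0.74),
      repolarization_from_depolarized    = list(tau_fast = 2.3, tau_slow = 177, fraction_fast = 0.63),
      hyperpolarization                  = list(tau_fast = 11,  tau_slow = 131, fraction_fast = 0.59),
      repolarization_from_hyperpolarized = list(tau_fast = 15,  tau_slow = 131, fraction_fast = 0.52)
    ),
    asap2s = list(
      ss100 = -0.387,
      depolarization                     = list(tau_fast = 5.2, tau_slow = 63,  fraction_fast = 0.56),
      repolarization_from_depolarized    = list(tau_fast = 24,  tau_slow = 106, fraction_fast = 0.49),
      hyperpolarization                  = list(tau_fast = 8.2, tau_slow = 104, fraction_fast = 0.53),
      repolarization_from_hyperpolarized = list(tau_fast = 13,  tau_slow = 114, fraction_fast = 0.51)
    ),
    arclight = list(
      ss100 = -0.35,
      depolarization                     = list(tau_fast = 20,  tau_slow = 267, fraction_fast = 0.37),
      repolarization_from_depolarized    = list(tau_fast = 113, tau_slow = 367, fraction_fast = 0.53),
      hyperpolarization                  = list(tau_fast = 20,  tau_slow = 208, fraction_fast = 0.49),
      repolarization_from_hyperpolarized = list(tau_fast = 42,  tau_slow = 265, fraction_fast = 0.57)
    )
  )
  if (!key %in% names(tab)) {
    stop("unknown indicator preset: ", name,
         " (available: ASAP1, ASAP2s, ArcLight)")
  }
  p <- tab[[key]]
  pretty <- c(asap1 = "ASAP1", asap2s = "ASAP2s", arclight = "ArcLight")[[key]]
  fv <- data.frame(
    voltage = c(-100, -70, 30),
    steady_state_dff = c(-0.3 * p$ss100, 0, p$ss100)
  )
  indicator_kinetics(pretty, p[-1], fv, holding_potential = -70)
}

#' Steady-state fractional fluorescence at a given voltage
#'
#' Piecewise-linear interpolation through the F-V anchor points, clamped to
#' the end anchors outside their span (with a warning, since the model is not
#' constrained there).
#'
#' @param kinetics An [indicator_kinetics()] object.
#' @param voltage Voltage(s) in mV.
#' @return Steady-state dF/F value(s).
#' @export
fv_value <- function(kinetics, voltage) {
  stopifnot(inherits(kinetics, "indicator_kinetics"))
  fv <- kinetics$fv_curve
  # numerically negligible overshoot (e.g. summed waveform tails) is clamped
  # silently
  tol <- 1e-6 * diff(range(fv$voltage))
  out_of_span <- voltage < min(fv$voltage) - tol |
    voltage > max(fv$voltage) + tol
  if (any(out_of_span)) {
    warning(sprintf(
      "%d voltage value(s) outside the F-V anchor span [%g, %g] mV; clamped",
      sum(out_of_span), min(fv$voltage), max(fv$voltage)))
  }
  stats::approx(fv$voltage, fv$steady_state_dff, xout = voltage, rule = 2)$y
}

#' @export
print.indicator_kinetics <- function(x, ...) {
  cat("Indicator kinetics:", x$name, "\n")
  cat("  holding potential:", x$holding_potential, "mV\n")
  for (r in names(x$transitions)) {
    tr <- x$transitions[[r]]
    cat(sprintf("  %-36s tau_fast %6.1f ms  tau_slow %6.1f ms  %%fast %4.0f\n",
                r, tr$tau_fast, tr$tau_slow, 100 * tr$fraction_fast))
  }
  cat("  F-V anchors (mV -> dF/F):",
      paste(sprintf("(%g, %.3f)", x$fv_curve$voltage,
                    x$fv_curve$steady_state_dff), collapse = " "), "\n")
  invisible(x)
}
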