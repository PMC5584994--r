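#' Simulate the dF/F response of an indicator to a voltage waveform
#'
#' Integrates two hidden first-order components, each relaxing toward the
#' steady-state dF/F given by the F-V curve at the instantaneous voltage.
#' The (tau_fast, tau_slow, fraction_fast) triplet in force at each moment
#' is selected by regime: voltage above holding and moving away uses the
#' depolarization constants, returning from above uses the repolarization
#' (from depolarized) constants, and symmetrically below holding. The output
#' is the fraction_fast-weighted sum of the two components; on a regime
#' switch both components are re-initialized at the current output value so
#' the trace stays continuous and subsequently relaxes with the new
#' regime's bi-exponential structure. Integration is exact per sample for a
#' piecewise-constant voltage (analytic exponential update), so long steps
#' reach the steady-state F-V value to machine precision.
#'
#' @param kinetics An [indicator_kinetics()] object.
#' @param waveform A [voltage_waveform()]. Must be sampled finer than a
#'   fifth of the smallest tau_fast.
#' @return List with `times` (s) and `dff` (dimensionless), plus the
#'   kinetics name as an attribute. Voltages outside the F-V anchor span are
#'   clamped with a warning.
#' @examples
#' k <- indicator_preset("ASAP2s")
#' wf <- make_step_waveform(30, step_time = 0, step_duration = 1000)
#' d <- simulate_dff(k, wf)
#' tail(d$dff, 1)  # ~ -0.387
#' @export
simulate_dff <- function(kinetics, waveform) {
  stopifnot(inherits(kinetics, "indicator_kinetics"),
            inherits(waveform, "voltage_waveform"))
  tt <- waveform$times
  vv <- waveform$voltages
  dt_s <- diff(tt)
  min_tau_s <- min(vapply(kinetics$transitions, function(tr) tr$tau_fast,
                          numeric(1))) / 1000
  if (max(dt_s) > min_tau_s / 5) {
    stop(sprintf(
      "waveform sample interval (%.3g ms) must be finer than tau_fast/5 (%.3g ms)",
      max(dt_s) * 1000, min_tau_s / 5 * 1000))
  }
  target <- fv_value(kinetics, vv)
  hold <- kinetics$holding_potential
  vtol <- 1e-9
  ytol <- 1e-12

  # Regime selection: (side of the excursion relative to holding, direction
  # of the fluorescence relaxation). While the response is still growing
  # toward a deeper steady-state level the "moving away" constants apply
  # (depolarization / hyperpolarization); once the response is relaxing
  # back toward rest the corresponding repolarization constants take over.
  dff <- numeric(length(tt))
  xf <- 0; xs <- 0
  reg <- "depolarization"
  tr <- kinetics$transitions[[reg]]
  w <- tr$fraction_fast
  y <- 0
  side <- "above"
  for (i in seq_along(tt)) {
    v <- vv[i]
    if (v > hold + vtol) side <- "above"
    else if (v < hold - vtol) side <- "below"
    # else: voltage at holding, keep the side it came from
    s <- target[i]
    rs <- sign(s)  # response direction of the current target level
    new_reg <- if (rs == 0) {
      # target is rest: the response can only relax back
      if (abs(y) < ytol) reg
      else if (side == "above") "repolarization_from_depolarized"
      else "repolarization_from_hyperpolarized"
    } else {
      drift <- (s - y) * rs
      if (drift > ytol) {
        if (side == "above") "depolarization" else "hyperpolarization"
      } else if (drift < -ytol) {
        if (side == "above") "repolarization_from_depolarized"
        else "repolarization_from_hyperpolarized"
      } else reg
    }
    if (new_reg != reg) {
      xf <- y; xs <- y  # keep the output continuous across the switch
      reg <- new_reg
      tr <- kinetics$transitions[[reg]]
      w <- tr$fraction_fast
    }
    if (i > 1) {
      h <- dt_s[i - 1] * 1000  # ms
      xf <- s + (xf - s) * exp(-h / tr$tau_fast)
      xs <- s + (xs - s) * exp(-h / tr$tau_slow)
    }
    y <- w * xf + (1 - w) * xs
    dff[i] <- y
  }
  structure(list(times = tt, dff = dff), indicator = kinetics$name,
            class = "dff_series")
}

# Linear interpolation of a dff series at arbitrary times; zero outside.
dff_at <- function(dff_series, t) {
  stats::approx(dff_series$times, dff_series$dff, xout = t,
                rule = 2, yleft = 0)$y
}

#' Simulate photon-count acquisition of a dF/F series
#'
#' Draws one Poisson photon count per frame with mean
#' `rest_rate * (1 + dff(t)) * bleach(t)`, sampling the dF/F series at frame
#' midpoints of the scanning schedule. Counts are reproducible bit-exact
#' given the seed.
#'
#' @param dff A `dff_series` from [simulate_dff()], or any list with
#'   `times` and `dff`.
#' @param rest_rate Resting photon rate, photons per dwell (= per frame for
#'   one voxel).
#' @param schedule A [scan_schedule()].
#' @param bleach A [bleach_model()] or NULL for no bleaching.
#' @param seed Integer seed.
#' @param n_frames Number of frames; defaults to the number covering the
#'   dF/F series span.
#' @param voxel_id,trial_id,events Passed to the returned [gevi_trace()].
#' @return A counts-kind [gevi_trace()] with the schedule attached as an
#'   attribute.
#' @export
simulate_photon_counts <- function(dff, rest_rate, schedule, bleach = NULL,
                                   seed = 1, n_frames = NULL,
                                   voxel_id = "v1", trial_id = "t1",
                                   events = NULL) {
  stopifnot(inherits(schedule, "scan_schedule"))
  if (rest_rate < 0) stop("rest_rate must be non-negative")
  period <- 1 / schedule$frame_rate
  if (is.null(n_frames)) n_frames <- floor(max(dff$times) / period)
  if (n_frames < 1) stop("dff series must cover at least one frame")
  t_mid <- (seq_len(n_frames) - 0.5) * period
  d <- dff_at(dff, t_mid)
  if (any(d < -1)) {
    stop("dff < -1 implies a negative photon rate; invalid input")
  }
  mu <- rest_rate * (1 + d)
  if (!is.null(bleach)) mu <- mu * bleach_value(bleach, t_mid)
  counts <- with_preserved_seed(seed, stats::rpois(n_frames, mu))
  tr <- gevi_trace(t_mid, counts, kind = "counts",
                   frame_rate = schedule$frame_rate, voxel_id = voxel_id,
                   trial_id = trial_id, events = events)
  attr(tr, "schedule") <- schedule
  attr(tr, "seed") <- seed
  tr
}

#' Simulate a multi-voxel, multi-trial voltage-imaging experiment
#'
#' For each voxel in the geometry the somatic dF/F response is scaled by the
#' voxel's attenuation factor and delayed by
#' `distance_from_soma / conduction_velocity` (backpropagation), then
#' `n_trials` independent Poisson photon-count traces are generated under
#' the scanning schedule. Per-(voxel, trial) substream seeds are derived
#' deterministically from `seed`, so the whole experiment is reproducible.
#'
#' @param kinetics An [indicator_kinetics()].
#' @param waveform A [voltage_waveform()] (somatic voltage command).
#' @param geometry A [cell_geometry()].
#' @param schedule A [scan_schedule()].
#' @param bleach A [bleach_model()] or NULL.
#' @param n_trials Trials per voxel (default 1).
#' @param seed Integer master seed.
#' @param events Event annotations copied onto every trace.
#' @return List of counts-kind [gevi_trace()] objects (voxel-major), with
#'   the noiseless per-voxel dF/F series attached as attribute
#'   `"dff_series"`.
#' @export
simulate_experiment <- function(kinetics, waveform, geometry, schedule,
                                bleach = NULL, n_trials = 1, seed = 1,
                                events = NULL) {
  stopifnot(inherits(geometry, "cell_geometry"))
  vox <- geometry$voxels
  if (!is.finite(geometry$conduction_velocity) &&
      geometry$conduction_velocity <= 0) {
    stop("conduction_velocity must be positive or Inf")
  }
  soma_dff <- simulate_dff(kinetics, waveform)
  n_sub <- nrow(vox) * n_trials
  sub_seeds <- with_preserved_seed(seed, sample.int(.Machine$integer.max - 1,
                                                    n_sub))
  traces <- vector("list", n_sub)
  dff_list <- vector("list", nrow(vox))
  k <- 0
  for (i in seq_len(nrow(vox))) {
    delay_s <- if (is.infinite(geometry$conduction_velocity)) 0 else {
      (vox$distance_um[i] * 1e-6) / geometry$conduction_velocity
    }
    dff_i <- list(times = soma_dff$times,
                  dff = vox$attenuation[i] *
                    dff_at(soma_dff, soma_dff$times - delay_s))
    dff_list[[i]] <- dff_i
    for (j in seq_len(n_trials)) {
      k <- k + 1
      traces[[k]] <- simulate_photon_counts(
        dff_i, rest_rate = vox$rest_rate[i], schedule = schedule,
        bleach = bleach, seed = sub_seeds[k],
        voxel_id = as.character(vox$voxel_id[i]),
        trial_id = sprintf("trial%02d", j), events = events)
    }
  }
  names(dff_list) <- as.character(vox$voxel_id)
  structure(traces, dff_series = dff_list, class = "gevi_experiment")
}

#' @export
as.data.frame.gevi_experiment <- function(x, ...) {
  do.call(rbind, lapply(unclass(x), as.data.frame))
}
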