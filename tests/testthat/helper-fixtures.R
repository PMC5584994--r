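# Shared fixtures for the test suite. Everything is generated in code; no
# data files are used.

ASAP2S <- indicator_preset("ASAP2s")
ASAP1 <- indicator_preset("ASAP1")
ARCLIGHT <- indicator_preset("ArcLight")

# Default study conditions: 50 us dwell, per-voxel period calibrated so that
# 5 voxels scan at 3700 Hz; resting rate of 200 photons per dwell.
REST_RATE <- 200

# A single-AP dF/F series for an indicator (trigger at `at_s`).
ap_dff <- function(kinetics, at_s = 0.3, duration_ms = 600, dt_ms = 0.1) {
  wf <- make_ap_waveform(4, 100, kinetics$holding_potential,
                         duration = duration_ms, dt = dt_ms)
  simulate_dff(kinetics, wf)
}

# Poisson counts trace from a dff series at a given schedule.
counts_trace <- function(dff, rest_rate, n_voxels, seed,
                         events = NULL) {
  sch <- scan_schedule(n_voxels)
  simulate_photon_counts(dff, rest_rate, sch, seed = seed, events = events)
}

# Events frame with spike trigger and stimulus onset at the same time.
spike_events <- function(t) {
  data.frame(kind = c("spike_trigger", "stimulus_onset"), time = c(t, t))
}

# Closed-form bi-exponential step response used as an independent oracle.
biexp_step <- function(t_ms, ss, tau_fast, tau_slow, frac_fast) {
  ss * (1 - frac_fast * exp(-t_ms / tau_fast) -
          (1 - frac_fast) * exp(-t_ms / tau_slow))
}
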