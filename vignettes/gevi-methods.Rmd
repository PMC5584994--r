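---
title: "Models and methods for GEVI trace simulation and analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for GEVI trace simulation and analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gevitools)
```

This vignette documents the scientific model behind `gevitools`: what the
forward simulator assumes, how each measurement is defined, which parameters
matter, and where the design was genuinely open and a choice had to be made.

## The measurement problem

A genetically encoded voltage indicator (GEVI) converts membrane potential
into fluorescence. Under random-access two-photon microscopy the laser hops
between a fixed set of membrane voxels, dwelling ~50 µs at each, and a
photomultiplier counts emitted photons. The resulting data are, per voxel,
a uniformly sampled photon-count series at a frame rate set by the voxel
count: with a per-voxel period of 54.054 µs, 5 voxels give 3700 Hz, 20 give
925 Hz, 80 give 231 Hz. An action potential (AP) appears as a brief
negative transient of order −10% ΔF/F against Poisson shot noise whose
relative SD is $1/\sqrt{F_0}$ per frame, $F_0$ being the resting photon
count per frame.

## Forward model

### Indicator kinetics

The response of ASAP-family indicators to a voltage step is well described
by a weighted sum of two exponentials whose constants depend on the
transition direction. `indicator_preset()` ships the measured triplets
(τ_fast, τ_slow, %fast) for ASAP1, ASAP2s and ArcLight Q239 in four
regimes: depolarization from rest, repolarization from a depolarized level,
hyperpolarization from rest, and repolarization from a hyperpolarized
level (HEK293A cells, 22 °C).

`simulate_dff()` integrates two hidden first-order states $x_f, x_s$, each
relaxing toward the steady-state ΔF/F target $s(V(t))$ given by the F–V
curve, with the time constants of the regime in force; the output is
$y = w\,x_f + (1-w)\,x_s$ with $w$ the regime's fast fraction. Two numerical
choices matter:

* **Exact stepwise integration.** Voltages are treated as piecewise
  constant over half-open frame intervals $[t, t+\Delta)$, and each state is
  updated analytically, $x \leftarrow s + (x - s)e^{-\Delta/\tau}$. Long
  steps therefore reach the F–V steady state to machine precision, and a
  depolarizing step reproduces the closed form
  $s\,(1 - w e^{-t/\tau_f} - (1-w)e^{-t/\tau_s})$ exactly at the sample
  points. Inputs must be sampled finer than one fifth of the smallest
  τ_fast (enforced).
* **Regime selection by (excursion side, relaxation direction).** While the
  response is still growing toward a deeper target the "moving away"
  constants apply (depolarization below… above holding respectively);
  once the target has crossed the current response the corresponding
  repolarization constants take over. At a switch both hidden states are
  re-initialized at the current output so the trace is continuous and then
  relaxes with the new regime's bi-exponential structure. With all four
  regimes set equal, an up-then-down step cycle is time-mirror symmetric
  (tested). The practical consequence of this rule is that during an AP's
  falling edge the indicator keeps charging with its fast depolarization
  constants until the instantaneous target crosses the response, which is
  what the fast kinetics of these indicators show.

### Steady-state F–V curve

Only two points of the F–V relation are available as printed numbers: the
response to a 100 mV step (−38.7% for ASAP2s, −23.3% for ASAP1) and zero at
the −70 mV holding potential. The curve between anchors is therefore
piecewise linear, with clamping (and a warning) outside the span. The
−100 mV anchor is set to the linear extension (−0.3 × the +30 mV anchor)
and the ArcLight +30 mV anchor to −35%; both are configuration defaults,
not measured values, and affect only simulated amplitudes, never the
kinetics-recovery results. The true nonlinearity between anchors is known
only graphically; linear interpolation is a stand-in, not a claim.

### AP surrogate

The published AP waveform is a recording, not a formula; only its 4.0 ms
full width at half maximum and 100 mV amplitude are stated. Any smooth
unimodal waveform satisfying both is admissible, so `make_ap_waveform()`
uses a Gaussian bump, and `make_spike_train()` superposes them at 1/f
spacing (refusing spacings that would merge spikes). A consequence worth
stating plainly: with the tabulated HEK-cell kinetics and *any* smooth 4 ms
surrogate, the simulated single-AP response of ASAP2s peaks near −11% with
an optical FWHM near 36 ms — the right regime, but not the exact amplitudes
measured in brain slices, whose APs and membrane environment differ. Tests
therefore check model-level properties (time-to-peak, relative ordering of
indicators, parameter recovery) rather than those printed point values.

### Photon counting, bleaching, geometry

`simulate_photon_counts()` draws one Poisson count per frame with mean
$F_0 (1 + \Delta F/F(t))\, b(t)$, sampling ΔF/F at frame midpoints;
$b(t)$ is a multi-exponential photobleaching factor normalized to 1 at
$t=0$ and applied multiplicatively to the rate. `simulate_experiment()`
adds cell geometry: each voxel's ΔF/F is scaled by a distance-dependent
attenuation factor (1 at the soma, non-increasing) and delayed by
distance / conduction velocity (default 0.16 m/s), emulating backpropagating
APs. All randomness is controlled by one master seed from which
per-(voxel, trial) substream seeds are derived; outputs are bit-exact
reproducible.

The default resting rate of 200 photons per 50 µs dwell was chosen once so
that simulated single-voxel SNR (~2 at 925 Hz) and whole-cell d′ (~40) land
in the published regime; resting rates in the source data are shown only
graphically, so this is configuration.

## Measurements

* **ΔF/F** uses F₀ = mean counts over a window 110–10 ms before the
  trigger (configurable); the transform is exactly invertible via the
  stored F₀.
* **Noise** is the SD of ΔF/F over the 200 ms before stimulus onset;
  **SNR** is peak |ΔF/F| (in the indicator's polarity, negative by default)
  divided by that noise.
* **Additive bleach correction** fits $a e^{-t/\tau} + c$ to resting
  sections (multi-start over τ decades, Levenberg–Marquardt polish) and
  subtracts the fitted curve re-anchored at a reference time. It preserves
  absolute transient heights exactly when the fit is exact (tested on
  analytic exponentials) and keeps the resting photon count constant — the
  form the d′ statistic needs. The offset term guards against
  non-bleaching traces, which the pure exponential model would fit poorly.
* **Divisive correction** fits $a e^{-bt} + c e^{-dt}$ (rates bounded at
  zero so a constant is absorbable) and uses the fit as a time-varying F₀;
  fractional modulations survive at their own amplitude.
* **Exponential fits** use a separable grid search — for fixed time
  constants the amplitudes are a linear least-squares solve — followed by
  `minpack.lm::nlsLM`. Noiseless forward-model step responses return every
  packaged kinetics triplet within 2% (tested for all indicators and all
  four regimes); near-equal rates are flagged degenerate rather than
  reported as two spurious components. r² is defined as
  $1 - SS_{res}/SS_{tot}$ on the fitted segment.
* **FWHM** interpolates the half-height crossings linearly, taking the
  outermost crossings at plateaus; a response that never returns below half
  height reports FWHM as absent with a flag rather than a fabricated value.
* **Binning** sums counts (averages ΔF/F) over k adjacent frames, dropping
  a trailing partial bin so counts remain exact Poisson sums; frame rate is
  divided and effective dwell multiplied by k. Binning by 4 trades a few
  percent of ASAP2s peak amplitude for a 2× noise reduction.
* **Conduction velocity** is the least-squares slope of distance against
  peak delay through the soma reference; pairwise velocities are also
  reported. On noisy traces the half-rise crossing is a far more stable
  timing landmark than the (flat-topped) peak, and since all voxels share
  one waveform shape any consistent landmark yields the same delays; the
  tests use it for noisy recovery.

## Spike detectability

The d′ statistic combines response amplitude, photon budget and decay time:
$d' = (\Delta F/F)\sqrt{F_0 \tau / 2}$. Units are the one place users get
burned: **F₀ must be an actual photon count per frame** (not a normalized
intensity) **and τ must be in frames**; `dprime_single()` makes the
conversion from seconds explicit. Traces must be additively
bleach-corrected first, since the statistic assumes a constant baseline.

For spike trains, F₀ and τ are recomputed per spike: at ≤ 30 Hz
fluorescence recovers between spikes and all spikes share
F₀ = mean of the inter-spike maxima; above 30 Hz the baseline shifts
within the train, so each spike uses the maximal fluorescence over its own
following interval. Peaks that cannot be located or fitted are excluded and
the inclusion fraction reported; the train d′ is the arithmetic mean over
included spikes. For a flat trace with no excursion in the indicator's
polarity the single-spike d′ is reported as exactly 0 (not included).

### ROC thresholding

Detection rates are defined by the stated simulation: 10⁶ samples, every
10th from Normal(1 + d′, 1), the rest from Normal(1, 1), i.i.d.;
single-sample spikes (N = 1); spike log-likelihood
$L(i) = f(i)\log(S_n/B) - S_n + B$; threshold swept over observed L values
and chosen to maximize TP − FP counts, ties toward the lowest threshold.
Because L is affine and increasing in f, thresholding L is equivalent to
thresholding f, which yields the closed-form oracle in `roc_analytic()`:
the optimal threshold $u$ above the noise mean solves
$p\,\varphi(u - d') = (1-p)\,\varphi(u)$, i.e.
$u = d'/2 + \ln((1-p)/p)/d'$, with detection rate $\Phi(d' - u)$ and
false-positive rate $\Phi(-u)$ per frame.

Two statistical facts the tests respect rather than fight:

* The TP − FP objective is *flat* near its maximum, so the data-chosen
  threshold wanders; empirical rates match the Gaussian tails at the chosen
  threshold to binomial precision, but agree with the rates at the exact
  optimum only to ~0.02 (tp) / ~0.005 (fp) at 10⁶ samples.
* $u(d')$ is non-monotone (minimum at $\sqrt{2\ln 9} \approx 2.1$ for
  p = 0.1), so the false-positive rate first *rises* with d′ before falling
  toward zero; only the detection rate is monotone.

## ROI analysis (alternating-flash protocols)

Frames are re-timed relative to their stimulus cycle (period = 2 × 300 ms
flash by default, 38.9 Hz imaging), pooled across cycles, and averaged with
a 25 ms moving window evaluated every 8.33 ms; empty grid windows are
flagged, never interpolated. An ROI "responds" when time-matched dark- and
light-phase samples differ (two-sample t-test, p < 0.01, equal-variance by
default) at ≥ 3 consecutive grid points — on null data fewer than 5% of
ROIs pass (tested). Phase metrics report A_max, its latency from flash
start, and τ_decay from a single-exponential fit of the decay, reported
only when r² > 0.5. A hardware-specific stimulus-timing offset can be
applied before re-timing (default 0).

## What the synthetic data do and do not show

The generator reproduces: bi-exponential voltage-step kinetics, Poisson
photon statistics (dispersion tested), the voxel-count/frame-rate ladder,
multi-exponential bleaching, amplitude attenuation and conduction delay of
backpropagating APs, and trial-to-trial independence. It does not model:
optics (PSF, AOD physics), motion, dark counts or detector afterpulsing,
subthreshold synaptic noise, indicator photophysics beyond the bleach
factor, or the true (sigmoidal) F–V nonlinearity between the printed
anchors. Passing tests therefore validate the *analysis pipeline* and the
stated statistical properties, not the in-tissue values of amplitudes or
kinetics, which depend on preparation and temperature.

## Problem sizes

Default test problem sizes were chosen to keep Monte-Carlo error well below
each assertion's tolerance: 10⁶-sample ROC streams, 48–200 trials for
averaging properties, 10⁴-frame dispersion checks, and five-voxel
geometries for propagation recovery. The acceptance script runs the full
10⁶-sample ROC at d′ = 4.1 in a few seconds.
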