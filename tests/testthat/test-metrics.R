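test_that("dF/F arithmetic and round trip are exact", {
  tt <- (seq_len(500) - 0.5) / 925
  vals <- rep(100, 500)
  vals[300] <- 85
  tr <- gevi_trace(tt, vals, kind = "counts", events = spike_events(0.3))
  d <- compute_dff(tr)
  expect_equal(attr(d, "f0"), 100)
  expect_equal(min(d$values), -0.15)
  # inverse transform recovers counts exactly
  back <- d$values * attr(d, "f0") + attr(d, "f0")
  expect_identical(back, vals)
  # constant trace gives identically zero
  cst <- gevi_trace(tt, rep(80, 500), kind = "counts",
                    events = spike_events(0.3))
  expect_true(all(compute_dff(cst)$values == 0))
})

test_that("dF/F rejects non-positive baselines and wrong kinds", {
  tt <- (seq_len(500) - 0.5) / 925
  z <- gevi_trace(tt, rep(0, 500), kind = "counts",
                  events = spike_events(0.3))
  expect_error(compute_dff(z), "F0")
  d <- gevi_trace(tt, rnorm(500), kind = "dff")
  expect_error(compute_dff(d, trigger = 0.3), "counts-kind")
})

test_that("baseline noise matches the Poisson coefficient of variation", {
  tt <- (seq_len(2000) - 0.5) / 925
  set.seed(1)
  counts <- rpois(2000, 100)
  tr <- gevi_trace(tt, counts, kind = "counts", events = spike_events(2.0))
  d <- compute_dff(tr)
  nz <- baseline_noise(d)
  n_win <- sum(tt >= 1.8 & tt < 2.0)
  se <- 0.1 / sqrt(2 * (n_win - 1))
  expect_lt(abs(nz - 0.1), 3 * se)
  # constant trace: zero noise
  cst <- gevi_trace(tt, rep(0, 2000), kind = "dff",
                    events = spike_events(2.0))
  expect_equal(baseline_noise(cst), 0)
})

test_that("short pre-stimulus windows raise a descriptive error", {
  tt <- (seq_len(200) - 0.5) / 925  # ~216 ms total
  tr <- gevi_trace(tt, rnorm(200), kind = "dff")
  expect_error(baseline_noise(tr, stimulus_onset = 0.15),
               "insufficient pre-stimulus")
})

test_that("SNR divides peak dF/F by baseline noise", {
  tt <- (seq_len(1000) - 0.5) / 925
  set.seed(2)
  vals <- rnorm(1000, 0, 0.03)
  vals[600] <- -0.15
  tr <- gevi_trace(tt, vals, kind = "dff", events = spike_events(0.6))
  measured <- snr(tr)
  expect_equal(measured, 0.15 / baseline_noise(tr), tolerance = 1e-9)
  # zero noise is undefined
  clean <- gevi_trace(tt, c(rep(0, 599), -0.15, rep(0, 400)), kind = "dff",
                      events = spike_events(0.6))
  expect_error(snr(clean), "zero")
})

test_that("additive bleach correction flattens a pure exponential", {
  tt <- seq(0, 2, by = 0.002)
  tr <- gevi_trace(tt, 100 * exp(-tt / 10), kind = "counts")
  cor <- bleach_correct_additive(tr, list(c(0, 2)), reference_time = 1)
  expect_equal(mean(cor$values), 100 * exp(-0.1), tolerance = 1e-3)
  expect_lt(diff(range(cor$values)), 0.1)
  # a bleach-free trace passes through unchanged
  flat <- gevi_trace(tt, rep(70, length(tt)), kind = "counts")
  corf <- bleach_correct_additive(flat, list(c(0, 2)), reference_time = 1)
  expect_equal(corf$values, flat$values, tolerance = 1e-6)
})

test_that("additive correction preserves absolute spike height exactly", {
  tt <- seq(0, 2, by = 0.001)
  bleach <- 120 * exp(-tt / 6)
  spike <- ifelse(tt >= 1, -30 * exp(-(tt - 1) / 0.02), 0)
  tr <- gevi_trace(tt, bleach + spike, kind = "counts")
  cor <- bleach_correct_additive(tr, list(c(0, 0.999), c(1.4, 2)),
                                 reference_time = 1)
  rest_level <- 120 * exp(-1 / 6)
  expect_equal(min(cor$values) - rest_level, -30, tolerance = 1e-4)
})

test_that("divisive correction removes a double-exponential trend", {
  tt <- seq(0, 10, by = 0.01)
  pure <- 150 * exp(-tt / 2) + 80 * exp(-tt / 30)
  d <- bleach_correct_divisive(gevi_trace(tt, pure, kind = "counts"))
  expect_lt(max(abs(d$values)), 1e-4)
  # a multiplicative modulation survives at its own amplitude
  mod <- pure * (1 + 0.1 * sin(2 * pi * 2 * tt))
  dm <- bleach_correct_divisive(gevi_trace(tt, mod, kind = "counts"))
  expect_equal(stats::sd(dm$values) * sqrt(2), 0.1, tolerance = 0.2)
  # constant traces degrade gracefully to zero dF/F
  dc <- bleach_correct_divisive(gevi_trace(tt, rep(50, length(tt)),
                                           kind = "counts"))
  expect_lt(max(abs(dc$values)), 1e-3)
})

test_that("binning sums counts, averages dF/F, and divides the frame rate", {
  tt <- (seq_len(8) - 0.5) / 925
  tr <- gevi_trace(tt, c(3, 1, 2, 4, 5, 0, 1, 2), kind = "counts")
  b <- bin_timepoints(tr, 4)
  expect_equal(b$values, c(10, 8))
  expect_equal(b$frame_rate, 925 / 4)
  expect_identical(bin_timepoints(tr, 1), tr)
  # trailing remainder is dropped
  tr9 <- gevi_trace((seq_len(9) - 0.5) / 925, c(3, 1, 2, 4, 5, 0, 1, 2, 7),
                    kind = "counts")
  expect_equal(bin_timepoints(tr9, 4)$values, c(10, 8))
  # dff kind averages
  trd <- gevi_trace(tt, rep(c(0.1, 0.3), 4), kind = "dff")
  expect_equal(bin_timepoints(trd, 2)$values, rep(0.2, 4))
  expect_error(bin_timepoints(tr, 0), "positive")
})

test_that("binning by four improves single-voxel AP SNR", {
  # signal amplitude is taken from the forward model (peak flattening),
  # noise from simulated resting photon counts; their ratio isolates the
  # sqrt(4) gain from the amplitude loss
  d <- ap_dff(ASAP2S, duration_ms = 800)
  sig <- counts_trace(d, REST_RATE, 20, seed = 1)
  noiseless <- gevi_trace(sig$times,
                          REST_RATE * (1 + dff_at(d, sig$times)),
                          kind = "counts", frame_rate = sig$frame_rate)
  peak1 <- abs(min(compute_dff(noiseless, trigger = 0.4)$values))
  nb <- bin_timepoints(noiseless, 4)
  peak4 <- abs(min(compute_dff(nb, trigger = 0.4)$values))
  noise_ratio <- mean(vapply(1:10, function(i) {
    flat <- list(times = c(0, 1.2), dff = c(0, 0))
    tr <- simulate_photon_counts(flat, REST_RATE, scan_schedule(20),
                                 seed = 600 + i)
    n1 <- baseline_noise(compute_dff(tr, trigger = 1.1), stimulus_onset = 1.1)
    tb <- bin_timepoints(tr, 4)
    n4 <- baseline_noise(compute_dff(tb, trigger = 1.1), stimulus_onset = 1.1)
    n1 / n4
  }, numeric(1)))
  expect_equal(noise_ratio, 2, tolerance = 0.15)     # sqrt(4) noise gain
  expect_gt(peak4 / peak1, 0.9)                      # mild peak flattening
  expect_gt((peak4 / peak1) * noise_ratio, 1.7)      # net SNR improvement
})

test_that("FWHM matches the Gaussian closed form across widths", {
  for (sigma_ms in c(1, 1.699, 5, 20, 50)) {
    dt <- sigma_ms / 20
    t_ms <- seq(0, 20 * sigma_ms, by = dt)
    y <- -0.2 * exp(-((t_ms - 10 * sigma_ms)^2) / (2 * sigma_ms^2))
    tr <- gevi_trace(t_ms / 1000, y, kind = "dff")
    pm <- peak_metrics(tr, trigger = 0, fit_decay = FALSE)
    expected <- 2 * sqrt(2 * log(2)) * sigma_ms
    expect_lt(abs(pm$fwhm * 1000 - expected), dt,
              label = sprintf("sigma %g ms", sigma_ms))
    expect_equal(pm$a_max, 0.2, tolerance = 1e-6)
  }
  # sigma 1.699 ms gives FWHM 4.0 ms
  t_ms <- seq(0, 40, by = 0.05)
  y <- -0.2 * exp(-((t_ms - 20)^2) / (2 * 1.699^2))
  pm <- peak_metrics(gevi_trace(t_ms / 1000, y, kind = "dff"),
                     trigger = 0, fit_decay = FALSE)
  expect_equal(pm$fwhm * 1000, 4.0, tolerance = 0.05)
})

test_that("a peak at the last sample yields an absent, flagged FWHM", {
  tt <- seq(0, 0.1, by = 0.001)
  tr <- gevi_trace(tt, -tt, kind = "dff")
  pm <- peak_metrics(tr, trigger = 0, fit_decay = FALSE)
  expect_true(is.na(pm$fwhm))
  expect_match(pm$fwhm_flag, "last sample")
})

test_that("model-level AP response shape is in the published regime", {
  # time-to-peak of the simulated ASAP2s AP response is near the measured
  # 6.0 ms; amplitude and width are model-level (surrogate AP shape)
  d <- ap_dff(ASAP2S, duration_ms = 600)
  tr <- gevi_trace(d$times, d$dff, kind = "dff", frame_rate = 1e4)
  # AP onset convention: where the surrogate rises above 10% of amplitude
  onset <- 0.3 - (4 / (2 * sqrt(2 * log(2)))) * sqrt(2 * log(10)) / 1000
  pm <- peak_metrics(tr, trigger = onset)
  expect_equal(pm$time_to_peak * 1000, 6.0, tolerance = 0.20)
  expect_gt(pm$a_max, 0.08)
  expect_lt(pm$a_max, 0.16)
  d1 <- ap_dff(ASAP1, duration_ms = 600)
  tr1 <- gevi_trace(d1$times, d1$dff, kind = "dff", frame_rate = 1e4)
  pm1 <- peak_metrics(tr1, trigger = onset)
  expect_lt(pm1$fwhm, pm$fwhm)  # faster indicator, narrower optical spike
})

test_that("conduction velocity is recovered from distance/delay pairs", {
  cv <- conduction_velocity(data.frame(distance_um = c(0, 150),
                                       t_peak = c(0.01, 0.0111)))
  expect_equal(cv$velocity_mps, 150e-6 / 1.1e-3, tolerance = 1e-9)
  expect_error(conduction_velocity(data.frame(distance_um = c(0, 100),
                                              t_peak = c(0.01, 0.01))),
               "undefined")
  expect_error(conduction_velocity(data.frame(distance_um = c(50, 100),
                                              t_peak = c(0.01, 0.02))),
               "soma")
})

test_that("attenuation profile computes percent reduction vs soma", {
  ap <- attenuation_profile(data.frame(distance_um = c(0, 144),
                                       a_max = c(0.15, 0.0936)))
  expect_equal(ap$percent_reduction, c(0, 37.6), tolerance = 1e-6)
  uni <- attenuation_profile(data.frame(distance_um = c(0, 50, 100),
                                        a_max = rep(0.1, 3)))
  expect_true(all(uni$percent_reduction == 0))
  expect_error(attenuation_profile(data.frame(distance_um = 0, a_max = 0)),
               "zero")
})

test_that("noise of an n-trace average scales as 1/sqrt(n)", {
  flat <- list(times = c(0, 1.2), dff = c(0, 0))
  sch <- scan_schedule(20)
  base <- lapply(1:64, function(i) {
    simulate_photon_counts(flat, 100, sch, seed = 2000 + i,
                           events = spike_events(1.0))
  })
  noise_at <- function(n, rep_idx) {
    sub <- base[((rep_idx - 1) * n + 1):(rep_idx * n)]
    avg <- average_traces(sub)
    baseline_noise(compute_dff(avg, trigger = 1.0))
  }
  n1 <- mean(vapply(1:32, function(r) noise_at(1, r), numeric(1)))
  n16 <- mean(vapply(1:4, function(r) noise_at(16, r), numeric(1)))
  ratio <- n1 / n16
  # expected sqrt(16) = 4; allow generous Monte-Carlo slack
  expect_gt(ratio, 3.2)
  expect_lt(ratio, 4.8)
})
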