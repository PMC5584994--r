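test_that("the d-prime formula and its edge cases", {
  expect_equal(dprime(0.15, 40, 15), 0.15 * sqrt(300))
  expect_equal(dprime(0, 100, 10), 0)
  expect_equal(dprime(0.15, 0, 15), 0)
  expect_error(dprime(-0.1, 10, 10), "non-negative")
  # monotone in every argument
  expect_true(all(diff(dprime(c(0.1, 0.2, 0.3), 40, 15)) > 0))
  expect_true(all(diff(dprime(0.15, c(10, 40, 90), 15)) > 0))
  expect_true(all(diff(dprime(0.15, 40, c(5, 15, 45))) > 0))
})

test_that("analytic ROC matches its closed form and limits", {
  r <- roc_analytic(4.1, 0.1)
  u <- 4.1 / 2 + log(9) / 4.1
  expect_equal(r$threshold_u, u)
  expect_equal(r$tp_rate, pnorm(4.1 - u))
  expect_equal(r$fp_rate, pnorm(-u))
  expect_equal(r$tp_rate, 0.935, tolerance = 0.001)
  expect_equal(r$fp_rate, 0.00486, tolerance = 0.01)
  # symmetric prior puts the threshold midway
  expect_equal(roc_analytic(3, 0.5)$threshold_u, 1.5)
  # printed bounds at the measured d-prime values
  for (dp in c(17.5, 15.0)) {
    rb <- roc_analytic(dp, 0.1)
    expect_gt(rb$tp_rate, 0.99)
    expect_lt(rb$fp_rate, 1e-8)
  }
  expect_error(roc_analytic(0), "positive")
  expect_error(roc_analytic(2, 1.5), "spike_fraction")
})

test_that("simulated ROC agrees with the analytic oracle across d-prime", {
  for (dp in c(0.5, 1, 2, 4.1, 6, 10)) {
    sim <- roc_simulate(dp, n_samples = 1e6, seed = 17)
    ana <- roc_analytic(dp, 0.1)
    # at the chosen threshold the empirical rates must match the Gaussian
    # tails to binomial precision
    tp_at <- pnorm(1 + dp - sim$threshold_f)
    fp_at <- pnorm(1 - sim$threshold_f)
    se_tp <- sqrt(tp_at * (1 - tp_at) / sim$n_signal)
    se_fp <- sqrt(fp_at * (1 - fp_at) / sim$n_noise)
    expect_lt(abs(sim$tp_rate - tp_at), 3 * se_tp + 3e-4,
              label = sprintf("tp at d'=%g", dp))
    expect_lt(abs(sim$fp_rate - fp_at), 3 * se_fp + 1e-4,
              label = sprintf("fp at d'=%g", dp))
    # the data-chosen threshold sits near the analytic optimum; the
    # objective is flat there, so the rates agree more loosely
    expect_lt(abs(sim$tp_rate - ana$tp_rate), 0.02,
              label = sprintf("tp vs optimum at d'=%g", dp))
    expect_lt(abs(sim$fp_rate - ana$fp_rate), 0.005,
              label = sprintf("fp vs optimum at d'=%g", dp))
  }
})

test_that("ROC rates are monotone in d-prime and thresholds map exactly", {
  dps <- c(1, 2, 4, 8)
  ana <- lapply(dps, roc_analytic, spike_fraction = 0.1)
  expect_true(all(diff(vapply(ana, `[[`, numeric(1), "tp_rate")) > 0))
  # the optimal threshold u = d'/2 + log(9)/d' is non-monotone (minimum at
  # sqrt(2 log 9) ~ 2.1), so the false-positive rate first rises, then
  # falls; beyond the turning point it decreases towards zero
  fp_ana <- vapply(ana, `[[`, numeric(1), "fp_rate")
  expect_gt(fp_ana[2], fp_ana[1])
  expect_true(all(diff(fp_ana[-1]) < 0))
  expect_lt(roc_analytic(20, 0.1)$fp_rate, 1e-20)
  sims <- lapply(dps, roc_simulate, n_samples = 2e5, seed = 3)
  tp <- vapply(sims, `[[`, numeric(1), "tp_rate")
  expect_true(all(diff(tp) >= 0))
  # L is affine in f: threshold_f * log(1 + d') - d' = threshold_L
  for (s in sims) {
    expect_equal(s$threshold_f * log(1 + s$dprime) - s$dprime,
                 s$threshold_L, tolerance = 1e-12)
  }
  expect_error(roc_simulate(0), "positive")
  expect_identical(roc_simulate(4.1, n_samples = 1e5, seed = 5)$tp_rate,
                   roc_simulate(4.1, n_samples = 1e5, seed = 5)$tp_rate)
})

test_that("single-spike d-prime matches generating parameters end-to-end", {
  tau <- 0.03; f0 <- 40; amp <- 0.2; fr <- 925
  tm <- (seq_len(1200) - 0.5) / fr
  dffv <- ifelse(tm >= 0.6, -amp * exp(-(tm - 0.6) / tau), 0)
  trials <- lapply(1:150, function(i) {
    set.seed(700 + i)
    gevi_trace(tm, rpois(length(tm), f0 * (1 + dffv)), kind = "counts",
               frame_rate = fr)
  })
  avg <- average_traces(trials)
  rep <- dprime_single(avg, spike_time = 0.6)
  truth <- dprime(amp, f0, tau * fr)
  expect_true(rep$included)
  expect_equal(rep$dprime, truth, tolerance = 0.10)
  expect_equal(rep$f0, f0, tolerance = 0.05)
})

test_that("a flat trace yields zero d-prime", {
  tm <- (seq_len(1000) - 0.5) / 925
  tr <- gevi_trace(tm, rep(50, 1000), kind = "counts", frame_rate = 925)
  rep <- dprime_single(tr, spike_time = 0.6)
  expect_equal(rep$dprime, 0)
  expect_false(rep$included)
})

test_that("whole-cell simulated d-prime falls in the published band", {
  d <- ap_dff(ASAP2S, duration_ms = 800)
  dps <- vapply(1:5, function(i) {
    tr <- counts_trace(d, 20 * REST_RATE, 20, seed = 40 + i)
    dprime_single(tr, spike_time = 0.395)$dprime
  }, numeric(1))
  expect_gt(mean(dps), 30)
  expect_lt(mean(dps), 80)
})

test_that("train d-prime applies the frequency-dependent F0 rules", {
  fr <- 925
  tm <- (seq_len(3000) - 0.5) / fr
  # 20 Hz train of 4 spikes starting at 1.0 s, with gap plateaus at
  # specified levels so the inter-spike maxima are known exactly
  spikes <- 1.0 + (0:3) * 0.05
  gap_levels <- c(100, 102, 98, 100)  # plateau level of each interval
  vals <- rep(100, length(tm))
  for (i in seq_along(spikes)) {
    sel <- tm >= spikes[i] & tm < spikes[i] + 0.05
    vals[sel] <- gap_levels[i] - 40 * exp(-(tm[sel] - spikes[i]) / 0.01)
  }
  tr <- gevi_trace(tm, vals, kind = "counts", frame_rate = fr)
  rep20 <- dprime_train(tr, spikes, train_freq = 20)
  expect_equal(rep20$f0_rule, "shared")
  expect_length(unique(rep20$per_spike$f0_used), 1)
  expect_equal(unique(rep20$per_spike$f0_used), mean(gap_levels),
               tolerance = 0.03)
  # 100 Hz branch: per-spike F0, generally distinct
  rep100 <- dprime_train(tr, spikes, train_freq = 100)
  expect_equal(rep100$f0_rule, "per_spike")
  # inclusion fraction reflects excluded spikes
  expect_true(rep20$inclusion_fraction <= 1 &&
                rep20$inclusion_fraction > 0)
})

test_that("a single-spike train reduces to the single-spike computation", {
  d <- ap_dff(ASAP2S, duration_ms = 800)
  tr <- counts_trace(d, 20 * REST_RATE, 20, seed = 77)
  single <- dprime_single(tr, spike_time = 0.395)
  train <- dprime_train(tr, 0.395, train_freq = 1)
  expect_equal(train$dprime, single$dprime)
  expect_equal(train$f0_rule, "single")
})

test_that("simulated train d-prime decreases at high spike frequency", {
  sch <- scan_schedule(20)
  dp_at <- function(freq) {
    wf <- make_spike_train(freq, 5, 4.0, 100, -70)
    spikes <- attr(wf, "spike_times")
    d <- simulate_dff(ASAP2S, wf)
    dps <- vapply(1:4, function(i) {
      tr <- simulate_photon_counts(d, 20 * REST_RATE, sch, seed = 500 + i)
      dprime_train(tr, spikes, train_freq = freq)$dprime
    }, numeric(1))
    mean(dps)
  }
  expect_gt(dp_at(10), dp_at(100))
})
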