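test_that("noise-free planted events are recovered with exact amplitudes", {
  ev_in <- data.frame(time_s = c(5, 12, 20.5, 33, 41),
                      amplitude_pa = rep(20, 5))
  tr <- simulate_epsc_trace(50, fs_khz = 10, noise_sd = 0, events = ev_in,
                            seed = 1)
  out <- detect_epscs(tr)
  acc <- out[out$accepted, ]
  expect_equal(nrow(acc), 5)
  expect_equal(acc$amplitude_pa, rep(20, 5), tolerance = 0.01)
  expect_equal(acc$time_s, ev_in$time_s, tolerance = 0.002)
  expect_true(all(acc$rise_ms < acc$decay_ms))
})

test_that("candidates above threshold for less than 1 ms are rejected", {
  # a sharp triangular blip 0.5 ms wide on a noisy background
  fs <- 10; n <- 15 * fs * 1000
  set.seed(1)
  x <- rnorm(n, 0, 2)
  i0 <- 5 * fs * 1000
  blip <- seq(0, 1, length.out = 3)
  x[i0:(i0 + 4)] <- x[i0:(i0 + 4)] - 30 * c(blip, rev(blip)[-1])
  out <- detect_epscs(x, fs_khz = fs)
  hit <- out[abs(out$time_s - 5) < 0.005, ]
  expect_gte(nrow(hit), 1)
  expect_false(any(hit$accepted))
  expect_lt(hit$duration_ms[1], 1)
})

test_that("traces shorter than 10 s are rejected", {
  expect_error(detect_epscs(rnorm(5000), fs_khz = 1), "shorter than 10 s")
})

test_that("detection recovers a planted Poisson rate without bias", {
  rates <- vapply(1:12, function(s) {
    tr <- simulate_epsc_trace(60, fs_khz = 5, rate_hz = 1.5,
                              amp_mean_pa = 20, amp_sd_pa = 2, noise_sd = 2,
                              seed = 300 + s)
    out <- detect_epscs(tr)
    sum(out$accepted) / 60
  }, numeric(1))
  expect_equal(mean(rates), 1.5, tolerance = 0.05)
})

test_that("frequency time course uses the minutes 3-6 window after onset", {
  # planted step: 0.02 Hz before onset at 60 s, then 2 Hz
  times <- c(25, seq(61, 479, length.out = 840))
  fc <- frequency_timecourse(times, onset_s = 60, end_s = 480)
  expect_equal(fc$minute, 0:6)
  # window covers exactly [onset+180, onset+360)
  expect_equal(fc$window_freq_hz,
               sum(times >= 240 & times < 420) / 180)
  expect_equal(fc$window_freq_hz, 2, tolerance = 0.05)
  # empty event list -> 0 Hz everywhere
  empty <- frequency_timecourse(numeric(0), onset_s = 60, end_s = 480)
  expect_true(all(empty$freq_hz == 0))
  expect_equal(empty$window_freq_hz, 0)
  expect_error(frequency_timecourse(times, onset_s = 200, end_s = 480),
               "past the end")
})

test_that("unitary EPSC amplitude averages successes only", {
  # idealized trials: identical 12 pA responses in every trial
  p <- clamp_protocol("minimal_stim", n_trials = 60)
  dt <- 0.1; n <- round(p$sweep_ms / dt)
  t_ms <- (seq_len(n) - 1) * dt
  resp <- -12 * biexp_waveform(t_ms - 51, 0.5, 4)
  cur <- matrix(rep(resp, 60), n, 60) + matrix(rnorm(n * 60, 0, 0.5), n, 60)
  rec <- sweep_set(cur, matrix(-63, n, 60), 10, p)
  u <- unitary_epsc(rec)
  expect_equal(u$p_success, 1)
  expect_equal(u$unitary_pa, 12, tolerance = 0.1)
})

test_that("unitary amplitude falls in the sampling CI of the planted mean", {
  ests <- vapply(1:8, function(s) {
    cell <- make_cell("control", 400 + s, overrides = list(noise_sd = 1))
    rec <- simulate_voltage_clamp(cell, clamp_protocol("minimal_stim"), s)
    u <- unitary_epsc(rec)
    expect_lt(abs(u$p_success - mean(rec$ground_truth$success)), 0.1)
    u$unitary_pa
  }, numeric(1))
  # planted 15 +/- 3 pA; cross-seed mean within the 95% CI of the mean
  n_eff <- 8 * 30
  expect_lt(abs(mean(ests) - 15), 1.96 * 3 / sqrt(n_eff) + 1)
})

test_that("trial counts outside 50-80 are warned about", {
  expect_warning(clamp_protocol("minimal_stim", n_trials = 40), "50-80")
  cell <- make_cell("control", 2)
  p <- suppressWarnings(clamp_protocol("minimal_stim", n_trials = 40))
  rec <- simulate_voltage_clamp(cell, p, 1)
  expect_warning(unitary_epsc(rec), "50-80")
})

test_that("no successes gives an undefined unitary amplitude", {
  p <- clamp_protocol("minimal_stim", n_trials = 60, p_success = 0)
  cell <- make_cell("control", 2)
  rec <- simulate_voltage_clamp(cell, p, 1)
  expect_message(u <- unitary_epsc(rec), "undefined")
  expect_true(is.na(u$unitary_pa))
  expect_equal(u$p_success, 0)
})

test_that("identical pulses with fast decay give PPR = 1", {
  cell <- make_cell("control", 3, overrides = list(noise_sd = 0))
  rec <- simulate_voltage_clamp(cell, clamp_protocol("paired_pulse",
                                                     ppr_true = 1), 1)
  expect_equal(paired_pulse_ratio(rec)$ppr, 1, tolerance = 0.02)
})

test_that("a planted PPR of 0.7 is recovered within 3%", {
  cell <- make_cell("control", 3, overrides = list(noise_sd = 0))
  rec <- simulate_voltage_clamp(cell, clamp_protocol("paired_pulse",
                                                     ppr_true = 0.7), 1)
  expect_equal(paired_pulse_ratio(rec)$ppr, 0.7, tolerance = 0.03)
})

test_that("PPR is invariant to amplitude scaling and the interval is checked", {
  cell <- make_cell("control", 5, overrides = list(noise_sd = 0))
  rec <- simulate_voltage_clamp(cell, clamp_protocol("paired_pulse",
                                                     ppr_true = 0.8), 1)
  a <- paired_pulse_ratio(rec)$ppr
  rec2 <- rec
  rec2$current <- rec$current * 3.7
  expect_equal(paired_pulse_ratio(rec2)$ppr, a, tolerance = 1e-10)
  bad <- rec
  bad$protocol$stim_ms <- c(50, 90)
  expect_error(paired_pulse_ratio(bad), "25 ms")
})
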