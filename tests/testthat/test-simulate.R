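test_that("passive probe transient matches the analytic RC-with-Rs solution", {
  cell <- make_cell("control", 3, overrides = list(noise_sd = 0, gNa_max = 0))
  p <- clamp_protocol("passive_probe", n_repeats = 1)
  rec <- simulate_voltage_clamp(cell, p, 1)
  dt <- rec$dt_ms
  i_on <- round(p$baseline_ms / dt) + 1
  i_off <- round((p$baseline_ms + p$step_ms) / dt)
  idx <- i_on:i_off
  meas <- rec$current[idx, 1] - mean(rec$current[1:(i_on - 1), 1])
  t_ms <- (idx - i_on) * dt
  ana <- analytic_probe_current(t_ms, 5, cell$Rs_mohm / 1000, cell$Rm_gohm,
                                cell$Cm_pf)
  expect_lt(max(abs(meas - ana)) / max(abs(ana)), 0.005)
})

test_that("identical (cell, protocol, seed) yields identical recordings", {
  cell <- make_cell("dko", 5)
  p <- clamp_protocol("passive_probe", n_repeats = 3)
  expect_identical(simulate_voltage_clamp(cell, p, 9),
                   simulate_voltage_clamp(cell, p, 9))
  b <- clamp_protocol("agonist_bath", total_s = 120,
                      schedule = data.frame(drug = "kainate", conc_um = 100,
                                            onset_s = 30, offset_s = 90))
  expect_identical(simulate_voltage_clamp(cell, b, 11)$current,
                   simulate_voltage_clamp(cell, b, 11)$current)
})

test_that("steady bath agonist current matches an independent ODE oracle", {
  skip_if_not_installed("deSolve")
  cell <- make_cell("control", 7, overrides = list(noise_sd = 0))
  p <- clamp_protocol("agonist_bath", total_s = 200,
                      schedule = data.frame(drug = "kainate", conc_um = 100,
                                            onset_s = 40, offset_s = 160))
  rec <- simulate_voltage_clamp(cell, p, 1)
  t_s <- sweep_times(rec)
  i_pkg <- rec$current[which.min(abs(t_s - 155)), 1]
  orc <- desolve_clamp(cell, function(t) -63,
                       t_ms = c(0, 40e3, 155e3),
                       wash_fun = function(t)
                         if (t < 40e3) 0 else 1 - exp(-(t - 40e3) / 20e3))
  expect_equal(i_pkg, unname(orc$i_rec[3]), tolerance = 0.02)
  # Rs-corrected amplitude recovers g_total * 63 mV within 2%
  props <- props_stub(cell$Rs_mohm, cell$Cm_pf, cell$Rm_gohm)
  resp <- agonist_response(rec, props)
  g_total <- cell$gA_max + cell$gK_max
  expect_equal(abs(resp$i_corr_pa), g_total * 63, tolerance = 0.02)
})

test_that("ground-truth event count falls in the Poisson 99% band", {
  # constant 2 Hz for 360 s -> expected 720 events
  tr <- simulate_epsc_trace(360, fs_khz = 2, rate_hz = 2, noise_sd = 0,
                            seed = 12)
  n <- nrow(tr$ground_truth$events)
  band <- qpois(c(0.005, 0.995), 720)
  expect_gte(n, band[1])
  expect_lte(n, band[2])
})

test_that("RR raises the event rate from a near-zero baseline", {
  cell <- make_cell("control", 2)
  p <- clamp_protocol("rr_epsc", total_s = 120, rr_onset_s = 60, fs_khz = 2)
  rec <- simulate_voltage_clamp(cell, p, 4)
  ev <- rec$ground_truth$events
  pre <- sum(ev$time_s < 60) / 60
  post <- sum(ev$time_s >= 60) / 60
  expect_lt(pre, 0.2)
  expect_gt(post, 5 * pre)
})

test_that("non-physical parameters are rejected at both layers", {
  expect_error(make_cell("control", 1, overrides = list(Cm_pf = -5)))
  cell <- make_cell("control", 1)
  cell$Cm_pf <- -5   # corrupt after construction: the integrator must catch it
  expect_error(simulate_voltage_clamp(cell, clamp_protocol("passive_probe"), 1),
               "positive")
})

test_that("sweep sets and ground truth round-trip through serialization", {
  cell <- make_cell("dko", 8)
  rec <- simulate_voltage_clamp(cell,
                                clamp_protocol("passive_probe", n_repeats = 2), 3)
  dir <- tempfile("sweeps")
  write_sweep_set(rec, dir)
  back <- read_sweep_set(dir)
  expect_equal(back$current, rec$current, ignore_attr = TRUE,
               tolerance = 1e-8)
  expect_equal(back$ground_truth$Rm_gohm, rec$ground_truth$Rm_gohm)
  expect_equal(back$ground_truth$gA_max, rec$ground_truth$gA_max)
  expect_equal(back$fs_khz, rec$fs_khz)
  unlink(dir, recursive = TRUE)
})
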