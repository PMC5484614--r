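# build a rectangular bath response trace by hand: i_before until onset,
# i_during over the application, back to i_before afterwards
flat_bath <- function(i_before, i_during, fs_khz = 1) {
  p <- clamp_protocol("agonist_bath", fs_khz = fs_khz)
  dt <- 1 / fs_khz
  n <- round(p$total_s * 1000 / dt)
  t_s <- (seq_len(n) - 1) * dt / 1000
  cur <- ifelse(t_s >= 60 & t_s < 180, i_during, i_before)
  sweep_set(matrix(cur, n, 1), matrix(p$hold_mv, n, 1), fs_khz, p)
}

test_that("with Rs = 0 the corrected current equals the measured current", {
  rec <- flat_bath(-10, -210)
  resp <- agonist_response(rec, props_stub(0, 25))
  expect_equal(resp$delta_i_pa, -200, tolerance = 0.01)
  expect_equal(resp$i_corr_pa, resp$delta_i_pa)
  expect_equal(resp$density_pa_pf, resp$i_corr_pa / 25)
})

test_that("Rs correction recovers a planted conductance within 2% (circuit)", {
  cell <- make_cell("control", 3,
                    overrides = list(noise_sd = 0, Rs_mohm = 20,
                                     gA_max = 1.2, gK_max = 0.3))
  rec <- simulate_voltage_clamp(cell, clamp_protocol("agonist_bath"), 1)
  resp <- agonist_response(rec, props_stub(20, cell$Cm_pf, cell$Rm_gohm))
  expect_equal(abs(resp$i_corr_pa) / 63, 1.5, tolerance = 0.02)
})

test_that("Rs correction stays within 2% up to 30 MOhm and 1 nA (property)", {
  for (rs in c(5, 15, 30)) {
    for (g_d in c(2, 8, 17)) {
      rs_g <- rs / 1000
      before <- analytic_bath_steady(-63, rs_g, 1.5, -63, 0)
      during <- analytic_bath_steady(-63, rs_g, 1.5, -63, g_d)
      if (abs(during$i_rec) > 1000) next    # beyond the stated current range
      rec <- flat_bath(before$i_rec, during$i_rec)
      resp <- agonist_response(rec, props_stub(rs, 25))
      expect_equal(abs(resp$i_corr_pa) / 63, g_d, tolerance = 0.02)
    }
  }
})

test_that("a collapsed driving force is flagged unquantifiable", {
  rec <- flat_bath(-5, -600)
  resp <- agonist_response(rec, props_stub(100, 25))   # Vm pulled to -3 mV
  expect_true(resp$unquantifiable)
  expect_true(is.na(resp$i_corr_pa))
})

test_that("drug windows outside the recording are rejected", {
  rec <- flat_bath(-10, -210)
  expect_error(agonist_response(rec, props_stub(10, 25),
                                measure_window = c(60, 500)),
               "past the recording")
})

test_that("RI of an ohmic conductance with E_rev = 0 is 17/63", {
  ctrl <- ideal_step_sweeps(0)
  drug <- ideal_step_sweeps(2.5)
  iv <- build_iv_and_ri(ctrl, drug)
  expect_equal(iv$ri, 17 / 63, tolerance = 1e-6)
  # drug-evoked currents are Ohm's law at every step voltage
  expect_equal(iv$current_pa, 2.5 * iv$voltage_mv, tolerance = 1e-6)
})

test_that("a fully rectifying conductance has RI = 0", {
  ctrl <- ideal_step_sweeps(0)
  drug <- ideal_step_sweeps(0)
  g <- 2.5
  rectified <- ifelse(drug$vcmd < 0, g * drug$vcmd, 0)
  drug$current <- drug$current + rectified
  expect_equal(build_iv_and_ri(ctrl, drug)$ri, 0)
})

test_that("RI of a rectifying knockout cell matches the conductance law", {
  cell <- make_cell("dko", 21, overrides = list(noise_sd = 0))
  ctrl <- simulate_voltage_clamp(cell, clamp_protocol("step_iv",
                                                      spermine = TRUE), 1)
  drug <- simulate_voltage_clamp(cell, clamp_protocol("step_iv",
                                                      drug = "kainate",
                                                      spermine = TRUE), 1)
  iv <- build_iv_and_ri(ctrl, drug)
  f <- function(v) 1 / (1 + exp((v - cell$rect_vh) / cell$rect_k))
  af <- cell$gA_max / (cell$gA_max + cell$gK_max)
  ri_pred <- ((f(17) * af + (1 - af)) * 17) / ((f(-63) * af + (1 - af)) * 63)
  expect_equal(iv$ri, ri_pred, tolerance = 0.05)
  expect_lt(iv$ri, 0.5 * 17 / 63)   # clearly inwardly rectifying
})

test_that("protocol mismatch is rejected", {
  a <- ideal_step_sweeps(0, fs_khz = 10)
  b <- ideal_step_sweeps(1, fs_khz = 20)
  expect_error(build_iv_and_ri(a, b), "differ")
})

test_that("block_fraction arithmetic", {
  expect_equal(block_fraction(-200, -40), 80)
  expect_equal(block_fraction(-150, -150), 0)
  expect_error(block_fraction(0, -10), "zero")
})

test_that("current density is invariant to cell size at fixed channel density", {
  dens <- vapply(c(10, 20, 35), function(cm) {
    g_tot <- 10 * cm / 63
    cell <- make_cell("control", 5,
                      overrides = list(noise_sd = 0, Cm_pf = cm,
                                       gA_max = 0.8 * g_tot,
                                       gK_max = 0.2 * g_tot))
    rec <- simulate_voltage_clamp(cell, clamp_protocol("agonist_bath"), 1)
    abs(agonist_response(rec, props_stub(cell$Rs_mohm, cm,
                                         cell$Rm_gohm))$density_pa_pf)
  }, numeric(1))
  expect_lt(diff(range(dens)) / mean(dens), 0.02)
})
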