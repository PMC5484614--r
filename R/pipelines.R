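#' Simulate and analyze an agonist cohort end-to-end
#'
#' For each cell: draw a cell from the preset, simulate the passive probe,
#' fit passive properties, apply QC (series-resistance rules bypassed, as
#' all cells are included in the kainate-current analysis and voltage
#' errors are corrected arithmetically), simulate the kainate bath
#' application and quantify the Rs-corrected current density. With
#' `gyki = TRUE` the antagonist is co-applied and the percent block
#' measured per cell.
#'
#' @param preset A [genotype_preset()] or name.
#' @param n_cells Cells in the cohort.
#' @param seed Master seed; per-cell seeds are drawn from it.
#' @param gyki Include the antagonist co-application.
#' @return Data.frame, one row per cell: recovered passive properties,
#'   QC flags, measured and corrected current, density, and (with
#'   `gyki`) the percent block.
#' @export
simulate_agonist_cohort <- function(preset, n_cells = 20, seed = 1,
                                    gyki = FALSE) {
  if (is.character(preset)) preset <- genotype_preset(preset)
  seeds <- with_seed(seed, matrix(sample.int(.Machine$integer.max - 1,
                                             n_cells * 3), ncol = 3))
  proto_probe <- clamp_protocol("passive_probe")
  proto_bath <- clamp_protocol("agonist_bath", gyki = gyki)
  rows <- lapply(seq_len(n_cells), function(i) {
    cell <- make_cell(preset, seeds[i, 1])
    probe <- simulate_voltage_clamp(cell, proto_probe, seeds[i, 2])
    props <- qc_cell(fit_passive(probe), ignore_rs = TRUE)
    bath <- simulate_voltage_clamp(cell, proto_bath, seeds[i, 3])
    resp <- agonist_response(bath, props,
                             measure_window = if (gyki)
                               c(60, 180) else NULL)
    row <- data.frame(
      cell = i, genotype = preset$name,
      rm_gohm = props$Rm_gohm, cm_pf = props$Cm_pf, rs_mohm = props$Rs_mohm,
      qc_pass = props$qc_pass,
      delta_i_pa = resp$delta_i_pa, i_corr_pa = resp$i_corr_pa,
      density_pa_pf = resp$density_pa_pf,
      true_density_pa_pf = cell$ground_truth$density_pa_pf,
      true_ampar_fraction = cell$ground_truth$ampar_fraction)
    if (gyki) row$block_pct <- agonist_block(bath, props)$block_pct
    row
  })
  do.call(rbind, rows)
}

#' Kainate current-density contrast between two genotype cohorts
#'
#' Runs [simulate_agonist_cohort()] for both presets and reports the
#' percent reduction (and ratio) of the mean Rs-corrected,
#' capacitance-normalized current density of cohort `b` relative to
#' cohort `a` (QC-passing cells). Both cohorts are generated from the same
#' master seed (common random numbers): cell-level draws are
#' preset-independent in [make_cell()], so each comparison cell is paired
#' with a control counterpart and the contrast isolates the planted
#' genotype effect from cell-sampling noise.
#'
#' @param preset_a,preset_b Preset names (reference and comparison).
#' @param n_cells Cells per cohort.
#' @param seed Master seed, shared by the two cohorts.
#' @return List: `reduction_pct` = `100 (1 - mean_b/mean_a)`,
#'   `ratio_pct` = `100 mean_b/mean_a`, per-cohort mean densities and the
#'   per-cell tables.
#' @export
kainate_density_contrast <- function(preset_a = "control", preset_b = "dko",
                                     n_cells = 20, seed = 1) {
  a <- simulate_agonist_cohort(preset_a, n_cells, seed)
  b <- simulate_agonist_cohort(preset_b, n_cells, seed)
  ma <- mean(abs(a$density_pa_pf[a$qc_pass]))
  mb <- mean(abs(b$density_pa_pf[b$qc_pass]))
  list(reduction_pct = 100 * (1 - mb / ma), ratio_pct = 100 * mb / ma,
       mean_density = c(stats::setNames(ma, preset_a),
                        stats::setNames(mb, preset_b)),
       cells_a = a, cells_b = b)
}

#' Mean antagonist block across a cohort
#'
#' @param preset Preset name.
#' @param n_cells Cells.
#' @param seed Master seed.
#' @return List: `mean_block_pct`, per-cell table.
#' @export
gyki_block_cohort <- function(preset, n_cells = 20, seed = 1) {
  cells <- simulate_agonist_cohort(preset, n_cells, seed, gyki = TRUE)
  list(mean_block_pct = mean(cells$block_pct[cells$qc_pass]), cells = cells)
}

#' Simulate and analyze an RR-evoked EPSC cohort
#'
#' For each cell: simulate a gap-free recording with Ruthenium Red applied
#' after a baseline period, run the full detection chain (2 Hz high-pass,
#' 3 x SD threshold, >= 1 ms, rise < decay), and summarize the frequency
#' over minutes 3–6 after drug onset and the mean accepted amplitude in
#' that window.
#'
#' @param preset A [genotype_preset()] or name.
#' @param n_cells Cells.
#' @param seed Master seed.
#' @return Data.frame per cell: `window_freq_hz`, `mean_amp_pa`,
#'   `n_events`, `true_rate_hz`.
#' @export
rr_frequency_cohort <- function(preset, n_cells = 15, seed = 1) {
  if (is.character(preset)) preset <- genotype_preset(preset)
  seeds <- with_seed(seed, matrix(sample.int(.Machine$integer.max - 1,
                                             n_cells * 2), ncol = 2))
  proto <- clamp_protocol("rr_epsc")
  rows <- lapply(seq_len(n_cells), function(i) {
    cell <- make_cell(preset, seeds[i, 1])
    rec <- simulate_voltage_clamp(cell, proto, seeds[i, 2])
    ev <- detect_epscs(rec)
    fc <- frequency_timecourse(ev, onset_s = proto$rr_onset_s)
    win <- proto$rr_onset_s + c(3, 6) * 60
    in_win <- ev$accepted & ev$time_s >= win[1] & ev$time_s < win[2]
    data.frame(cell = i, genotype = preset$name,
               window_freq_hz = fc$window_freq_hz,
               mean_amp_pa = if (any(in_win)) mean(ev$amplitude_pa[in_win])
                             else NA_real_,
               n_events = sum(ev$accepted),
               true_rate_hz = cell$ground_truth$rr_rate_hz)
  })
  do.call(rbind, rows)
}

#' RR-evoked EPSC frequency contrast between genotypes
#'
#' Both cohorts share the master seed (common random numbers, see
#' [kainate_density_contrast()]), pairing each mutant cell with a control
#' counterpart whose synapse-rate draw differs only by the planted
#' `synapse_rate_rel` multiplier.
#'
#' @param preset_a,preset_b Preset names.
#' @param n_cells Cells per genotype.
#' @param seed Master seed, shared by the two cohorts.
#' @return List: `freq_reduction_pct`, `amplitude_p` (two-group test on
#'   per-cell mean amplitudes), per-cohort tables.
#' @export
epsc_frequency_contrast <- function(preset_a = "control", preset_b = "dko",
                                    n_cells = 15, seed = 1) {
  a <- rr_frequency_cohort(preset_a, n_cells, seed)
  b <- rr_frequency_cohort(preset_b, n_cells, seed)
  amp_p <- tryCatch(
    compare_groups(a$mean_amp_pa[!is.na(a$mean_amp_pa)],
                   b$mean_amp_pa[!is.na(b$mean_amp_pa)])$p,
    error = function(e) NA_real_)
  list(freq_reduction_pct =
         100 * (1 - mean(b$window_freq_hz) / mean(a$window_freq_hz)),
       amplitude_p = amp_p, cells_a = a, cells_b = b)
}

#' Oligodendrocyte-density contrast on a synthetic histology cohort
#'
#' Generates a P14-style count cohort, computes per-animal CC1+ densities
#' and compares genotypes with the normality-gated test.
#'
#' @param preset Preset name.
#' @param n_per_group Animals per genotype.
#' @param age Age preset for the planted effect.
#' @param seed Integer seed.
#' @return List: `reduction_pct`, `p`, `test`, per-animal table.
#' @export
ol_density_contrast <- function(preset = "dko", n_per_group = 14,
                                age = "P14", seed = 1) {
  tab <- simulate_histology_counts(preset, n_control = n_per_group,
                                   n_mutant = n_per_group, age = age,
                                   seed = seed)
  m <- count_metrics(tab)
  dc <- m$density_CC1[m$genotype == "control"]
  dm <- m$density_CC1[m$genotype == "mutant"]
  cmp <- compare_groups(dc, dm)
  list(reduction_pct = 100 * (1 - mean(dm) / mean(dc)), p = cmp$p,
       test = cmp$test, animals = m)
}
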