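#' Genotype presets for the synthetic-data generator
#'
#' Bundles the generator parameters that differ between the three genotypes
#' studied: `control` (GluA2/3 intact), `dko` (GluA2/GluA3 double knockout in
#' the oligodendrocyte lineage) and `tko` (GluA2/3/4 triple knockout).
#' Relative values are expressed as fractions of the control condition:
#'
#' * `kainate_density_rel` — fraction of the control total kainate-evoked
#'   current density at −63 mV (dko 0.53, i.e. a ~47% reduction; tko
#'   0.23 × dko ≈ 0.122 of control).
#' * `ampar_fraction` — fraction of the kainate-evoked current carried by
#'   AMPARs (blocked by GYKI-52466): 0.80 in control and dko, 0.39 in tko.
#' * `ampar_rectifying` — whether AMPARs lack GluA2 and hence show
#'   polyamine-dependent inward rectification with intracellular spermine
#'   (`TRUE` only for dko; the residual tko current is kainate-receptor
#'   mediated and linear).
#' * `synapse_rate_rel` — fraction of the control Ruthenium-Red-evoked EPSC
#'   frequency (dko 0.30, i.e. ~70% fewer events; tko 0.01, "almost none").
#' * `epsc_amplitude_mean`, `epsc_amplitude_sd` (pA) — quantal amplitude
#'   parameters, identical across genotypes (amplitude is genotype-invariant).
#' * `ol_density_effect` — fractional reduction of CC1+ oligodendrocyte
#'   density by age (P7 0.22, P14 0.27; no planted effect at P21/P70).
#' * `caspase_factor` — fold-change of the apoptotic (cleaved Caspase-3+)
#'   fraction of Olig2+ cells (dko 1.194, tko 1.242).
#' * `myelin_density_effect` — fractional reduction of transverse myelin
#'   figures per unit area at P14 (0.20 for dko and tko).
#'
#' @param name One of `"control"`, `"dko"`, `"tko"`.
#' @return An object of class `genotype_preset` (a named list).
#' @examples
#' genotype_preset("dko")$kainate_density_rel  # 0.53
#' @export
genotype_preset <- function(name = c("control", "dko", "tko")) {
  name <- match.arg(name)
  base <- list(
    name = name,
    epsc_amplitude_mean = 20,  # pA
    epsc_amplitude_sd = 4      # pA
  )
  spec <- switch(name,
    control = list(
      kainate_density_rel = 1.0, ampar_fraction = 0.80,
      ampar_rectifying = FALSE, synapse_rate_rel = 1.0,
      ol_density_effect = c(P7 = 0, P14 = 0, P21 = 0, P70 = 0),
      caspase_factor = 1.0, myelin_density_effect = 0.0
    ),
    dko = list(
      kainate_density_rel = 0.53, ampar_fraction = 0.80,
      ampar_rectifying = TRUE, synapse_rate_rel = 0.30,
      ol_density_effect = c(P7 = 0.22, P14 = 0.27, P21 = 0, P70 = 0),
      caspase_factor = 1.194, myelin_density_effect = 0.20
    ),
    tko = list(
      kainate_density_rel = 0.53 * 0.23, ampar_fraction = 0.39,
      ampar_rectifying = FALSE, synapse_rate_rel = 0.01,
      ol_density_effect = c(P7 = 0.22, P14 = 0.27, P21 = 0, P70 = 0),
      caspase_factor = 1.242, myelin_density_effect = 0.20
    )
  )
  out <- c(base, spec)
  class(out) <- "genotype_preset"
  validate_preset(out)
  out
}

validate_preset <- function(p) {
  stopifnot(
    p$kainate_density_rel > 0, p$kainate_density_rel <= 1,
    p$ampar_fraction >= 0, p$ampar_fraction <= 1,
    p$synapse_rate_rel > 0, p$synapse_rate_rel <= 1,
    is.logical(p$ampar_rectifying),
    p$epsc_amplitude_mean > 0, p$epsc_amplitude_sd >= 0
  )
  invisible(p)
}

#' @export
print.genotype_preset <- function(x, ...) {
  cat("<genotype_preset>", x$name, "\n")
  cat(sprintf("  kainate density (rel. control): %.3f\n", x$kainate_density_rel))
  cat(sprintf("  AMPAR fraction (GYKI-blockable): %.2f  rectifying: %s\n",
              x$ampar_fraction, x$ampar_rectifying))
  cat(sprintf("  synapse rate (rel. control): %.2f\n", x$synapse_rate_rel))
  cat(sprintf("  EPSC amplitude: %.1f +/- %.1f pA (genotype-invariant)\n",
              x$epsc_amplitude_mean, x$epsc_amplitude_sd))
  invisible(x)
}

#' Draw a synthetic OP cell from a genotype preset
#'
#' Samples the parameters of a single-compartment oligodendrocyte precursor
#' model. Cell-level random draws (Rm, Cm, Rs, Na+ conductance, density
#' scatter, receptor-fraction jitter, synapse-rate scatter) depend only on
#' `seed`, not on the preset, so cells generated with the same seed under two
#' presets differ exactly by the planted genotype multipliers: for example,
#' the total kainate-evoked conductance of `(dko, seed)` is exactly 0.53 of
#' `(control, seed)`.
#'
#' Distributions (documented generator conditions):
#' * Rm: 1 + lognormal(log 0.5, 0.5) GΩ — all cells pass the ≥1 GΩ OP rule.
#' * Cm: uniform 10–35 pF. Rs: uniform 10–20 MΩ (typical reported range).
#' * Total kainate-evoked current density: 10 pA/pF in control on average
#'   (arbitrary absolute scale), lognormal cell scatter with CV 0.15,
#'   multiplied by `kainate_density_rel`.
#' * AMPAR fraction: preset mean with SD 0.03 (0.04 for tko), truncated.
#' * RR-evoked plateau EPSC rate: 2 Hz in control on average, lognormal
#'   scatter CV 0.2, multiplied by `synapse_rate_rel`; spontaneous baseline
#'   0.02 Hz.
#' * Quantal amplitude: preset mean and SD scaled by a cell-level lognormal
#'   factor (CV 0.15); the factor's draw is preset-independent, so the
#'   planted amplitude distribution is genotype-invariant.
#'
#' @param preset A [genotype_preset()] or preset name.
#' @param seed Integer seed; identical `(preset, seed)` gives identical cells.
#' @param overrides Named list of parameter overrides applied after sampling
#'   (e.g. `list(noise_sd = 0, Rs_mohm = 15)`).
#' @return An object of class `cell_params`, with the planted ground truth in
#'   `$ground_truth`.
#' @export
make_cell <- function(preset, seed, overrides = list()) {
  if (is.character(preset)) preset <- genotype_preset(preset)
  if (!inherits(preset, "genotype_preset")) stop("unknown preset")
  draws <- with_seed(seed, list(
    rm = 1 + rlnorm(1, log(0.5), 0.5),      # GOhm
    cm = runif(1, 10, 35),                   # pF
    rs = runif(1, 10, 20),                   # MOhm
    gna = runif(1, 4, 10),                   # nS
    dens_z = rnorm(1),                       # density scatter
    af_z = rnorm(1),                         # receptor-fraction jitter
    rate_z = rnorm(1),                       # synapse-rate scatter
    amp_z = rnorm(1)                         # quantal-amplitude scatter
  ))
  dens_cv <- 0.15
  dens_total <- 10 * preset$kainate_density_rel *
    exp(draws$dens_z * dens_cv - dens_cv^2 / 2)      # pA/pF at -63 mV
  af_sd <- if (preset$name == "tko") 0.04 else 0.03
  af <- min(0.98, max(0.02, preset$ampar_fraction + af_sd * draws$af_z))
  g_total <- dens_total * draws$cm / 63              # nS (|I| = g * 63 mV)
  rate_cv <- 0.2
  rr_rate <- 2 * preset$synapse_rate_rel *
    exp(draws$rate_z * rate_cv - rate_cv^2 / 2)      # Hz plateau under RR
  # cell-level quantal amplitude scale: genotype-invariant by construction
  # (the draw does not involve the preset)
  amp_cv <- 0.15
  amp_scale <- exp(draws$amp_z * amp_cv - amp_cv^2 / 2)

  cell <- list(
    genotype = preset$name,
    Rm_gohm = draws$rm, Cm_pf = draws$cm, Rs_mohm = draws$rs,
    E_leak = -70, E_glu = 0, E_na = 60,
    gNa_max = draws$gna,
    na_kinetics = list(vhalf_m = -30, k_m = 7, tau_m = 0.15,
                       vhalf_h = -55, k_h = 7, tau_h = 1.5),
    gA_max = g_total * af, gK_max = g_total * (1 - af),
    ampar_rectifying = preset$ampar_rectifying,
    rect_vh = -20, rect_k = 15,
    rr_rate_hz = rr_rate, rr_baseline_hz = 0.02,
    epsc_amplitude_mean = preset$epsc_amplitude_mean * amp_scale,
    epsc_amplitude_sd = preset$epsc_amplitude_sd * amp_scale,
    noise_sd = 2, junction_potential = -3,
    seed = as.integer(seed)
  )
  for (nm in names(overrides)) cell[[nm]] <- overrides[[nm]]
  stopifnot(cell$Rm_gohm > 0, cell$Cm_pf > 0, cell$Rs_mohm > 0)
  cell$ground_truth <- list(
    Rm_gohm = cell$Rm_gohm, Cm_pf = cell$Cm_pf, Rs_mohm = cell$Rs_mohm,
    gA_max = cell$gA_max, gK_max = cell$gK_max,
    g_kainate_total = cell$gA_max + cell$gK_max,
    density_pa_pf = (cell$gA_max + cell$gK_max) * 63 / cell$Cm_pf,
    ampar_fraction = af, rr_rate_hz = cell$rr_rate_hz,
    epsc_amplitude_mean = cell$epsc_amplitude_mean
  )
  class(cell) <- "cell_params"
  cell
}

#' @export
print.cell_params <- function(x, ...) {
  cat("<cell_params>", x$genotype, "\n")
  cat(sprintf("  Rm %.2f GOhm, Cm %.1f pF, Rs %.1f MOhm\n",
              x$Rm_gohm, x$Cm_pf, x$Rs_mohm))
  cat(sprintf("  gA %.3f nS, gK %.3f nS (rectifying: %s), gNa %.1f nS\n",
              x$gA_max, x$gK_max, x$ampar_rectifying, x$gNa_max))
  invisible(x)
}
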