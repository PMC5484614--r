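#' Voltage-clamp protocol specifications
#'
#' Constructs the stimulation/acquisition protocols used in the study:
#'
#' * `passive_probe`: repeated +5 mV steps from −63 mV for passive-property
#'   estimation.
#' * `step_iv`: 200 ms steps in 20 mV increments from −63 mV covering exactly
#'   \{−103, −83, −63, −43, −23, −3, +17\} mV, optionally during bath kainate
#'   (for I–V / rectification analysis) and with or without intracellular
#'   spermine.
#' * `agonist_bath`: gap-free recording at −63 mV with a bath drug schedule
#'   (kainate 100 µM; optionally GYKI-52466 50 µM co-applied).
#' * `rr_epsc`: gap-free recording at −83 mV with Ruthenium Red applied after
#'   a baseline period (EPSC frequency analysis).
#' * `minimal_stim`: 50–80 stimulus-locked trials for unitary EPSC amplitude.
#' * `paired_pulse`: two pulses 25 ms apart, ten repeats, for the PPR.
#'
#' @param kind Protocol kind (see above).
#' @param ... Overrides of kind-specific defaults (e.g. `fs_khz`,
#'   `n_repeats`, `spermine`, `drug`, `n_trials`, `rr_onset_s`).
#' @return An object of class `clamp_protocol`.
#' @export
clamp_protocol <- function(kind = c("passive_probe", "step_iv", "agonist_bath",
                                    "rr_epsc", "minimal_stim", "paired_pulse"),
                           ...) {
  kind <- match.arg(kind)
  p <- switch(kind,
    passive_probe = list(
      hold_mv = -63, probe_mv = 5, fs_khz = 50,
      baseline_ms = 60, step_ms = 40, tail_ms = 40, n_repeats = 20
    ),
    step_iv = list(
      hold_mv = -63, step_mv = seq(-103, 17, by = 20), fs_khz = 20,
      baseline_ms = 100, step_ms = 200, tail_ms = 100,
      drug = NULL,            # NULL or "kainate" (steps during steady bath)
      spermine = FALSE,
      template_repeats = 16   # extra -20 mV sweeps averaged into the
                              # passive-subtraction template
    ),
    agonist_bath = list(
      hold_mv = -63, fs_khz = 1, total_s = 240, spermine = FALSE,
      schedule = data.frame(drug = "kainate", conc_um = 100,
                            onset_s = 60, offset_s = 180),
      gyki = FALSE
    ),
    rr_epsc = list(
      hold_mv = -83, fs_khz = 5, total_s = 390, rr_onset_s = 30,
      gyki = FALSE
    ),
    minimal_stim = list(
      hold_mv = -63, fs_khz = 10, n_trials = 60, sweep_ms = 150,
      stim_ms = 50, p_success = 0.5, amp_mean_pa = 15, amp_sd_pa = 3
    ),
    paired_pulse = list(
      hold_mv = -63, fs_khz = 10, n_repeats = 10, sweep_ms = 200,
      stim_ms = c(50, 75), ipi_ms = 25, amp1_pa = 60, ppr_true = 0.9
    )
  )
  ov <- list(...)
  for (nm in names(ov)) p[[nm]] <- ov[[nm]]
  p$kind <- kind
  if (kind == "agonist_bath" && isTRUE(p$gyki) &&
      !any(p$schedule$drug == "gyki")) {
    # co-apply the AMPAR antagonist during a prolonged agonist application
    p$schedule <- data.frame(
      drug = c("kainate", "gyki"), conc_um = c(100, 50),
      onset_s = c(60, 180), offset_s = c(360, 300))
    p$total_s <- max(p$total_s, 420)
  }
  if (kind == "step_iv" &&
      !isTRUE(all.equal(p$step_mv, seq(-103, 17, by = 20))))
    warning("non-standard step voltages; the canonical protocol is -103..+17 mV in 20 mV increments")
  if (kind == "paired_pulse" && length(p$stim_ms) == 2 &&
      abs(diff(p$stim_ms) - 25) > 1e-9)
    warning("paired-pulse interval is not 25 ms")
  if (kind == "minimal_stim" && (p$n_trials < 50 || p$n_trials > 80))
    warning("minimal-stimulation trial count outside the 50-80 range")
  class(p) <- "clamp_protocol"
  p
}

#' @export
print.clamp_protocol <- function(x, ...) {
  cat("<clamp_protocol>", x$kind, sprintf("(hold %g mV, %g kHz)\n",
      x$hold_mv, x$fs_khz))
  invisible(x)
}
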