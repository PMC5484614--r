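#' Quantify a bath-agonist-evoked current with series-resistance correction
#'
#' The holding current is smoothed with a 1 s moving average (bath responses
#' are slow); the drug response `dI` is the largest deflection from the
#' pre-drug baseline within the application window. The measured amplitude
#' is then corrected for the series-resistance voltage error using the
#' reversal potential of 0 mV and the currents flowing before and during
#' the drug response: both membrane potentials are reconstructed as
#' `Vm = Vcmd - I * Rs`, the leak-current change caused by the potential
#' shift (`(Vm_during - Vm_before)/Rm`) is removed from the measured
#' deflection, and the remainder is rescaled by the driving-force ratio:
#' `I_corr = (dI - dVm/Rm) * (Vcmd - E_rev) / (Vm_during - E_rev)`.
#' This is exact for an ohmic leak. The current density is `I_corr / Cm`
#' (capacitance is proportional to cell surface area).
#'
#' @param sweeps A `sweep_set` from an `agonist_bath` protocol.
#' @param props A `passive_props` (supplies Rs and Cm).
#' @param smooth_s Moving-average width (s).
#' @param e_rev Reversal potential of the agonist-gated current (mV).
#' @param measure_window Optional `c(start_s, end_s)` restricting the peak
#'   search (defaults to the full agonist application).
#' @return An object of class `agonist_response`: `delta_i_pa` (measured),
#'   `i_corr_pa` (Rs-corrected), `density_pa_pf`, `vm_during_mv`,
#'   `baseline_pa`, `unquantifiable` flag.
#' @export
agonist_response <- function(sweeps, props, smooth_s = 1, e_rev = 0,
                             measure_window = NULL) {
  stopifnot(inherits(sweeps, "sweep_set"), inherits(props, "passive_props"))
  p <- sweeps$protocol
  kain <- p$schedule[p$schedule$drug == "kainate", , drop = FALSE]
  if (nrow(kain) != 1) stop("schedule must contain one agonist application")
  fs <- sweeps$fs_khz * 1000             # Hz
  x <- moving_average(sweeps$current[, 1], round(smooth_s * fs))
  t_s <- sweep_times(sweeps)
  if (kain$onset_s <= 5) stop("baseline window must precede drug onset")
  base_idx <- t_s >= 2 & t_s <= kain$onset_s - 2
  baseline <- mean(x[base_idx])
  win <- measure_window %||% c(kain$onset_s, kain$offset_s)
  if (win[2] > max(t_s) + 1e-9) stop("drug window extends past the recording")
  widx <- which(t_s >= win[1] & t_s <= win[2])
  k <- widx[which.max(abs(x[widx] - baseline))]
  delta_i <- x[k] - baseline
  vcmd <- p$hold_mv
  rs <- props$Rs_mohm / 1000                # GOhm
  vm0 <- vcmd - baseline * rs               # membrane potential before drug
  vm <- vcmd - x[k] * rs                    # ... at the response peak
  unq <- abs(vm - e_rev) < 5                # driving force collapsed
  leak_shift <- (vm - vm0) / props$Rm_gohm  # leak-current change, pA
  i_corr <- if (unq) NA_real_ else
    (delta_i - leak_shift) * (vcmd - e_rev) / (vm - e_rev)
  out <- list(delta_i_pa = delta_i, i_corr_pa = i_corr,
              density_pa_pf = i_corr / props$Cm_pf, vm_during_mv = vm,
              baseline_pa = baseline, unquantifiable = unq)
  class(out) <- "agonist_response"
  out
}

#' @export
print.agonist_response <- function(x, ...) {
  cat(sprintf("<agonist_response> dI %.1f pA, corrected %.1f pA, density %.2f pA/pF\n",
              x$delta_i_pa, x$i_corr_pa, x$density_pa_pf))
  invisible(x)
}

#' Measure antagonist block of an agonist response
#'
#' For a recording in which the AMPAR antagonist is co-applied during a
#' prolonged agonist application, measures the pre-antagonist response peak
#' and the residual response over the late antagonist window (when wash-in
#' is complete), both as deflections from the pre-agonist baseline.
#'
#' @param sweeps A `sweep_set` from an `agonist_bath` protocol with a `gyki`
#'   schedule entry.
#' @param props A `passive_props`.
#' @param steady_s Width of the late-antagonist measurement window (s).
#' @return List: `delta_i_pre_pa`, `delta_i_antag_pa`, `block_pct`.
#' @export
agonist_block <- function(sweeps, props, steady_s = 30) {
  p <- sweeps$protocol
  gy <- p$schedule[p$schedule$drug == "gyki", , drop = FALSE]
  if (nrow(gy) != 1) stop("schedule must contain one antagonist application")
  kain <- p$schedule[p$schedule$drug == "kainate", , drop = FALSE]
  pre <- agonist_response(sweeps, props,
                          measure_window = c(kain$onset_s, gy$onset_s))
  fs <- sweeps$fs_khz * 1000
  x <- moving_average(sweeps$current[, 1], round(fs))
  t_s <- sweep_times(sweeps)
  late <- t_s >= gy$offset_s - steady_s & t_s <= gy$offset_s
  d_antag <- mean(x[late]) - pre$baseline_pa
  list(delta_i_pre_pa = pre$delta_i_pa, delta_i_antag_pa = d_antag,
       block_pct = block_fraction(pre$delta_i_pa, d_antag))
}

#' Percent block of a response by an antagonist
#'
#' `100 * (1 - response_during / response_before)`; also applicable to event
#' frequencies.
#'
#' @param pre Response before the antagonist (pA or Hz).
#' @param during Response during the antagonist, same units and sign.
#' @return Percent block.
#' @examples
#' block_fraction(-200, -40)  # 80
#' @export
block_fraction <- function(pre, during) {
  if (any(pre == 0)) stop("pre-antagonist response is zero")
  100 * (1 - during / pre)
}

#' Drug-evoked I–V relation and rectification index
#'
#' Subtracts control step responses from step responses during the agonist:
#' per-voltage drug-evoked current = steady-state current (mean over the
#' last 50 ms of the 200 ms step) during drug minus control. The
#' rectification index is the drug-evoked current at +17 mV divided by the
#' current at −63 mV.
#'
#' @param control_steps,drug_steps `sweep_set`s from identical `step_iv`
#'   protocols, without and with the bath agonist.
#' @param ss_window_ms Steady-state window at the end of each step (ms).
#' @return An object of class `iv_curve`: `voltage_mv`, `current_pa`, `ri`.
#' @export
build_iv_and_ri <- function(control_steps, drug_steps, ss_window_ms = 50) {
  stopifnot(inherits(control_steps, "sweep_set"),
            inherits(drug_steps, "sweep_set"))
  pc <- control_steps$protocol; pd <- drug_steps$protocol
  if (!isTRUE(all.equal(pc$step_mv, pd$step_mv)) ||
      pc$hold_mv != pd$hold_mv || pc$step_ms != pd$step_ms ||
      control_steps$fs_khz != drug_steps$fs_khz)
    stop("control and drug step protocols differ")
  dt <- control_steps$dt_ms
  i_on <- round(pc$baseline_ms / dt) + 1
  i_off <- round((pc$baseline_ms + pc$step_ms) / dt)
  ss_idx <- (i_off - round(ss_window_ms / dt) + 1):i_off
  v <- unique(pc$sweep_step_mv %||% pc$step_mv)
  ss <- function(s) {
    sw <- s$protocol$sweep_step_mv %||% s$protocol$step_mv
    per <- colMeans(s$current[ss_idx, , drop = FALSE])
    vapply(v, function(vv) mean(per[sw == vv]), numeric(1))
  }
  cur <- ss(drug_steps) - ss(control_steps)
  if (!all(c(17, -63) %in% v))
    stop("rectification index needs both the +17 mV and -63 mV steps")
  # ratio of current amplitudes: the response at -63 mV is inward (negative),
  # so an ohmic conductance with E_rev = 0 gives RI = +17/63
  ri <- -cur[v == 17] / cur[v == -63]
  out <- list(voltage_mv = v, current_pa = unname(cur), ri = unname(ri))
  class(out) <- "iv_curve"
  out
}

#' @export
print.iv_curve <- function(x, ...) {
  cat("<iv_curve> RI =", format(x$ri, digits = 4), "\n")
  print(data.frame(voltage_mv = x$voltage_mv,
                   current_pa = round(x$current_pa, 2)))
  invisible(x)
}
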