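#' Isolate the voltage-gated Na+ current by scaled passive subtraction
#'
#' The current response to the 20 mV hyperpolarizing step (−63 → −83 mV),
#' which contains only the capacitive transient and ohmic leak, is linearly
#' scaled by `dV / −20 mV` and subtracted from every step response. Because
#' both template and test sweep pass through the same access resistance, the
#' subtraction is exact (to noise) for any linear cell regardless of Rs.
#' Each trace is referenced to its own pre-step baseline before scaling.
#'
#' The peak Na+ current is the most negative excursion of the subtracted
#' trace within the first 10 ms of the step, searched over depolarizing
#' steps; its density is `peak / Cm`.
#'
#' @param sweeps A `sweep_set` from a `step_iv` protocol (no drug) that
#'   includes the −83 mV step.
#' @param cm_pf Membrane capacitance from [fit_passive()] (pF).
#' @param peak_window_ms Search window after step onset for the transient.
#' @return List: `subtracted` (samples x steps matrix), `step_mv`,
#'   `peak_pa`, `peak_step_mv`, `density_pa_pf`.
#' @export
isolate_na_current <- function(sweeps, cm_pf, peak_window_ms = 10) {
  stopifnot(inherits(sweeps, "sweep_set"))
  if (missing(cm_pf) || is.null(cm_pf) || is.na(cm_pf))
    stop("Cm unavailable: run fit_passive first")
  p <- sweeps$protocol
  sweep_mv <- p$sweep_step_mv %||% p$step_mv
  steps <- unique(sweep_mv)
  hold <- p$hold_mv
  if (!any(abs((sweep_mv - hold) - (-20)) < 1e-9))
    stop("missing the 20 mV hyperpolarizing step (-83 mV) needed as passive template")
  dt <- sweeps$dt_ms
  i_on <- round(p$baseline_ms / dt) + 1
  base_idx <- seq_len(i_on - 1)
  # baseline-referenced traces, averaged per step voltage (hyperpolarizing
  # template repeats collapse into one low-noise trace)
  ref0 <- sweep(sweeps$current, 2,
                colMeans(sweeps$current[base_idx, , drop = FALSE]))
  ref <- vapply(steps, function(v)
    rowMeans(ref0[, sweep_mv == v, drop = FALSE]), numeric(nrow(ref0)))
  template <- ref[, abs((steps - hold) - (-20)) < 1e-9]
  scale <- (steps - hold) / -20
  subtracted <- ref - outer(template, scale)
  win <- i_on:min(nrow(ref), i_on + round(peak_window_ms / dt))
  depol <- steps > hold
  if (!any(depol)) stop("no depolarizing steps present")
  mins <- apply(subtracted[win, depol, drop = FALSE], 2, min)
  k <- which.min(mins)
  list(subtracted = subtracted, step_mv = steps,
       peak_pa = mins[k], peak_step_mv = steps[depol][k],
       density_pa_pf = mins[k] / cm_pf)
}
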