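#' Estimate passive membrane properties from a probe-step transient
#'
#' Averages the repeated +5 mV probe sweeps, then fits the post-step current
#' transient to a single exponential `I(t) = I_ss + (I_0 - I_ss) exp(-t/tau)`.
#' The fit window starts 0.2 ms after step onset (clamp settle); `I_0` is the
#' fit's extrapolation back to step onset, not the raw peak sample. The
#' circuit solution then gives
#' `Rs = dV / (I_0 - I_base)`, `R_total = dV / (I_ss - I_base)`,
#' `Rm = R_total - Rs`, and `Cm = tau * (Rs + Rm) / (Rs * Rm)`.
#'
#' @param sweeps A `sweep_set` from a `passive_probe` protocol (a baseline
#'   segment of at least 50 ms must precede the step).
#' @param settle_ms Dead time skipped after step onset before fitting.
#' @return An object of class `passive_props`: `Rm_gohm`, `Cm_pf`, `Rs_mohm`,
#'   `tau_ms`, `rms_error_pa`, plus `qc_pass`/`qc_reasons` slots filled by
#'   [qc_cell()].
#' @export
fit_passive <- function(sweeps, settle_ms = 0.2) {
  stopifnot(inherits(sweeps, "sweep_set"))
  v <- sweeps$vcmd[, 1]
  dv <- unique(v[v != v[1]])
  if (length(dv) != 1) stop("probe protocol must contain a single step level")
  dV <- dv - v[1]
  i_on <- which(v != v[1])[1]
  i_off <- max(which(v != v[1]))
  dt <- sweeps$dt_ms
  if ((i_on - 1) * dt < 50) stop("baseline segment before the probe step must be >= 50 ms")

  avg <- rowMeans(sweeps$current)
  i_base <- mean(avg[seq_len(i_on - 1)])
  fit_from <- i_on + max(1L, round(settle_ms / dt))
  idx <- fit_from:i_off
  tt <- (idx - i_on) * dt          # ms since step onset
  y <- avg[idx]

  i_ss0 <- mean(y[tt > 0.75 * max(tt)])
  dy <- y - i_ss0
  # sign-robust log-linear seed for tau over the early transient
  early <- tt <= max(tt) / 3 & abs(dy) > 1e-12
  if (sum(early) < 4 || abs(dy[1]) < 3 * stats::sd(y[tt > 0.75 * max(tt)]) / sqrt(length(y)) + 1e-9) {
    # transient indistinguishable from steady state
    if (abs(dy[1]) < 1e-6) stop("cannot resolve Rs: probe transient is absent (I_0 = I_ss)")
  }
  tau0 <- tryCatch({
    cf <- stats::lm(log(abs(dy[early])) ~ tt[early])$coefficients
    max(dt, -1 / cf[2])
  }, error = function(e) 5 * dt)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ iss + (i0 - iss) * exp(-tt / tau),
                      start = list(iss = i_ss0, i0 = y[1] * exp(tt[1] / tau0) -
                                     i_ss0 * (exp(tt[1] / tau0) - 1), tau = tau0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("passive fit failed to converge: ",
                             conditionMessage(e)))
  cf <- coef(fit)
  d0 <- cf[["i0"]] - i_base
  dss <- cf[["iss"]] - i_base
  if (abs(d0 - dss) < 1e-9 || abs(d0) < 1e-12)
    stop("cannot resolve Rs: probe transient is absent (I_0 = I_ss)")
  rs <- dV / d0            # GOhm (mV / pA)
  r_tot <- dV / dss
  rm <- r_tot - rs
  if (rs <= 0 || rm <= 0)
    stop("passive fit produced non-physical (negative) resistances")
  tau <- cf[["tau"]]
  cm <- tau * (rs + rm) / (rs * rm)   # pF
  out <- list(Rm_gohm = rm, Cm_pf = cm, Rs_mohm = rs * 1000, tau_ms = tau,
              rms_error_pa = sqrt(mean(stats::residuals(fit)^2)),
              qc_pass = NA, qc_reasons = character(0))
  class(out) <- "passive_props"
  out
}

#' @export
print.passive_props <- function(x, ...) {
  cat(sprintf("<passive_props> Rm %.2f GOhm, Cm %.1f pF, Rs %.1f MOhm, tau %.3f ms\n",
              x$Rm_gohm, x$Cm_pf, x$Rs_mohm, x$tau_ms))
  if (!is.na(x$qc_pass))
    cat("  QC:", if (x$qc_pass) "pass" else
      paste("FAIL -", paste(x$qc_reasons, collapse = "; ")), "\n")
  invisible(x)
}

#' Cell inclusion/exclusion rules
#'
#' Applies the recording QC used throughout the study to a time course of
#' passive-property measurements from one cell:
#'
#' * not an OP if membrane resistance < 1 GΩ or capacitance > 35 pF;
#' * excluded if series resistance exceeds 30 MΩ at any point;
#' * excluded if series resistance changes by more than 50% relative to its
#'   first measurement.
#'
#' The two series-resistance rules can be bypassed with `ignore_rs = TRUE`
#' for analyses in which all cells are included irrespective of their series
#' resistance (as done for the kainate-evoked current quantification, where
#' voltage errors are corrected arithmetically instead).
#'
#' @param props A `passive_props` object or a list of them (repeated
#'   monitoring during the recording).
#' @param ignore_rs Bypass the series-resistance rules.
#' @return The first `passive_props` with `qc_pass` and `qc_reasons` filled.
#' @export
qc_cell <- function(props, ignore_rs = FALSE) {
  if (inherits(props, "passive_props")) props <- list(props)
  if (length(props) == 0) stop("qc_cell needs at least one measurement")
  stopifnot(all(vapply(props, inherits, logical(1), "passive_props")))
  reasons <- character(0)
  first <- props[[1]]
  if (first$Rm_gohm < 1)
    reasons <- c(reasons, "not OP: Rm < 1 GOhm")
  if (first$Cm_pf > 35)
    reasons <- c(reasons, "not OP: Cm > 35 pF")
  if (!ignore_rs) {
    rs <- vapply(props, `[[`, numeric(1), "Rs_mohm")
    if (any(rs > 30))
      reasons <- c(reasons, "Rs > 30 MOhm")
    if (length(rs) > 1 && any(abs(rs[-1] - rs[1]) / rs[1] > 0.5))
      reasons <- c(reasons, "Rs changed by > 50% during recording")
  }
  first$qc_pass <- length(reasons) == 0
  first$qc_reasons <- reasons
  first
}
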