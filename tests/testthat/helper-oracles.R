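# Independent oracles used across the suite.

# Analytic recorded current for a passive cell + series resistance under a
# command step of dV (relative to the pre-step baseline, t measured from the
# step onset): I(t) = dV/(Rs+Rm) + dV (1/Rs - 1/(Rs+Rm)) exp(-t/tau),
# tau = Cm Rs Rm / (Rs + Rm).  Units mV, GOhm, pF -> pA, ms.
analytic_probe_current <- function(t_ms, dv_mv, rs_gohm, rm_gohm, cm_pf) {
  tau <- cm_pf * rs_gohm * rm_gohm / (rs_gohm + rm_gohm)
  iss <- dv_mv / (rs_gohm + rm_gohm)
  i0 <- dv_mv / rs_gohm
  iss + (i0 - iss) * exp(-t_ms / tau)
}

# Steady-state clamp circuit with an added ohmic drug conductance g_d (nS,
# reversal 0 mV): returns the membrane potential and recorded current.
analytic_bath_steady <- function(vcmd, rs_gohm, rm_gohm, e_leak, g_d) {
  g_acc <- 1 / rs_gohm; g_l <- 1 / rm_gohm
  vm <- (vcmd * g_acc + g_l * e_leak) / (g_acc + g_l + g_d)
  list(vm = vm, i_rec = (vcmd - vm) * g_acc)
}

# Independent ODE integration (deSolve::lsoda) of the full clamp circuit,
# with prescribed drug occupancy wash(t) and optional Na+ channel.
desolve_clamp <- function(cell, vcmd_fun, t_ms, wash_fun = function(t) 0,
                          with_na = TRUE, rectify = FALSE) {
  g_acc <- 1000 / cell$Rs_mohm          # nS
  g_l <- 1 / cell$Rm_gohm
  kin <- cell$na_kinetics
  deriv <- function(t, y, parms) {
    v <- y[1]; m <- y[2]; h <- y[3]
    vc <- vcmd_fun(t)
    w <- wash_fun(t)
    f <- if (rectify) 1 / (1 + exp((v - cell$rect_vh) / cell$rect_k)) else 1
    gna <- if (with_na) cell$gNa_max * m^3 * h else 0
    g_drug <- (cell$gA_max * f + cell$gK_max) * w
    dv <- ((vc - v) * g_acc - g_l * (v - cell$E_leak) -
             gna * (v - cell$E_na) - g_drug * (v - cell$E_glu)) / cell$Cm_pf
    minf <- 1 / (1 + exp(-(v - kin$vhalf_m) / kin$k_m))
    hinf <- 1 / (1 + exp((v - kin$vhalf_h) / kin$k_h))
    list(c(dv, (minf - m) / kin$tau_m, (hinf - h) / kin$tau_h))
  }
  v0 <- (vcmd_fun(0) * g_acc + g_l * cell$E_leak) / (g_acc + g_l)
  m0 <- 1 / (1 + exp(-(v0 - kin$vhalf_m) / kin$k_m))
  h0 <- 1 / (1 + exp((v0 - kin$vhalf_h) / kin$k_h))
  out <- deSolve::lsoda(c(v = v0, m = m0, h = h0), t_ms, deriv, NULL,
                        rtol = 1e-9, atol = 1e-9)
  i_rec <- (vapply(t_ms, vcmd_fun, numeric(1)) - out[, "v"]) * g_acc
  list(t_ms = t_ms, v = out[, "v"], i_rec = i_rec)
}

# Ideal (no access resistance, no capacitance) step sweep set for an ohmic
# conductance g_ns with reversal e_rev added on top of a leak g_leak_ns:
# currents are exact Ohm's-law steady states from the first sample.
ideal_step_sweeps <- function(g_ns, e_rev = 0, g_leak_ns = 0.5,
                              e_leak = -70, fs_khz = 10) {
  p <- clamp_protocol("step_iv", fs_khz = fs_khz)
  dt <- 1 / fs_khz
  n <- round((p$baseline_ms + p$step_ms + p$tail_ms) / dt)
  i_on <- round(p$baseline_ms / dt) + 1
  i_off <- round((p$baseline_ms + p$step_ms) / dt)
  vc <- matrix(p$hold_mv, n, length(p$step_mv))
  for (j in seq_along(p$step_mv)) vc[i_on:i_off, j] <- p$step_mv[j]
  cur <- g_leak_ns * (vc - e_leak) + g_ns * (vc - e_rev)
  sweep_set(cur, vc, fs_khz, p)
}

# Construct a minimal passive_props object by hand (for analyses that only
# need Rs and Cm).
props_stub <- function(rs_mohm, cm_pf, rm_gohm = 1.5) {
  structure(list(Rm_gohm = rm_gohm, Cm_pf = cm_pf, Rs_mohm = rs_mohm,
                 tau_ms = NA_real_, rms_error_pa = 0, qc_pass = TRUE,
                 qc_reasons = character(0)),
            class = "passive_props")
}
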