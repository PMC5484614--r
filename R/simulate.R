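#' @title Sweep sets
#' @description A `sweep_set` holds a multi-sweep (or gap-free) voltage-clamp
#' recording: a samples-by-sweeps current matrix (pA), the matching command
#' waveforms (mV), sampling metadata, the protocol, per-cell metadata and —
#' for synthetic data — the planted ground truth.
#' @param current,vcmd Numeric matrices (samples x sweeps), pA and mV.
#' @param fs_khz Sampling rate (kHz).
#' @param protocol A [clamp_protocol()].
#' @param meta Named list of cell metadata (genotype, Rs, ...).
#' @param ground_truth Optional list of planted values.
#' @return An object of class `sweep_set`.
#' @export
sweep_set <- function(current, vcmd, fs_khz, protocol, meta = list(),
                      ground_truth = NULL) {
  current <- as.matrix(current); vcmd <- as.matrix(vcmd)
  stopifnot(all(dim(current) == dim(vcmd)), fs_khz > 0)
  structure(list(current = current, vcmd = vcmd, fs_khz = fs_khz,
                 dt_ms = 1 / fs_khz, protocol = protocol, meta = meta,
                 ground_truth = ground_truth),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("<sweep_set> %d sweep(s) x %d samples @ %g kHz (%s)\n",
              ncol(x$current), nrow(x$current), x$fs_khz,
              x$protocol$kind %||% "?"))
  invisible(x)
}

#' Time axis of a sweep set (seconds)
#' @param x A `sweep_set`.
#' @export
sweep_times <- function(x) (seq_len(nrow(x$current)) - 1) * x$dt_ms / 1000

#' Normalized biexponential synaptic waveform
#'
#' `(exp(-t/tau_decay) - exp(-t/tau_rise))`, scaled to unit peak; 0 for t < 0.
#' @param t_ms Time from event onset (ms).
#' @param tau_rise,tau_decay Rise and decay time constants (ms).
#' @export
biexp_waveform <- function(t_ms, tau_rise = 0.5, tau_decay = 4) {
  stopifnot(tau_decay > tau_rise, tau_rise > 0)
  tp <- tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
  norm <- exp(-tp / tau_decay) - exp(-tp / tau_rise)
  out <- numeric(length(t_ms))
  pos <- t_ms >= 0
  out[pos] <- (exp(-t_ms[pos] / tau_decay) - exp(-t_ms[pos] / tau_rise)) / norm
  out
}

# Bath-drug occupancy time course: first-order wash-in (tau_on) from onset,
# first-order wash-out (tau_off) from offset.
drug_wash <- function(t_s, onset_s, offset_s, tau_on = 20, tau_off = 60) {
  w <- numeric(length(t_s))
  during <- t_s >= onset_s & t_s < offset_s
  w[during] <- 1 - exp(-(t_s[during] - onset_s) / tau_on)
  after <- t_s >= offset_s
  w_off <- 1 - exp(-(offset_s - onset_s) / tau_on)
  w[after] <- w_off * exp(-(t_s[after] - offset_s) / tau_off)
  w
}

# Superimpose unit-peak biexponential conductance events onto a zero vector.
add_conductance_events <- function(n, dt_ms, onset_s, g_peak_ns,
                                   tau_rise, tau_decay) {
  g <- numeric(n)
  if (length(onset_s) == 0) return(g)
  span <- ceiling(10 * max(tau_decay) / dt_ms)
  for (i in seq_along(onset_s)) {
    i0 <- floor(onset_s[i] * 1000 / dt_ms) + 1
    if (i0 > n) next
    idx <- i0:min(n, i0 + span)
    tt <- (idx - i0) * dt_ms
    g[idx] <- g[idx] + g_peak_ns[i] *
      biexp_waveform(tt, tau_rise[min(i, length(tau_rise))],
                     tau_decay[min(i, length(tau_decay))])
  }
  g
}

# Inhomogeneous Poisson event times by thinning. rate_fun maps seconds -> Hz.
poisson_times <- function(rate_fun, rate_max, duration_s) {
  if (rate_max <= 0) return(numeric(0))
  n_cand <- rpois(1, rate_max * duration_s)
  if (n_cand == 0) return(numeric(0))
  tt <- sort(runif(n_cand, 0, duration_s))
  tt[runif(n_cand) < rate_fun(tt) / rate_max]
}

# Choose the internal integration sub-step per protocol physics.
pick_n_sub <- function(cell, dt_ms, na_excited = FALSE, fast_syn = FALSE) {
  target <- 1e6
  if (na_excited && cell$gNa_max > 0) target <- cell$na_kinetics$tau_m / 5
  if (fast_syn) target <- min(target, 0.05)
  max(1L, as.integer(ceiling(dt_ms / target)))
}

run_clamp <- function(cell, vcmd, dt_ms, wash_ampa = numeric(0),
                      wash_kar = numeric(0), gsyn = numeric(0),
                      spermine = FALSE, n_sub = 1L) {
  clamp_integrate_cpp(
    vcmd, dt_ms, n_sub,
    cell$Cm_pf, cell$Rs_mohm / 1000, cell$Rm_gohm, cell$E_leak,
    cell$gNa_max, cell$E_na,
    cell$na_kinetics$vhalf_m, cell$na_kinetics$k_m, cell$na_kinetics$tau_m,
    cell$na_kinetics$vhalf_h, cell$na_kinetics$k_h, cell$na_kinetics$tau_h,
    cell$gA_max, cell$gK_max, cell$E_glu,
    wash_ampa, wash_kar, gsyn,
    isTRUE(spermine) && isTRUE(cell$ampar_rectifying),
    cell$rect_vh, cell$rect_k)
}

#' Simulate a voltage-clamp recording from a synthetic OP cell
#'
#' Forward model: a single-compartment cell behind an access resistance, with
#' leak, Hodgkin–Huxley-style Na+ current, AMPAR and kainate-receptor
#' conductances (reversal 0 mV) driven by bath agonist wash-in/out
#' (first-order, tau 20 s on / 60 s off), Poisson synaptic events with
#' biexponential conductance waveforms (tau 0.5 / 4 ms), optional polyamine
#' rectification of the AMPAR limb, and additive Gaussian recording noise.
#'
#' The command waveform is built from `protocol`; the recorded current is the
#' pipette current `(Vcmd - Vm)/Rs`, so capacitive transients and
#' series-resistance voltage errors are present in the output exactly as they
#' would be in a recording.
#'
#' @param cell A [make_cell()] object.
#' @param protocol A [clamp_protocol()].
#' @param seed Integer seed for event times, amplitudes and recording noise.
#' @return A [sweep_set()] carrying `ground_truth` (planted cell parameters
#'   and, for synaptic scenarios, the true event list).
#' @export
simulate_voltage_clamp <- function(cell, protocol, seed) {
  stopifnot(inherits(cell, "cell_params"), inherits(protocol, "clamp_protocol"))
  with_seed(seed, switch(protocol$kind,
    passive_probe = sim_probe(cell, protocol),
    step_iv = sim_steps(cell, protocol),
    agonist_bath = sim_bath(cell, protocol),
    rr_epsc = sim_rr(cell, protocol),
    minimal_stim = sim_minstim(cell, protocol),
    paired_pulse = sim_ppr(cell, protocol),
    stop("unknown protocol kind")))
}

sim_probe <- function(cell, p) {
  dt <- 1 / p$fs_khz
  n <- round((p$baseline_ms + p$step_ms + p$tail_ms) / dt)
  v <- rep(p$hold_mv, n)
  i_on <- round(p$baseline_ms / dt) + 1
  i_off <- round((p$baseline_ms + p$step_ms) / dt)
  v[i_on:i_off] <- p$hold_mv + p$probe_mv
  base <- run_clamp(cell, v, dt, n_sub = pick_n_sub(cell, dt))
  cur <- vapply(seq_len(p$n_repeats),
                function(k) base + rnorm(n, 0, cell$noise_sd), numeric(n))
  sweep_set(cur, matrix(v, n, p$n_repeats), p$fs_khz, p,
            meta = list(genotype = cell$genotype),
            ground_truth = cell$ground_truth)
}

sim_steps <- function(cell, p) {
  dt <- 1 / p$fs_khz
  n <- round((p$baseline_ms + p$step_ms + p$tail_ms) / dt)
  i_on <- round(p$baseline_ms / dt) + 1
  i_off <- round((p$baseline_ms + p$step_ms) / dt)
  on_drug <- identical(p$drug, "kainate")
  w <- if (on_drug) rep(1, n) else numeric(0)
  # the -20 mV hyperpolarizing step (passive-subtraction template) is
  # acquired repeatedly so averaging suppresses its noise before scaling
  reps <- ifelse(abs((p$step_mv - p$hold_mv) - (-20)) < 1e-9,
                 max(1L, p$template_repeats %||% 1L), 1L)
  steps <- rep(p$step_mv, reps)
  vc <- matrix(p$hold_mv, n, length(steps))
  cur <- matrix(0, n, length(steps))
  for (j in seq_along(steps)) {
    vc[i_on:i_off, j] <- steps[j]
    cur[, j] <- run_clamp(cell, vc[, j], dt, wash_ampa = w, wash_kar = w,
                          spermine = p$spermine,
                          n_sub = pick_n_sub(cell, dt, na_excited = TRUE)) +
      rnorm(n, 0, cell$noise_sd)
  }
  p$sweep_step_mv <- steps
  sweep_set(cur, vc, p$fs_khz, p,
            meta = list(genotype = cell$genotype, drug = p$drug,
                        spermine = p$spermine),
            ground_truth = cell$ground_truth)
}

sim_bath <- function(cell, p) {
  dt <- 1 / p$fs_khz
  n <- round(p$total_s * 1000 / dt)
  t_s <- (seq_len(n) - 1) * dt / 1000
  v <- rep(p$hold_mv, n)
  kain <- p$schedule[p$schedule$drug == "kainate", , drop = FALSE]
  if (nrow(kain) != 1) stop("agonist_bath protocol needs one kainate entry")
  w_k <- drug_wash(t_s, kain$onset_s, kain$offset_s)
  gy <- p$schedule[p$schedule$drug == "gyki", , drop = FALSE]
  block <- if (nrow(gy) == 1) drug_wash(t_s, gy$onset_s, gy$offset_s) else 0
  cur <- run_clamp(cell, v, dt, wash_ampa = w_k * (1 - block), wash_kar = w_k,
                   spermine = p$spermine, n_sub = pick_n_sub(cell, dt)) +
    rnorm(n, 0, cell$noise_sd)
  sweep_set(cur, v, p$fs_khz, p,
            meta = list(genotype = cell$genotype, schedule = p$schedule),
            ground_truth = cell$ground_truth)
}

sim_rr <- function(cell, p) {
  dt <- 1 / p$fs_khz
  n <- round(p$total_s * 1000 / dt)
  base <- cell$rr_baseline_hz
  plateau <- cell$rr_rate_hz
  tau_rise_s <- 60  # frequency climbs to plateau within ~3 min of RR onset
  rate_fun <- function(tt) {
    r <- rep(base, length(tt))
    on <- tt >= p$rr_onset_s
    r[on] <- base + (plateau - base) * (1 - exp(-(tt[on] - p$rr_onset_s) / tau_rise_s))
    r
  }
  times <- poisson_times(rate_fun, max(base, plateau), p$total_s)
  amp <- pmax(2, rnorm(length(times), cell$epsc_amplitude_mean,
                       cell$epsc_amplitude_sd))
  tau_d <- 4 * exp(rnorm(length(times), 0, 0.1))
  g_peak <- amp / abs(p$hold_mv - cell$E_glu)
  gsyn <- add_conductance_events(n, dt, times, g_peak, rep(0.5, length(times)),
                                 tau_d)
  v <- rep(p$hold_mv, n)
  cur <- run_clamp(cell, v, dt, gsyn = gsyn,
                   n_sub = pick_n_sub(cell, dt, fast_syn = TRUE)) +
    rnorm(n, 0, cell$noise_sd)
  truth <- c(cell$ground_truth, list(
    events = data.frame(time_s = times, amplitude_pa = amp,
                        g_peak_ns = g_peak, tau_rise_ms = 0.5,
                        tau_decay_ms = tau_d),
    rr_onset_s = p$rr_onset_s, plateau_rate_hz = plateau))
  sweep_set(cur, v, p$fs_khz, p,
            meta = list(genotype = cell$genotype, rr_onset_s = p$rr_onset_s),
            ground_truth = truth)
}

sim_minstim <- function(cell, p) {
  dt <- 1 / p$fs_khz
  n <- round(p$sweep_ms / dt)
  v <- rep(p$hold_mv, n)
  success <- runif(p$n_trials) < p$p_success
  amp <- pmax(1, rnorm(p$n_trials, p$amp_mean_pa, p$amp_sd_pa))
  cur <- matrix(0, n, p$n_trials)
  for (k in seq_len(p$n_trials)) {
    gs <- numeric(0)
    if (success[k]) {
      lat <- p$stim_ms / 1000 + (1 + rnorm(1, 0, 0.2)) / 1000
      gs <- add_conductance_events(n, dt, lat,
                                   amp[k] / abs(p$hold_mv - cell$E_glu),
                                   0.5, 4)
    }
    cur[, k] <- run_clamp(cell, v, dt, gsyn = gs,
                          n_sub = pick_n_sub(cell, dt, fast_syn = TRUE)) +
      rnorm(n, 0, cell$noise_sd)
  }
  truth <- c(cell$ground_truth,
             list(success = success, amplitude_pa = ifelse(success, amp, NA),
                  p_success = p$p_success))
  sweep_set(cur, matrix(v, n, p$n_trials), p$fs_khz, p,
            meta = list(genotype = cell$genotype, stim_ms = p$stim_ms),
            ground_truth = truth)
}

sim_ppr <- function(cell, p) {
  dt <- 1 / p$fs_khz
  n <- round(p$sweep_ms / dt)
  v <- rep(p$hold_mv, n)
  amp1 <- p$amp1_pa
  amp2 <- p$ppr_true * amp1
  drive <- abs(p$hold_mv - cell$E_glu)
  gs <- add_conductance_events(n, dt, p$stim_ms / 1000 + 0.001,
                               c(amp1, amp2) / drive, c(0.5, 0.5), c(4, 4))
  cur <- vapply(seq_len(p$n_repeats), function(k)
    run_clamp(cell, v, dt, gsyn = gs,
              n_sub = pick_n_sub(cell, dt, fast_syn = TRUE)) +
      rnorm(n, 0, cell$noise_sd), numeric(n))
  truth <- c(cell$ground_truth, list(ppr_true = p$ppr_true, amp1_pa = amp1))
  sweep_set(cur, matrix(v, n, p$n_repeats), p$fs_khz, p,
            meta = list(genotype = cell$genotype, stim_ms = p$stim_ms),
            ground_truth = truth)
}

#' Simulate an idealized EPSC trace (no clamp filtering)
#'
#' Builds a gap-free current trace as a direct sum of biexponential EPSC
#' waveforms plus white noise, without the access-resistance low-pass of the
#' circuit model. This is the benchmark input for detector performance
#' studies, where the planted amplitudes must appear in the trace unchanged.
#'
#' @param duration_s Trace duration (s).
#' @param fs_khz Sampling rate (kHz).
#' @param rate_hz Poisson event rate (Hz), constant over the trace; or a
#'   function of time (s) returning Hz.
#' @param amp_mean_pa,amp_sd_pa Normal amplitude parameters (pA), truncated
#'   at 2 pA.
#' @param noise_sd Gaussian noise SD (pA).
#' @param seed Integer seed.
#' @param tau_rise_ms,tau_decay_ms Event kinetics (ms).
#' @param events Optional data.frame(time_s, amplitude_pa) of planted events,
#'   bypassing the Poisson draw.
#' @return A [sweep_set()] with the ground-truth event list.
#' @export
simulate_epsc_trace <- function(duration_s, fs_khz = 5, rate_hz = 2,
                                amp_mean_pa = 20, amp_sd_pa = 4, noise_sd = 3,
                                seed = 1, tau_rise_ms = 0.5, tau_decay_ms = 4,
                                events = NULL) {
  dt <- 1 / fs_khz
  n <- round(duration_s * 1000 / dt)
  with_seed(seed, {
    if (is.null(events)) {
      if (is.function(rate_hz)) {
        rmax <- max(rate_hz(seq(0, duration_s, length.out = 512)))
        times <- poisson_times(rate_hz, rmax, duration_s)
      } else {
        times <- poisson_times(function(tt) rep(rate_hz, length(tt)),
                               rate_hz, duration_s)
      }
      amp <- pmax(2, rnorm(length(times), amp_mean_pa, amp_sd_pa))
    } else {
      times <- events$time_s
      amp <- events$amplitude_pa
    }
    # inward (negative) synaptic currents on a flat baseline
    cur <- -add_conductance_events(n, dt, times, amp,
                                   rep(tau_rise_ms, length(times)),
                                   rep(tau_decay_ms, length(times)))
    if (noise_sd > 0) cur <- cur + rnorm(n, 0, noise_sd)
    truth <- list(events = data.frame(time_s = times, amplitude_pa = amp),
                  noise_sd = noise_sd)
    proto <- clamp_protocol("rr_epsc", fs_khz = fs_khz, total_s = duration_s,
                            rr_onset_s = 0)
    sweep_set(cur, rep(-83, n), fs_khz, proto,
              meta = list(idealized = TRUE), ground_truth = truth)
  })
}
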