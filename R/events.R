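#' Detect EPSCs by threshold search
#'
#' Implements the detection criteria used in the study: the gap-free trace
#' is high-pass filtered at 2 Hz (zero-phase, 2nd order) to remove baseline
#' drift; the noise SD is estimated iteratively from event-free stretches
#' (detect, mask detections ± 20 ms, re-estimate, repeat to convergence);
#' the amplitude threshold is 3 × noise SD; candidate events must stay above
#' threshold for at least 1 ms and have a 20–80% rise time shorter than
#' their decay time constant. All candidates are returned with an
#' `accepted` flag (rejected candidates are retained for audit).
#'
#' @param sweeps A gap-free `sweep_set` (single sweep), or a numeric vector
#'   with `fs_khz` supplied.
#' @param threshold_sd Amplitude threshold in noise SDs.
#' @param min_duration_ms Minimum time above threshold.
#' @param hp_hz High-pass corner frequency.
#' @param polarity −1 for inward (negative) events.
#' @param mask_ms Half-width of the mask around detections during noise
#'   estimation.
#' @param fs_khz Sampling rate, required when `sweeps` is a bare vector.
#' @param max_iter Maximum noise-estimation iterations (error if the
#'   estimate has not converged by then).
#' @return An `event_list`: data.frame with `time_s` (onset), `peak_time_s`,
#'   `amplitude_pa`, `duration_ms`, `rise_ms` (20–80%), `decay_ms`,
#'   `accepted`; attributes `noise_sd`, `threshold_pa`, `duration_s`.
#' @export
detect_epscs <- function(sweeps, threshold_sd = 3, min_duration_ms = 1,
                         hp_hz = 2, polarity = -1, mask_ms = 20,
                         fs_khz = NULL, max_iter = 10) {
  if (inherits(sweeps, "sweep_set")) {
    if (ncol(sweeps$current) != 1)
      stop("detect_epscs needs a gap-free (single-sweep) recording")
    x <- sweeps$current[, 1]
    fs_khz <- sweeps$fs_khz
  } else {
    x <- as.numeric(sweeps)
    if (is.null(fs_khz)) stop("fs_khz required for a bare trace")
  }
  fs <- fs_khz * 1000
  dur_s <- length(x) / fs
  if (dur_s < 10) stop("trace shorter than 10 s")

  w <- polarity * highpass2(x, hp_hz, fs)

  # iterative noise estimate from event-free stretches
  sd_est <- max(stats::mad(w), 1e-3)
  mask_n <- round(mask_ms / 1000 * fs)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    thr <- threshold_sd * sd_est
    above <- w > thr
    keep <- !grow_mask(above, mask_n)
    new_sd <- if (any(keep)) max(sd(w[keep]), 1e-3) else sd_est
    if (abs(new_sd - sd_est) / sd_est < 0.01) { sd_est <- new_sd; converged <- TRUE; break }
    sd_est <- new_sd
  }
  if (!converged) stop("noise SD estimation failed to converge in ", max_iter,
                       " iterations")
  thr <- threshold_sd * sd_est

  runs <- runs_above(w > thr, merge_gap = round(0.001 * fs))
  if (nrow(runs) == 0) {
    ev <- data.frame(time_s = numeric(0), peak_time_s = numeric(0),
                     amplitude_pa = numeric(0), duration_ms = numeric(0),
                     rise_ms = numeric(0), decay_ms = numeric(0),
                     accepted = logical(0))
    return(event_list(ev, sd_est, thr, dur_s))
  }
  pre_n <- round(0.010 * fs)
  # kinetics are read off a lightly smoothed copy (0.6 ms box) so that
  # single-sample noise dips do not truncate the decay or jitter the rise
  ws <- moving_average(w, max(3L, round(0.0006 * fs)))
  nr <- nrow(runs)
  pk <- amp <- rise <- dec <- numeric(nr)
  for (k in seq_len(nr)) {
    a <- runs$start[k]; b <- runs$end[k]
    pk[k] <- a + which.max(w[a:b]) - 1L
    base <- median(ws[max(1, a - pre_n):max(1, a - 1)])
    amp[k] <- w[pk[k]] - base
    rise[k] <- rise_time(ws, a, pk[k], base, ws[pk[k]] - base, fs)
    dec[k] <- decay_time(ws, pk[k], base, ws[pk[k]] - base, fs)
  }
  ev <- data.frame(time_s = (runs$start - 1) / fs,
                   peak_time_s = (pk - 1) / fs,
                   amplitude_pa = amp,
                   duration_ms = (runs$end - runs$start + 1) / fs * 1000,
                   rise_ms = rise, decay_ms = dec)
  ev$accepted <- ev$amplitude_pa >= thr &
    ev$duration_ms >= min_duration_ms &
    ev$rise_ms < ev$decay_ms
  ev <- ev[order(ev$time_s), ]
  rownames(ev) <- NULL
  event_list(ev, sd_est, thr, dur_s)
}

event_list <- function(df, noise_sd, threshold, duration_s) {
  attr(df, "noise_sd") <- noise_sd
  attr(df, "threshold_pa") <- threshold
  attr(df, "duration_s") <- duration_s
  class(df) <- c("event_list", "data.frame")
  df
}

# zero-phase 2nd-order Butterworth high-pass
highpass2 <- function(x, hp_hz, fs) {
  bf <- signal::butter(2, hp_hz / (fs / 2), type = "high")
  signal::filtfilt(bf, x)
}

# dilate a logical mask by +/- half_n samples
grow_mask <- function(mask, half_n) {
  if (!any(mask) || half_n == 0) return(mask)
  idx <- which(mask)
  out <- logical(length(mask))
  lo <- pmax(1L, idx - half_n); hi <- pmin(length(mask), idx + half_n)
  # mark ranges via difference trick
  d <- integer(length(mask) + 1L)
  for (k in seq_along(lo)) { d[lo[k]] <- d[lo[k]] + 1L; d[hi[k] + 1L] <- d[hi[k] + 1L] - 1L }
  cumsum(d[-length(d)]) > 0L
}

# contiguous TRUE runs, merging runs separated by <= merge_gap samples
runs_above <- function(above, merge_gap = 0L) {
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  s <- starts[r$values]; e <- ends[r$values]
  if (length(s) == 0) return(data.frame(start = integer(0), end = integer(0)))
  if (merge_gap > 0L && length(s) > 1L) {
    keep_s <- s[1]; out_s <- integer(0); out_e <- integer(0)
    cur_e <- e[1]
    for (k in seq_along(s)[-1]) {
      if (s[k] - cur_e - 1L <= merge_gap) cur_e <- e[k]
      else { out_s <- c(out_s, keep_s); out_e <- c(out_e, cur_e)
             keep_s <- s[k]; cur_e <- e[k] }
    }
    s <- c(out_s, keep_s); e <- c(out_e, cur_e)
  }
  data.frame(start = s, end = e)
}

# 20-80% rise time by linear interpolation walking back from the peak
rise_time <- function(w, a, pk, base, amp, fs) {
  lo <- base + 0.2 * amp; hi <- base + 0.8 * amp
  seg_start <- max(1L, a - round(0.005 * fs))
  seg <- w[seg_start:pk]
  t20 <- last_crossing(seg, lo); t80 <- last_crossing(seg, hi)
  if (is.na(t20) || is.na(t80)) return(NA_real_)
  (t80 - t20) / fs * 1000
}

last_crossing <- function(seg, level) {
  below <- which(seg[-length(seg)] < level & seg[-1] >= level)
  if (length(below) == 0) return(if (seg[1] >= level) 1 else NA_real_)
  k <- max(below)
  k + (level - seg[k]) / (seg[k + 1] - seg[k])
}

# time to decay to 1/e of the peak amplitude above local baseline
decay_time <- function(w, pk, base, amp, fs, max_ms = 50) {
  target <- base + amp * exp(-1)
  stop_i <- min(length(w), pk + round(max_ms / 1000 * fs))
  seg <- w[pk:stop_i]
  k <- which(seg <= target)[1]
  if (is.na(k)) return(Inf)
  (k - 1) / fs * 1000
}

#' @export
print.event_list <- function(x, ...) {
  cat(sprintf("<event_list> %d candidates, %d accepted; noise SD %.2f pA, threshold %.2f pA\n",
              nrow(x), sum(x$accepted), attr(x, "noise_sd"),
              attr(x, "threshold_pa")))
  if (nrow(x) > 0) print.data.frame(head(as.data.frame(x), 10))
  invisible(x)
}

#' Match detected events against a ground-truth list
#'
#' Greedy one-to-one matching of detected onsets to true event times within
#' a tolerance; reports recall (of the selected truth subset) and the
#' false-positive rate.
#'
#' @param events An `event_list` (accepted events are used).
#' @param truth_times_s True event onset times (s).
#' @param tol_ms Matching tolerance.
#' @param duration_s Recording duration for the false-positive rate; taken
#'   from the `event_list` attribute when absent.
#' @return List: `recall`, `fp_rate_hz`, `n_matched`.
#' @export
match_events <- function(events, truth_times_s, tol_ms = 5,
                         duration_s = NULL) {
  duration_s <- duration_s %||% attr(events, "duration_s")
  det <- events$time_s[events$accepted]
  used <- logical(length(det))
  matched <- 0L
  for (tt in truth_times_s) {
    d <- abs(det - tt)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol_ms / 1000) {
      used[j] <- TRUE; matched <- matched + 1L
    }
  }
  list(recall = if (length(truth_times_s)) matched / length(truth_times_s) else NA_real_,
       fp_rate_hz = sum(!used) / duration_s,
       n_matched = matched)
}

#' Per-minute EPSC frequency and the 3–6 min analysis window
#'
#' Computes the event frequency for each minute of drug application and the
#' summary frequency over minutes 3–6 after drug onset (the window in which
#' the secretagogue effect has plateaued).
#'
#' @param events An `event_list` (accepted events only) or numeric event
#'   times (s).
#' @param onset_s Drug onset time (s).
#' @param end_s Recording end time (s); from the `event_list` attribute when
#'   absent.
#' @param bin_s Bin width (s).
#' @param window_min Analysis window, minutes after onset.
#' @return List: `minute` (bin start, min after onset), `freq_hz` per bin,
#'   `window_freq_hz`.
#' @export
frequency_timecourse <- function(events, onset_s, end_s = NULL, bin_s = 60,
                                 window_min = c(3, 6)) {
  if (inherits(events, "event_list")) {
    end_s <- end_s %||% attr(events, "duration_s")
    times <- events$time_s[events$accepted]
  } else times <- as.numeric(events)
  if (is.null(end_s)) stop("end_s required")
  win <- onset_s + window_min * 60
  if (win[2] > end_s + 1e-9)
    stop("analysis window extends past the end of the recording")
  breaks <- seq(onset_s, end_s, by = bin_s)
  post <- times[times >= onset_s]
  counts <- if (length(breaks) > 1)
    table(cut(post, breaks, right = FALSE)) else integer(0)
  list(minute = (head(breaks, -1) - onset_s) / 60,
       freq_hz = as.numeric(counts) / bin_s,
       window_freq_hz = sum(times >= win[1] & times < win[2]) / diff(win))
}

#' Unitary EPSC amplitude from minimal-stimulation trials
#'
#' Classifies each stimulus-locked trial as success or failure by threshold
#' crossing in a post-stimulus window, and averages the peak amplitudes of
#' the successes only.
#'
#' Trials are lightly smoothed (0.6 ms box) before classification; because
#' no minimum-duration criterion is available inside the short window, the
#' success threshold defaults to 4 SDs of the smoothed pre-stimulus noise.
#'
#' @param sweeps A `sweep_set` from a `minimal_stim` protocol.
#' @param window_ms Post-stimulus search window.
#' @param threshold_sd Success threshold in (smoothed) pre-stimulus noise
#'   SDs.
#' @return List: `unitary_pa` (NA with a message if no successes),
#'   `p_success`, `n_trials`, `success` (logical per trial),
#'   `peak_pa` per trial.
#' @export
unitary_epsc <- function(sweeps, window_ms = 10, threshold_sd = 4) {
  stopifnot(inherits(sweeps, "sweep_set"))
  p <- sweeps$protocol
  n_tr <- ncol(sweeps$current)
  if (n_tr < 50 || n_tr > 80)
    warning("trial count (", n_tr, ") outside the 50-80 range of the minimal-stimulation protocol")
  dt <- sweeps$dt_ms
  fs <- sweeps$fs_khz * 1000
  s_i <- round(p$stim_ms / dt) + 1
  sm <- apply(sweeps$current, 2, moving_average,
              width = max(3L, round(0.0006 * fs)))
  pre <- sm[seq_len(s_i - 1), , drop = FALSE]
  pre_c <- sweep(pre, 2, colMeans(pre))
  noise_sd <- sd(as.numeric(pre_c))
  win <- s_i:min(nrow(sm), s_i + round(window_ms / dt))
  base <- colMeans(pre)
  peaks <- vapply(seq_len(n_tr), function(k)
    -(min(sm[win, k]) - base[k]), numeric(1))
  success <- peaks > threshold_sd * noise_sd
  unitary <- if (any(success)) mean(peaks[success]) else {
    message("no successful trials: unitary amplitude undefined")
    NA_real_
  }
  list(unitary_pa = unitary, p_success = mean(success), n_trials = n_tr,
       success = success, peak_pa = peaks, noise_sd = noise_sd)
}

#' Paired-pulse ratio from averaged stimulus pairs
#'
#' Averages the repeats, measures the first peak, fits a single exponential
#' to the decay of the first response between its peak and the second
#' stimulus, subtracts its extrapolation, and measures the second peak on
#' the corrected trace. `PPR = peak2 / peak1`.
#'
#' @param sweeps A `sweep_set` from a `paired_pulse` protocol (two stimuli
#'   25 ms apart, >= 10 repeats averaged).
#' @param peak_window_ms Peak search window after each stimulus.
#' @return List: `ppr`, `peak1_pa`, `peak2_pa`, `decay_tau_ms`.
#' @export
paired_pulse_ratio <- function(sweeps, peak_window_ms = 20) {
  stopifnot(inherits(sweeps, "sweep_set"))
  p <- sweeps$protocol
  if (length(p$stim_ms) != 2 || abs(diff(p$stim_ms) - 25) > 1e-6)
    stop("paired-pulse protocol must contain two stimuli 25 ms apart")
  dt <- sweeps$dt_ms
  avg <- rowMeans(sweeps$current)
  s1 <- round(p$stim_ms[1] / dt) + 1
  s2 <- round(p$stim_ms[2] / dt) + 1
  base <- mean(avg[seq_len(s1 - 1)])
  w <- -(avg - base)                      # inward responses positive
  win1 <- s1:(s2 - 1)
  p1_rel <- which.max(w[win1]); p1 <- win1[p1_rel]
  peak1 <- w[p1]
  if (peak1 <= 0) stop("first-pulse peak is zero")
  # exponential decay of response 1, extrapolated under response 2
  fit_idx <- p1:(s2 - 1)
  fit_idx <- fit_idx[w[fit_idx] > 0.02 * peak1]
  tau <- NA_real_
  ext <- numeric(length(w))
  if (length(fit_idx) > 5 && w[s2 - 1] > 0.02 * peak1) {
    tt <- (fit_idx - p1) * dt
    cf <- stats::lm(log(w[fit_idx]) ~ tt)$coefficients
    tau <- -1 / cf[2]
    if (is.finite(tau) && tau > 0) {
      t_all <- (seq_along(w) - p1) * dt
      ext[t_all >= 0] <- exp(cf[1]) * exp(-t_all[t_all >= 0] / tau)
    } else tau <- NA_real_
  }
  win2 <- s2:min(length(w), s2 + round(peak_window_ms / dt))
  corr <- w - ext
  peak2 <- max(corr[win2])
  list(ppr = peak2 / peak1, peak1_pa = peak1, peak2_pa = peak2,
       decay_tau_ms = unname(tau))
}
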