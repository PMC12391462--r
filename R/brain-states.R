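#' @title Offline frames, theta phase and cycles, ripples, theta state
#' @name brain_states
NULL

#' Analytic signal via FFT
#'
#' Standard frequency-domain construction: double positive frequencies, zero
#' negative frequencies, inverse transform.
#'
#' @param x real signal.
#' @return complex analytic signal, same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

bandpass <- function(x, rate, band, order = 4) {
  ny <- rate / 2
  bf <- signal::butter(order, band / ny, type = "pass")
  signal::filtfilt(bf, x)            # zero-phase forward-backward
}

#' Instantaneous theta phase and cycle boundaries
#'
#' Band-pass 7-10 Hz (zero-phase Butterworth) then analytic-signal phase.
#' Phase 0 is the filtered-LFP peak, increasing through the trough at pi.
#' Cycles are the intervals between consecutive phase peaks (wrap points).
#'
#' @param lfp an `lfp_channel`.
#' @param band theta band (Hz).
#' @param order Butterworth order.
#' @return list with `t`, `phase` in \[0, 2pi), `filtered`, and `cycles`
#'   data.frame (start, stop, duration, in_band flag for 7-10 Hz durations).
#' @export
theta_phase <- function(lfp, band = c(7, 10), order = 4) {
  if (stats::sd(lfp$samples) == 0) stop("flat LFP: phase undefined")
  filt <- bandpass(lfp$samples, lfp$rate, band, order)
  ph <- Arg(analytic_signal(filt)) %% (2 * pi)
  t <- lfp_times(lfp)
  wrap <- which(diff(ph) < -pi)      # phase falls from ~2pi to ~0 at each peak
  cyc <- NULL
  if (length(wrap) >= 2) {
    st <- t[wrap[-length(wrap)] + 1L]
    en <- t[wrap[-1] + 1L]
    dur <- en - st
    cyc <- data.frame(start = st, stop = en, duration = dur,
                      in_band = dur >= 0.9 / band[2] & dur <= 1.1 / band[1])
  }
  list(t = t, phase = ph, filtered = filt, cycles = cyc)
}

#' Phase at arbitrary times
#' @param tp result of [theta_phase()].
#' @param times query times (s).
#' @return phase in \[0, 2pi) at each time (nearest-sample lookup).
#' @export
phase_at <- function(tp, times) {
  idx <- pmin(pmax(round((times - tp$t[1]) * 1 /
                           (tp$t[2] - tp$t[1])) + 1L, 1L), length(tp$t))
  tp$phase[idx]
}

#' Detect multi-unit burst frames
#'
#' Pyramidal MUA binned at 1 ms and Gaussian-smoothed (sd 15 ms); candidates
#' where MUA exceeds mean + 2 sd are extended outward to the mean crossing,
#' then filtered to 100-1200 ms duration, >= 5 distinct units, and animal
#' velocity below 2 cm/s throughout. MUA mean/sd are computed over the
#' immobility periods only.
#'
#' @param spikes a `spike_ensemble` (pyramidal units only are used).
#' @param t_range c(start, stop) of the session (s).
#' @param velocity_t,velocity optional velocity series; `NULL` means immobile
#'   throughout (sleep box).
#' @param bin MUA bin (s).
#' @param sigma smoothing sd (s).
#' @param z_enter threshold in sd above mean.
#' @param min_units minimum distinct active units.
#' @param dur_range allowed duration range (s).
#' @param speed_max immobility threshold (cm/s).
#' @return data.frame of class `frame_set`: start, stop, duration, n_units,
#'   peak_z; member spikes retrievable with [frame_spikes()].
#' @export
detect_frames <- function(spikes, t_range, velocity_t = NULL, velocity = NULL,
                          bin = 0.001, sigma = 0.015, z_enter = 2,
                          min_units = 5, dur_range = c(0.1, 1.2),
                          speed_max = 2) {
  ids <- unit_ids(spikes, label = "pyramidal")
  all_t <- sort(unlist(lapply(spikes[ids], function(u) u$times)))
  empty <- data.frame(start = numeric(0), stop = numeric(0),
                      duration = numeric(0), n_units = integer(0),
                      peak_z = numeric(0))
  class(empty) <- c("frame_set", "data.frame")
  if (!length(all_t)) return(empty)
  edges <- seq(t_range[1], t_range[2] + bin, by = bin)
  mua <- graphics::hist(all_t[all_t >= t_range[1] & all_t <= t_range[2]],
                        breaks = edges, plot = FALSE)$counts
  mua_s <- smooth_vec(mua, gauss_kernel(sigma / bin))
  tc <- edges[-length(edges)] + bin / 2
  immobile <- if (is.null(velocity)) rep(TRUE, length(tc)) else {
    stats::approx(velocity_t, velocity, tc, rule = 2)$y < speed_max
  }
  m <- mean(mua_s[immobile]); s <- stats::sd(mua_s[immobile])
  if (!is.finite(s) || s == 0) return(empty)
  above <- mua_s > m + z_enter * s
  above_mean <- mua_s > m
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  out <- NULL
  last_stop <- -Inf
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    while (i0 > 1 && above_mean[i0 - 1]) i0 <- i0 - 1L          # extend to mean
    while (i1 < length(mua_s) && above_mean[i1 + 1]) i1 <- i1 + 1L
    st <- tc[i0]; en <- tc[i1]
    if (st <= last_stop) next                                   # merged
    dur <- en - st
    if (dur < dur_range[1] || dur > dur_range[2]) { last_stop <- en; next }
    if (!all(immobile[i0:i1])) { last_stop <- en; next }
    nu <- sum(vapply(spikes[ids], function(u) {
      any(u$times >= st & u$times <= en)
    }, logical(1)))
    if (nu < min_units) { last_stop <- en; next }
    out <- rbind(out, data.frame(start = st, stop = en, duration = dur,
                                 n_units = nu,
                                 peak_z = (max(mua_s[i0:i1]) - m) / s))
    last_stop <- en
  }
  if (is.null(out)) return(empty)
  class(out) <- c("frame_set", "data.frame")
  out
}

#' Member spikes of an event window
#' @param spikes a `spike_ensemble`.
#' @param start,stop window bounds (s).
#' @return data.frame (unit, time) sorted by time.
#' @export
frame_spikes <- function(spikes, start, stop) {
  out <- do.call(rbind, lapply(spikes, function(u) {
    tt <- u$times[u$times >= start & u$times <= stop]
    if (!length(tt)) return(NULL)
    data.frame(unit = u$unit_id, time = tt, stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    return(data.frame(unit = character(0), time = numeric(0)))
  }
  out[order(out$time), , drop = FALSE]
}

#' Detect ripple events
#'
#' 140-220 Hz band power envelope (squared analytic amplitude, smoothed);
#' candidates above mean + 5 sd extended to the mean + 2 sd crossings, with a
#' 30-200 ms duration filter.
#'
#' @param lfp an `lfp_channel`.
#' @param band ripple band (Hz).
#' @param z_enter,z_extend thresholds (sd above mean).
#' @param dur_range allowed duration range (s).
#' @param smooth_sd envelope smoothing sd (s).
#' @return data.frame: start, stop, duration, peak_z.
#' @export
detect_ripples <- function(lfp, band = c(140, 220), z_enter = 5, z_extend = 2,
                           dur_range = c(0.03, 0.2), smooth_sd = 0.002) {
  filt <- bandpass(lfp$samples, lfp$rate, band)
  env <- Mod(analytic_signal(filt))^2
  env <- smooth_vec(env, gauss_kernel(smooth_sd * lfp$rate))
  m <- mean(env); s <- stats::sd(env)
  t <- lfp_times(lfp)
  hi <- env > m + z_enter * s
  lo <- env > m + z_extend * s
  r <- rle(hi)
  ends <- cumsum(r$lengths); starts <- c(1L, utils::head(ends, -1) + 1L)
  out <- NULL; last_stop <- -Inf
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    while (i0 > 1 && lo[i0 - 1]) i0 <- i0 - 1L
    while (i1 < length(env) && lo[i1 + 1]) i1 <- i1 + 1L
    if (t[i0] <= last_stop) next
    dur <- t[i1] - t[i0]
    last_stop <- t[i1]
    if (dur < dur_range[1] || dur > dur_range[2]) next
    out <- rbind(out, data.frame(start = t[i0], stop = t[i1], duration = dur,
                                 peak_z = (max(env[i0:i1]) - m) / s))
  }
  if (is.null(out)) out <- data.frame(start = numeric(0), stop = numeric(0),
                                      duration = numeric(0), peak_z = numeric(0))
  out
}

#' Classify theta brain state during run
#'
#' Theta state requires velocity above 10 cm/s and the instantaneous power
#' ratio (7-10 Hz)/(2-15 Hz) above its session median.
#'
#' @param lfp an `lfp_channel`.
#' @param velocity_t,velocity velocity series (s, cm/s).
#' @param speed_min velocity threshold (cm/s).
#' @param theta_band,broad_band frequency bands (Hz).
#' @param smooth_sd power smoothing sd (s).
#' @return list: `t`, `theta_state` logical, `ratio`, `ratio_median`.
#' @export
classify_theta_state <- function(lfp, velocity_t, velocity, speed_min = 10,
                                 theta_band = c(7, 10), broad_band = c(2, 15),
                                 smooth_sd = 0.25) {
  pw <- function(band) {
    e <- Mod(analytic_signal(bandpass(lfp$samples, lfp$rate, band)))^2
    smooth_vec(e, gauss_kernel(smooth_sd * lfp$rate))
  }
  ratio <- pw(theta_band) / pmax(pw(broad_band), 1e-12)
  t <- lfp_times(lfp)
  v <- stats::approx(velocity_t, velocity, t, rule = 2)$y
  med <- stats::median(ratio)
  list(t = t, theta_state = v > speed_min & ratio > med, ratio = ratio,
       ratio_median = med)
}

#' Export event intervals as a BED-like table
#' @param events data.frame with start/stop columns.
#' @param type event type label.
#' @param score optional numeric score column name present in `events`.
#' @return data.frame (start, stop, type, score).
#' @export
events_to_bed <- function(events, type, score = NULL) {
  data.frame(start = events$start, stop = events$stop, type = type,
             score = if (!is.null(score)) events[[score]] else NA_real_)
}
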