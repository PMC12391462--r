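#' @title Theta-sequence statistics, phase locking/precession, jitter, CCG bias
#' @name theta_sequences
NULL

#' Quadrant ratio of a theta-cycle posterior
#'
#' The posterior is recentered on the animal's current position (rows outside
#' +/- `window` cm are dropped) with the spatial axis oriented along the
#' running direction; quadrants split at the cycle's temporal midpoint.
#' QR = (P(Q1) + P(Q3) - P(Q2) - P(Q4)) / sum, with Q1 the immediate future
#' (ahead, late half) and Q3 the recent past (behind, early half).
#'
#' @param post space x time posterior.
#' @param x spatial coordinates of rows (cm).
#' @param current_x animal position at the cycle (cm).
#' @param direction +1 or -1 (running direction along the spatial axis).
#' @param t temporal coordinates of columns (defaults to column index).
#' @param window spatial window around the animal (cm).
#' @return quadrant ratio in \[-1, 1\], NA if all mass falls outside the
#'   window (cycle dropped).
#' @export
quadrant_ratio <- function(post, x = seq_len(nrow(post)), current_x,
                           direction = 1, t = seq_len(ncol(post)),
                           window = 40) {
  rel <- (x - current_x) * sign(direction)
  keep <- abs(rel) <= window
  if (!any(keep)) return(NA_real_)
  P <- post[keep, , drop = FALSE]
  rel <- rel[keep]
  tm <- (min(t) + max(t)) / 2
  late <- t > tm; early <- t < tm
  ahead <- rel > 0; behind <- rel < 0
  q1 <- sum(P[ahead, late, drop = FALSE])
  q3 <- sum(P[behind, early, drop = FALSE])
  q2 <- sum(P[ahead, early, drop = FALSE])
  q4 <- sum(P[behind, late, drop = FALSE])
  tot <- q1 + q2 + q3 + q4
  if (tot <= 0) return(NA_real_)
  (q1 + q3 - q2 - q4) / tot
}

#' Population significance of theta sequences
#'
#' One-sided Wilcoxon signed-rank test that the quadrant-ratio distribution
#' is positive.
#'
#' @param qr quadrant ratios (NAs dropped).
#' @param alpha significance level.
#' @return list: `p_value`, `significant`, `n`, `median`.
#' @export
theta_sequence_test <- function(qr, alpha = 0.05) {
  qr <- qr[!is.na(qr)]
  if (length(qr) < 2) return(list(p_value = NA_real_, significant = FALSE,
                                  n = length(qr), median = stats::median(qr)))
  p <- suppressWarnings(stats::wilcox.test(qr, mu = 0,
                                           alternative = "greater")$p.value)
  list(p_value = p, significant = is.finite(p) && p < alpha, n = length(qr),
       median = stats::median(qr))
}

#' Rayleigh test of circular uniformity
#'
#' Z = n * Rbar^2 with the standard series p-value approximation.
#'
#' @param phases angles in radians.
#' @return list: `z`, `p_value`, `r` (mean resultant length), `mean_phase`.
#' @export
rayleigh_test <- function(phases) {
  n <- length(phases)
  if (n < 2) return(list(z = NA_real_, p_value = NA_real_, r = NA_real_,
                         mean_phase = NA_real_))
  C <- mean(cos(phases)); S <- mean(sin(phases))
  r <- sqrt(C^2 + S^2)
  z <- n * r^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - (n * r)^2)) - (1 + 2 * n))
  list(z = z, p_value = min(1, p), r = r, mean_phase = atan2(S, C) %% (2 * pi))
}

#' Theta phase locking of a unit
#'
#' Rayleigh test on spike phases; the preferred phase is the peak of the
#' 20-degree phase histogram.
#'
#' @param phases spike phases in radians.
#' @param bin_deg histogram bin width (degrees).
#' @return list: `z`, `p_value`, `preferred_phase` (radians, bin center).
#' @export
phase_locking <- function(phases, bin_deg = 20) {
  rt <- rayleigh_test(phases)
  edges <- seq(0, 2 * pi, by = bin_deg * pi / 180)
  h <- graphics::hist(phases %% (2 * pi), breaks = edges, plot = FALSE)
  list(z = rt$z, p_value = rt$p_value,
       preferred_phase = h$mids[which.max(h$counts)])
}

#' Theta phase precession within a place field
#'
#' Linear Pearson correlation between spike theta phase (not unwrapped) and
#' normalized in-field position.
#'
#' @param phases spike phases in radians.
#' @param pos_norm normalized position in the field, 0 (entry) to 1 (exit).
#' @return list: `r`, `p_value`, `n`.
#' @export
phase_precession <- function(phases, pos_norm) {
  ok <- is.finite(phases) & is.finite(pos_norm)
  if (sum(ok) < 3) return(list(r = NA_real_, p_value = NA_real_, n = sum(ok)))
  ct <- stats::cor.test(phases[ok], pos_norm[ok])
  list(r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}

#' Jitter spike times uniformly
#'
#' Each spike is independently shifted by U(-half_range, +half_range).
#' Generate once per half-range and reuse the same jittered set for both the
#' precession and the sequence tests.
#'
#' @param times spike times (s).
#' @param half_range jitter half-range (s); 0 returns times unchanged.
#' @return jittered (unsorted order preserved) spike times.
#' @export
jitter_spikes <- function(times, half_range) {
  if (half_range == 0) return(times)
  times + stats::runif(length(times), -half_range, half_range)
}

#' Jitter every unit of an ensemble
#' @param spikes a `spike_ensemble`.
#' @param half_range jitter half-range (s).
#' @return a new `spike_ensemble` with jittered, re-sorted spike times.
#' @export
jitter_ensemble <- function(spikes, half_range) {
  spike_ensemble(lapply(spikes, function(u) {
    spike_train(u$unit_id, sort(jitter_spikes(u$times, half_range)), u$label)
  }))
}

ccg_lags <- function(ti, tj, window) {
  if (!length(ti) || !length(tj)) return(numeric(0))
  tj <- sort(tj)
  lo <- findInterval(ti - window, tj) + 1L
  hi <- findInterval(ti + window, tj)
  n <- pmax(hi - lo + 1L, 0L)
  idx <- sequence(n) + rep(lo - 1L, n)
  rep(ti, n) * -1 + tj[idx]
}

#' Cross-correlogram temporal bias of a unit pair
#'
#' Center of mass of the lag distribution t_j - t_i within the window:
#' +/- 200 ms for the theta-compressed scale, +/- 1000 ms for the behavioral
#' scale. Exactly antisymmetric under swapping the pair.
#'
#' @param ti,tj spike times of units i and j (s).
#' @param window half-window (s).
#' @return list: `bias` (s), `n_pairs`.
#' @export
ccg_bias <- function(ti, tj, window = 0.2) {
  lags <- ccg_lags(ti, tj, window)
  lags <- lags[abs(lags) <= window]
  list(bias = if (length(lags)) mean(lags) else NA_real_,
       n_pairs = length(lags))
}

#' Binned, low-pass-filtered CCG curve with peak significance
#'
#' @param ti,tj spike times (s).
#' @param window half-window (s).
#' @param bin histogram bin (s).
#' @param lp_cutoff low-pass cutoff (Hz); < 0.5 Hz behavioral, < 30 Hz theta.
#' @return list: `lag` (bin centers), `curve` (filtered counts), `counts`,
#'   `significant` (peak > mean + 2 sd and > 2 counts).
#' @export
ccg_curve <- function(ti, tj, window = 1, bin = 0.01, lp_cutoff = 0.5) {
  lags <- ccg_lags(ti, tj, window)
  edges <- seq(-window, window + bin * 1e-9, by = bin)
  h <- graphics::hist(lags[lags >= -window & lags <= window],
                      breaks = edges, plot = FALSE)
  rate <- 1 / bin
  curve <- if (lp_cutoff < rate / 2 && length(h$counts) > 12) {
    bf <- signal::butter(2, lp_cutoff / (rate / 2), type = "low")
    as.numeric(signal::filtfilt(bf, h$counts))
  } else h$counts
  sig <- max(h$counts) > mean(h$counts) + 2 * stats::sd(h$counts) &&
    max(h$counts) > 2
  list(lag = h$mids, curve = curve, counts = h$counts, significant = sig)
}

#' False-positive calibration of the theta-sequence significance test
#'
#' Draws random subpopulations of cycle posteriors, independently
#' column-shuffles each drawn posterior (destroying the time-position sweep),
#' scores quadrant ratios, and runs the one-sided signed-rank positivity test
#' on each subpopulation at `alpha`. The fraction of significant
#' subpopulations estimates the procedure's empirical false-positive rate.
#'
#' @param posteriors list of space x time cycle posteriors.
#' @param x spatial axis of the posteriors (centered on the animal).
#' @param n_subpop number of subpopulation draws.
#' @param subpop_size cycles per subpopulation.
#' @param alpha signed-rank significance level.
#' @param window quadrant-ratio spatial window (cm).
#' @return list: `fpr` (fraction significant), `n_subpop`, `alpha`.
#' @export
qr_shuffle_calibration <- function(posteriors, x, n_subpop = 1000,
                                   subpop_size = 100, alpha = 0.01,
                                   window = 40) {
  n <- length(posteriors)
  sig <- logical(n_subpop)
  for (b in seq_len(n_subpop)) {
    idx <- sample.int(n, subpop_size, replace = subpop_size > n)
    qr <- vapply(idx, function(i) {
      P <- posteriors[[i]]
      quadrant_ratio(P[, sample.int(ncol(P)), drop = FALSE], x = x,
                     current_x = 0, window = window)
    }, numeric(1))
    sig[b] <- isTRUE(theta_sequence_test(qr, alpha = alpha)$significant)
  }
  list(fpr = mean(sig), n_subpop = n_subpop, alpha = alpha)
}

#' Matched-false-positive comparison of theta-sequence vs replay emergence
#'
#' Estimates the replay criterion's empirical false-positive rate from
#' time-bin shuffles of the candidate frames, sets the theta-sequence alpha
#' to at most that rate, then for each candidate frame tests whether the
#' population of quadrant ratios from all earlier theta cycles is
#' significantly positive. Reports the first significant time and lap for
#' each phenomenon.
#'
#' @param cycles data.frame with `time`, `lap`, `qr` per theta cycle.
#' @param frames list of space x time frame posteriors.
#' @param frame_times,frame_laps time (s) and lap index per frame.
#' @param alpha configured theta-sequence alpha (capped by the empirical
#'   replay false-positive rate).
#' @param wc_min,jump_max replay two-parameter criterion.
#' @param n_shuffles shuffles per frame for the false-positive estimate.
#' @return list: `theta_time`, `theta_lap`, `replay_time`, `replay_lap`,
#'   `replay_fpr`, `alpha_used`, per-frame replay flags.
#' @export
emergence_comparison <- function(cycles, frames, frame_times, frame_laps,
                                 alpha = 0.01, wc_min = 0.6, jump_max = 0.4,
                                 n_shuffles = 200) {
  stopifnot(length(frames) == length(frame_times))
  fp <- 0L; tot <- 0L
  replay_sig <- logical(length(frames))
  for (k in seq_along(frames)) {
    P <- frames[[k]]
    res <- time_bin_shuffle_test(P, n_shuffles = n_shuffles, wc_min = wc_min,
                                 jump_max = jump_max, criterion = "two_param")
    replay_sig[k] <- res$significant
    nc <- ncol(P)
    sh <- vapply(seq_len(n_shuffles), function(s) {
      Q <- P[, sample.int(nc), drop = FALSE]
      abs(weighted_correlation(Q)) > wc_min && max_jump(Q) < jump_max
    }, logical(1))
    fp <- fp + sum(sh); tot <- tot + n_shuffles
  }
  fpr <- fp / max(tot, 1)
  alpha_used <- min(alpha, max(fpr, 1e-6))
  ord <- order(frame_times)
  theta_time <- NA_real_; theta_lap <- NA_integer_
  for (k in ord) {
    prior <- cycles[cycles$time < frame_times[k], , drop = FALSE]
    tst <- theta_sequence_test(prior$qr, alpha = alpha_used)
    if (isTRUE(tst$significant)) {
      theta_time <- frame_times[k]
      theta_lap <- frame_laps[k]
      break
    }
  }
  first_rep <- ord[replay_sig[ord]][1]
  list(theta_time = theta_time, theta_lap = theta_lap,
       replay_time = if (!is.na(first_rep)) frame_times[first_rep] else NA_real_,
       replay_lap = if (!is.na(first_rep)) frame_laps[first_rep] else NA_integer_,
       replay_fpr = fpr, alpha_used = alpha_used, replay_significant = replay_sig)
}
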