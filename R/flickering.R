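#' @title Alternate-context (flicker) decoding during run
#'
#' @description During runs the posterior is distributed over five
#' concatenated segment templates — first stationary, current segment, last
#' stationary, alternative segment, control segment — rescaled to a common
#' mean rate. Epochs where the alternative context's summed probability
#' exceeds 0.5 at running speed are flicker epochs; strong-representation
#' bins (probability > 0.9, >= 3 active units) are tested for theta-phase
#' modulation.
#' @name flickering
NULL

#' Five-segment concatenated flicker decoding
#'
#' @param counts units x time-bins spike counts (40 ms bins).
#' @param templates named list of the five units x bins segment templates
#'   (names become context labels, e.g. first_stationary, current,
#'   last_stationary, alternative, control).
#' @param tau time-bin width (s).
#' @param min_active downstream analyses use only bins with more than this
#'   many active units.
#' @return the `posterior` from [concatenated_decode()] plus attribute
#'   `usable` (per-bin active-unit gate).
#' @export
flicker_decode <- function(counts, templates, tau = 0.04, min_active = 3) {
  P <- concatenated_decode(counts, templates, tau, rescale = TRUE)
  attr(P, "usable") <- attr(P, "n_active") > min_active
  P
}

#' Identify context-representing epochs
#'
#' The summed context probability is smoothed with a 40 ms moving average;
#' epochs are maximal runs with smoothed probability above the threshold and
#' running speed above 10 cm/s. Boundary bins below threshold are excluded.
#'
#' @param prob summed context probability per time bin.
#' @param t bin center times (s).
#' @param velocity velocity at bin centers (cm/s).
#' @param threshold probability cut.
#' @param smooth_bins moving-average width (bins; 1 = the 40 ms native bin).
#' @param speed_min running-speed cut (cm/s).
#' @return data.frame: start, stop, duration, mean_prob.
#' @export
find_epochs <- function(prob, t, velocity, threshold = 0.5, smooth_bins = 1,
                        speed_min = 10) {
  ps <- if (smooth_bins > 1) {
    as.numeric(zoo::rollmean(zoo::zoo(prob), smooth_bins, fill = NA))
  } else prob
  ok <- !is.na(ps) & ps > threshold & velocity > speed_min
  r <- rle(ok)
  ends <- cumsum(r$lengths); starts <- c(1L, utils::head(ends, -1) + 1L)
  out <- NULL
  dt <- if (length(t) > 1) t[2] - t[1] else 0.04
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    out <- rbind(out, data.frame(start = t[i0] - dt / 2, stop = t[i1] + dt / 2,
                                 duration = t[i1] - t[i0] + dt,
                                 mean_prob = mean(ps[i0:i1])))
  }
  if (is.null(out)) out <- data.frame(start = numeric(0), stop = numeric(0),
                                      duration = numeric(0),
                                      mean_prob = numeric(0))
  out
}

#' Theta-phase modulation of context probability
#'
#' Mean context probability per phase bin (probability assigned to the
#' decoding-window midpoint's phase) with an s.e.m. whose degrees of freedom
#' are corrected to 10% of the window count (for 90%-overlap windows), plus
#' a Rayleigh uniformity test on the phases of strong-representation bins.
#'
#' @param prob context probability per window.
#' @param phase theta phase at each window midpoint (radians).
#' @param usable logical active-unit gate per window.
#' @param strong_threshold strong-representation probability cut.
#' @param n_phase_bins phase histogram bins.
#' @param df_fraction fraction of windows counted as independent.
#' @return list: `curve` data.frame (phase, mean, sem), `rayleigh` test on
#'   strong-bin phases (NULL with a message if none).
#' @export
phase_modulation <- function(prob, phase, usable = rep(TRUE, length(prob)),
                             strong_threshold = 0.9, n_phase_bins = 18,
                             df_fraction = 0.1) {
  keep <- usable & !is.na(prob) & !is.na(phase)
  edges <- seq(0, 2 * pi, length.out = n_phase_bins + 1)
  bin <- findInterval(phase[keep] %% (2 * pi), edges, all.inside = TRUE)
  pv <- prob[keep]
  curve <- do.call(rbind, lapply(seq_len(n_phase_bins), function(b) {
    v <- pv[bin == b]
    n_eff <- max(1, round(length(v) * df_fraction))
    data.frame(phase = (edges[b] + edges[b + 1]) / 2,
               mean = mean(v), sem = stats::sd(v) / sqrt(n_eff), n = length(v))
  }))
  strong <- phase[keep][pv > strong_threshold]
  ray <- if (length(strong) >= 2) rayleigh_test(strong) else {
    message("no strong-representation bins; Rayleigh test skipped")
    NULL
  }
  list(curve = curve, rayleigh = ray, n_strong = length(strong))
}

#' Lap-by-position pattern of non-local probability and its first PC
#'
#' Probability averaged into a (lap x position-bin) matrix, then PCA; PC1
#' loadings give the spatial profile and PC1 scores the across-lap profile.
#' The corner contrast compares mean PC1 loading within `near` cm of the
#' segment-entry corners against loadings beyond `far` cm.
#'
#' @param prob non-local probability per window.
#' @param lap lap index per window.
#' @param pos linear position per window (cm).
#' @param corner_pos corner positions (cm) on the current track.
#' @param pos_bin position bin (cm).
#' @param near,far corner-distance cuts (cm).
#' @return list: `matrix` (laps x bins), `pc1_spatial`, `pc1_temporal`,
#'   `corner_contrast` (near mean - far mean of PC1 loadings).
#' @export
spatiotemporal_pattern <- function(prob, lap, pos, corner_pos,
                                   pos_bin = 5, near = 20, far = 40) {
  laps <- sort(unique(lap))
  if (length(laps) < 2) stop("need >= 2 laps")
  edges <- seq(min(pos), max(pos) + pos_bin, by = pos_bin)
  pb <- findInterval(pos, edges, all.inside = TRUE)
  nb <- length(edges) - 1
  M <- matrix(NA_real_, length(laps), nb)
  for (i in seq_along(laps)) {
    for (b in seq_len(nb)) {
      v <- prob[lap == laps[i] & pb == b]
      if (length(v)) M[i, b] <- mean(v)
    }
  }
  Mz <- M; Mz[is.na(Mz)] <- mean(M, na.rm = TRUE)
  pc <- stats::prcomp(Mz, center = TRUE, scale. = FALSE)
  ## loadings scaled by the component sd so magnitudes reflect structure;
  ## sign fixed so the spatial profile points toward positive probability
  rot <- pc$rotation[, 1]
  if (sum(rot) < 0) rot <- -rot
  load <- rot * pc$sdev[1]
  score <- as.numeric(Mz %*% rot)
  ctr <- edges[-length(edges)] + pos_bin / 2
  dcorner <- vapply(ctr, function(x) min(abs(x - corner_pos)), numeric(1))
  contrast <- mean(load[dcorner < near]) - mean(load[dcorner > far])
  list(matrix = M, pc1_spatial = load, pc1_temporal = score,
       bin_centers = ctr, corner_contrast = contrast)
}

#' Classify units by their flicker-epoch spiking preference
#'
#' A unit is non-local-representing if the majority of its in-epoch spikes
#' fall in non-local epochs, local-representing otherwise; units with no
#' in-epoch spikes are unclassified.
#'
#' @param spikes a `spike_ensemble`.
#' @param nonlocal_epochs,local_epochs epoch tables (start, stop).
#' @return data.frame: unit, n_nonlocal, n_local, class.
#' @export
classify_flicker_cells <- function(spikes, nonlocal_epochs, local_epochs) {
  count_in <- function(tt, ep) {
    if (!nrow(ep)) return(0L)
    sum(vapply(seq_len(nrow(ep)), function(r) {
      sum(tt >= ep$start[r] & tt < ep$stop[r])
    }, integer(1)))
  }
  do.call(rbind, lapply(spikes, function(u) {
    nn <- count_in(u$times, nonlocal_epochs)
    nl <- count_in(u$times, local_epochs)
    cls <- if (nn + nl == 0) NA_character_
    else if (nn > nl) "nonlocal" else "local"
    data.frame(unit = u$unit_id, n_nonlocal = nn, n_local = nl, class = cls,
               stringsAsFactors = FALSE)
  }))
}

#' Score flicker-epoch spike sequences under a sleep transition model
#'
#' Eq-4 normalized probability and random-sequence percentile per epoch
#' sequence; non-local vs local epochs are compared with a rank-sum test.
#' Epochs with fewer than 2 units are excluded.
#'
#' @param model a `transition_model` from the preceding sleep.
#' @param nonlocal_seqs,local_seqs lists of epoch unit sequences.
#' @param n_shuffles random sequences per epoch.
#' @return list: `nonlocal`, `local` (percentile data.frames), `p_value`
#'   (one-sided rank-sum, nonlocal > local on normalized log-probability).
#' @export
flicker_sleep_prediction <- function(model, nonlocal_seqs, local_seqs,
                                     n_shuffles = 10000) {
  prep <- function(seqs) {
    seqs <- lapply(seqs, function(s) s[s %in% model$units])
    seqs[lengths(seqs) >= 2]
  }
  nl <- prep(nonlocal_seqs); lc <- prep(local_seqs)
  score <- function(seqs) {
    if (!length(seqs)) return(NULL)
    res <- sequence_significance_batch(model, seqs, n_shuffles)
    res$norm_log_prob <- res$log_prob / res$length
    res
  }
  rn <- score(nl); rl <- score(lc)
  p <- if (!is.null(rn) && !is.null(rl)) {
    suppressWarnings(stats::wilcox.test(rn$norm_log_prob, rl$norm_log_prob,
                                        alternative = "greater")$p.value)
  } else NA_real_
  list(nonlocal = rn, local = rl, p_value = p)
}
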