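#' @title Memoryless Bayesian decoding and trajectory statistics
#'
#' @description Standard memoryless Poisson population decoder with a uniform
#' spatial prior: P(x | n) is proportional to prod_i f_i(x)^(n_i) *
#' exp(-tau * sum_i f_i(x)), accumulated in log space. Template rates are
#' floored at rate + mean_rate * 1e-5 to avoid zero decoding probability.
#' @name decoding
NULL

#' Bin spikes into a counts matrix
#'
#' @param spikes a `spike_ensemble`.
#' @param start,stop window (s).
#' @param tau time-bin width (s).
#' @param units unit ids (row order of the counts matrix).
#' @return units x time-bins integer matrix; bin centers as attribute `t`.
#' @export
bin_spikes <- function(spikes, start, stop, tau, units = unit_ids(spikes)) {
  edges <- seq(start, stop + tau * 1e-9, by = tau)
  if (edges[length(edges)] < stop - 1e-12) edges <- c(edges, edges[length(edges)] + tau)
  nb <- length(edges) - 1L
  M <- matrix(0L, length(units), nb, dimnames = list(units, NULL))
  for (i in seq_along(units)) {
    tt <- spikes[[units[i]]]$times
    tt <- tt[tt >= start & tt < edges[length(edges)]]
    if (length(tt)) M[i, ] <- graphics::hist(tt, breaks = edges, plot = FALSE)$counts
  }
  attr(M, "t") <- edges[-length(edges)] + tau / 2
  M
}

floor_template <- function(rate) {
  rate[is.na(rate)] <- 0
  mr <- rowMeans(rate)
  rate + pmax(mr, 1e-12) * 1e-5
}

#' Memoryless Bayesian posterior over position
#'
#' @param counts units x time-bins spike counts ([bin_spikes()]).
#' @param template units x space-bins rate matrix (Hz); NA bins treated as 0
#'   before flooring.
#' @param tau time-bin width (s).
#' @return space-bins x time-bins posterior of class `posterior`; each column
#'   sums to 1. Attributes: `tau`, `n_active` spikes-emitting units per bin,
#'   `zero_spike` flag for uniform-prior-dominated columns.
#' @export
decode_posterior <- function(counts, template, tau) {
  stopifnot(nrow(counts) == nrow(template))
  f <- floor_template(template)
  lf <- log(f)
  ll <- t(lf) %*% counts - matrix(colSums(f) * tau, ncol(template), ncol(counts))
  ll <- sweep(ll, 2, apply(ll, 2, max))
  P <- exp(ll)
  P <- sweep(P, 2, colSums(P), "/")
  attr(P, "tau") <- tau
  attr(P, "n_active") <- colSums(counts > 0)
  attr(P, "zero_spike") <- colSums(counts) == 0
  attr(P, "t") <- attr(counts, "t")
  class(P) <- c("posterior", class(P))
  P
}

#' Concatenated multi-track decoding
#'
#' Templates from several tracks/segments are rescaled to a common mean
#' firing rate, concatenated along the spatial axis, and decoded jointly so
#' tracks compete for posterior probability.
#'
#' @param counts units x time-bins spike counts.
#' @param templates named list of units x bins rate matrices.
#' @param tau time-bin width (s).
#' @param rescale rescale each template to the common mean rate.
#' @return `posterior` with attribute `context` (template name per spatial
#'   row) and `context_prob` (templates x time-bins summed probability).
#' @export
concatenated_decode <- function(counts, templates, tau, rescale = TRUE) {
  stopifnot(length(templates) >= 2)
  if (rescale) {
    mr <- vapply(templates, function(m) mean(m, na.rm = TRUE), numeric(1))
    target <- mean(mr)
    templates <- Map(function(m, r) m * (target / max(r, 1e-12)), templates, mr)
  }
  big <- do.call(cbind, templates)
  ctx <- rep(names(templates), vapply(templates, ncol, integer(1)))
  P <- decode_posterior(counts, big, tau)
  cp <- do.call(rbind, lapply(names(templates), function(nm) {
    colSums(P[ctx == nm, , drop = FALSE])
  }))
  rownames(cp) <- names(templates)
  attr(P, "context") <- ctx
  attr(P, "context_prob") <- cp
  P
}

#' Weighted correlation of a posterior
#'
#' Pearson correlation between time-bin index and spatial-bin index weighted
#' by the posterior mass: cov_w(t, x) / sqrt(var_w(t) var_w(x)).
#'
#' @param post space x time posterior matrix.
#' @param x spatial coordinates per row (default row index).
#' @param t temporal coordinates per column (default column index).
#' @return weighted correlation in \[-1, 1\]; NA if a weighted variance is 0.
#' @export
weighted_correlation <- function(post, x = seq_len(nrow(post)),
                                 t = seq_len(ncol(post))) {
  w <- as.matrix(post)
  W <- sum(w)
  if (W <= 0) return(NA_real_)
  mx <- sum(w * x) / W
  mt <- sum(sweep(w, 2, t, "*")) / W
  vx <- sum(w * (x - mx)^2) / W
  vt <- sum(sweep(w, 2, (t - mt)^2, "*")) / W
  if (vx <= 0 || vt <= 0) return(NA_real_)
  cv <- sum(sweep(w * (x - mx), 2, (t - mt), "*")) / W
  cv / sqrt(vx * vt)
}

#' Normalized maximum jump distance
#'
#' Maximum absolute difference between peak decoded locations in consecutive
#' time bins, normalized by the track length.
#'
#' @param post space x time posterior.
#' @param bin_width spatial bin width (cm).
#' @param track_length track length (cm); default spans the posterior.
#' @return value in \[0, 1\]; 0 for a single-column posterior.
#' @export
max_jump <- function(post, bin_width = 1,
                     track_length = nrow(post) * bin_width) {
  pk <- apply(post, 2, which.max)
  if (length(pk) < 2) return(0)
  max(abs(diff(pk))) * bin_width / track_length
}

#' Time-bin shuffle significance of a decoded trajectory
#'
#' Shuffle = random permutation of the posterior's time-bin columns (circular
#' column shift available as an option). Reports the percentile of |wc|
#' against the shuffle distribution plus the two-parameter criterion
#' |wc| > `wc_min` AND normalized max jump < `jump_max`.
#'
#' @param post space x time posterior.
#' @param n_shuffles number of shuffles.
#' @param wc_min,jump_max two-parameter criterion thresholds.
#' @param criterion `"two_param"` (thresholds) or `"percentile"` (|wc| above
#'   `pct_min` of shuffles).
#' @param pct_min percentile cut for the one-parameter criterion.
#' @param variant `"permute"` or `"circular"` column shuffle.
#' @param bin_width,track_length forwarded to [max_jump()].
#' @return list of class `trajectory_score`: `wc`, `jump`, `percentile`,
#'   `significant`, `shuffle_wc`.
#' @export
time_bin_shuffle_test <- function(post, n_shuffles = 1000, wc_min = 0.6,
                                  jump_max = 0.4,
                                  criterion = c("two_param", "percentile"),
                                  pct_min = 95, variant = c("permute", "circular"),
                                  bin_width = 1,
                                  track_length = nrow(post) * bin_width) {
  criterion <- match.arg(criterion)
  variant <- match.arg(variant)
  wc <- weighted_correlation(post)
  jump <- max_jump(post, bin_width, track_length)
  nc <- ncol(post)
  shuffle_wc <- vapply(seq_len(n_shuffles), function(s) {
    idx <- if (variant == "permute") sample.int(nc) else {
      ((seq_len(nc) - 1 + sample.int(nc, 1)) %% nc) + 1
    }
    abs(weighted_correlation(post[, idx, drop = FALSE]))
  }, numeric(1))
  pct <- 100 * mean(shuffle_wc < abs(wc), na.rm = TRUE)
  sig <- if (criterion == "two_param") {
    !is.na(wc) && abs(wc) > wc_min && jump < jump_max
  } else {
    !is.na(wc) && pct > pct_min
  }
  structure(list(wc = wc, jump = jump, percentile = pct, significant = sig,
                 shuffle_wc = shuffle_wc, criterion = criterion),
            class = "trajectory_score")
}

#' Classify a frame as forward/reverse replay of a template
#'
#' The frame is decoded against every candidate (track, direction) template;
#' a significant frame is assigned to the template with the best |wc|
#' (ties: higher |wc|, then lower template index). Forward means the decoded
#' trajectory advances along the template's running direction (wc > 0).
#'
#' @param counts units x time-bins frame spike counts.
#' @param templates named list of units x bins rate templates.
#' @param tau time-bin width (s).
#' @param ... passed to [time_bin_shuffle_test()].
#' @return list: `direction` ("forward"/"reverse"/"none"), `template`, `wc`,
#'   `jump`, `scores` per template.
#' @export
classify_replay_direction <- function(counts, templates, tau, ...) {
  scores <- lapply(templates, function(tp) {
    P <- decode_posterior(counts, tp, tau)
    time_bin_shuffle_test(P, ...)
  })
  wcs <- vapply(scores, function(s) abs(s$wc %||% NA_real_), numeric(1))
  sig <- vapply(scores, function(s) isTRUE(s$significant), logical(1))
  if (!any(sig)) {
    return(list(direction = "none", template = NA_character_,
                wc = NA_real_, jump = NA_real_, scores = scores))
  }
  cand <- which(sig)
  best <- cand[order(-wcs[cand], cand)][1]
  bs <- scores[[best]]
  list(direction = if (bs$wc > 0) "forward" else "reverse",
       template = names(templates)[best], wc = bs$wc, jump = bs$jump,
       scores = scores)
}

#' Median absolute decoding error during run
#'
#' Validation utility: decode the run at coarse bins and compare the
#' posterior peak with the animal's actual linear position.
#'
#' @param spikes a `spike_ensemble`.
#' @param trajectory a `trajectory_session`.
#' @param template units x bins rate matrix with `bin_centers` attribute or
#'   a `place_map_set`.
#' @param tau validation time-bin width (s).
#' @param speed_min restrict to running samples (cm/s).
#' @return median absolute error (cm).
#' @export
decoding_error <- function(spikes, trajectory, template, tau = 0.2,
                           speed_min = 10) {
  if (inherits(template, "place_map_set")) {
    ctr <- template$bin_centers
    template <- template$rate
  } else {
    ctr <- attr(template, "bin_centers")
  }
  counts <- bin_spikes(spikes, min(trajectory$t), max(trajectory$t), tau)
  P <- decode_posterior(counts, template, tau)
  tb <- attr(P, "t")
  pos <- stats::approx(trajectory$t, trajectory$lin, tb, rule = 2)$y
  v <- stats::approx(trajectory$t, trajectory$velocity, tb, rule = 2)$y
  keep <- v > speed_min & !attr(P, "zero_spike")
  est <- ctr[apply(P, 2, which.max)]
  stats::median(abs(est - pos)[keep])
}
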