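#' @title Plastic/elastic indices, assemblies, regression variance shares,
#'   drift prediction
#' @name plasticity_drift
NULL

#' Concatenated stationary-segment tuning vector
#'
#' Rates on the first and last 50 cm stationary segments, concatenated, so
#' the vector length matches across sessions regardless of the middle
#' segment's configuration.
#'
#' @param maps a `place_map_set`.
#' @param track track index (1-4).
#' @return units x bins matrix restricted to the two stationary segments.
#' @export
tuning_vector <- function(maps, track) {
  keep <- maps$segment %in% c("first_stationary", "last_stationary")
  idx <- which(keep & maps$track == track)
  maps$rate[, idx, drop = FALSE]
}

#' Plastic/elastic index of a unit or assembly
#'
#' cos(post, det) - cos(post, pre): +1 when the post-detour tuning equals the
#' detour tuning given complete pre-to-detour remapping (plastic), -1 when it
#' reverts to the pre-detour tuning (elastic), ~0 for stable or random
#' tunings.
#'
#' @param pre,det,post nonnegative tuning vectors of equal length.
#' @param threshold |index| classification cut.
#' @return list: `index`, `class` ("plastic", "elastic" or "neutral").
#' @export
plastic_elastic <- function(pre, det, post, threshold = 0.3) {
  stopifnot(length(pre) == length(det), length(det) == length(post))
  idx <- cosine_sim(post, det) - cosine_sim(post, pre)
  cls <- if (is.na(idx)) NA_character_
  else if (idx > threshold) "plastic"
  else if (idx < -threshold) "elastic"
  else "neutral"
  list(index = idx, class = cls)
}

#' Session-pair tuning similarity grouped by detour relation
#'
#' Cosine similarity of concatenated stationary-segment tunings for every
#' session pair, labeled by session lag and detour-relation group:
#' `no_detour` (pairs on never-detoured tracks, virtual detour sessions
#' assigned per the counterbalancing), `before_vs_detour`, `after_vs_detour`,
#' `before_vs_after`.
#'
#' @param tunings list over sessions of units x bins tuning matrices
#'   (same shape).
#' @param detour_session index of the detour session for this track, or NA
#'   for a control track (virtual detour session index must then be given).
#' @param virtual_detour virtual detour session index for control tracks.
#' @param is_control logical: control (never-detoured) track.
#' @return data.frame: session_a, session_b, lag, group, similarity (mean
#'   over units).
#' @export
session_pair_similarity_groups <- function(tunings, detour_session = NA,
                                           virtual_detour = NA,
                                           is_control = is.na(detour_session)) {
  ns <- length(tunings)
  if (ns < 2) stop("need >= 2 sessions")
  det <- if (is_control) virtual_detour else detour_session
  out <- NULL
  for (a in 1:(ns - 1)) {
    for (b in (a + 1):ns) {
      grp <- if (is_control) "no_detour"
      else if (a < det && b == det) "before_vs_detour"
      else if (a == det && b > det) "after_vs_detour"
      else if (a < det && b > det) "before_vs_after"
      else "no_detour"
      sims <- vapply(seq_len(nrow(tunings[[a]])), function(i) {
        cosine_sim(tunings[[a]][i, ], tunings[[b]][i, ])
      }, numeric(1))
      out <- rbind(out, data.frame(session_a = a, session_b = b, lag = b - a,
                                   group = grp,
                                   similarity = mean(sims, na.rm = TRUE)))
    }
  }
  out
}

#' Detect cell assemblies by Marchenko-Pastur thresholded PCA
#'
#' Spikes are binned (20 ms) and z-scored per unit; principal components of
#' the unit correlation matrix whose eigenvalues exceed the Marchenko-Pastur
#' upper bound (1 + sqrt(N_units / N_bins))^2 are assemblies. Member units
#' have weights more than 2 sd above the eigenvector's mean weight. The
#' eigenvector sign is fixed so the largest-magnitude weight is positive.
#'
#' @param spikes a `spike_ensemble` or a pre-binned units x bins matrix.
#' @param t_range window (s) when `spikes` is an ensemble.
#' @param bin bin width (s).
#' @return object of class `assembly_set`: `weights` (units x assemblies),
#'   `eigenvalues`, `bound`, `members` (list), `dropped` silent units.
#' @export
detect_assemblies <- function(spikes, t_range = NULL, bin = 0.02) {
  if (inherits(spikes, "spike_ensemble")) {
    stopifnot(!is.null(t_range))
    M <- bin_spikes(spikes, t_range[1], t_range[2], bin)
  } else M <- spikes
  if (nrow(M) < 2) stop("need >= 2 units")
  sds <- apply(M, 1, stats::sd)
  dropped <- rownames(M)[sds == 0]
  if (length(dropped)) {
    warning("dropping silent units: ", paste(dropped, collapse = ", "))
  }
  M <- M[sds > 0, , drop = FALSE]
  nu <- nrow(M); nb <- ncol(M)
  if (nb < nu) stop("fewer time bins than units: Marchenko-Pastur bound undefined")
  Z <- (M - rowMeans(M)) / apply(M, 1, stats::sd)
  C <- tcrossprod(Z) / nb
  eg <- eigen(C, symmetric = TRUE)
  bound <- (1 + sqrt(nu / nb))^2
  keep <- which(eg$values > bound)
  W <- eg$vectors[, keep, drop = FALSE]
  for (k in seq_len(ncol(W))) {
    if (W[which.max(abs(W[, k])), k] < 0) W[, k] <- -W[, k]
  }
  rownames(W) <- rownames(M)
  members <- lapply(seq_len(ncol(W)), function(k) {
    w <- W[, k]
    rownames(M)[w > mean(w) + 2 * stats::sd(w)]
  })
  structure(list(weights = W, eigenvalues = eg$values[keep], bound = bound,
                 members = members, units = rownames(M), dropped = dropped,
                 bin = bin),
            class = "assembly_set")
}

#' Assembly activation time series
#'
#' A(t) = z(t)' (w w' - diag(w w')) z(t) on z-scored bins; the zeroed
#' diagonal removes single-unit contributions.
#'
#' @param weights unit weight vector of one assembly.
#' @param spikes a `spike_ensemble` or pre-binned units x bins matrix (rows
#'   must match the weight vector's units).
#' @param t_range,bin binning parameters when `spikes` is an ensemble.
#' @return numeric activation per time bin (attribute `t` when binned here).
#' @export
assembly_activation <- function(weights, spikes, t_range = NULL, bin = 0.02) {
  if (inherits(spikes, "spike_ensemble")) {
    M <- bin_spikes(spikes, t_range[1], t_range[2], bin,
                    units = names(weights))
  } else M <- spikes
  sds <- apply(M, 1, stats::sd)
  Z <- (M - rowMeans(M)) / ifelse(sds > 0, sds, 1)
  P <- tcrossprod(weights)
  diag(P) <- 0
  a <- colSums(Z * (P %*% Z))
  attr(a, "t") <- attr(M, "t")
  a
}

#' Assembly similarity between two sessions
#'
#' Pearson correlations between all weight-vector pairs across the two
#' assembly sets; the mean over rows of the row-maximum is the session-pair
#' similarity.
#'
#' @param setA,setB `assembly_set` objects over the same units.
#' @return mean of row-max correlations (rows = assemblies of `setA`).
#' @export
assembly_similarity <- function(setA, setB) {
  common <- intersect(setA$units, setB$units)
  WA <- setA$weights[common, , drop = FALSE]
  WB <- setB$weights[common, , drop = FALSE]
  if (!ncol(WA) || !ncol(WB)) return(NA_real_)
  R <- stats::cor(WA, WB)
  mean(apply(R, 1, max))
}

#' Variance of post-detour tuning explained by each regressor
#'
#' Fits Post = c0 + c1*Ave + b1*Pre + b2*Det + b3*OT + b4*T1 + b5*T3 by
#' ordinary least squares across stacked (unit, spatial-bin) observations.
#' Each regressor's variance share is (resid_without - resid_full) /
#' resid_full using Frobenius-norm residuals; significance comes from an
#' observation-identity (unit) shuffle of that regressor.
#'
#' @param post units x bins matrix of post-detour tunings.
#' @param regressors named list of units x bins matrices (must include
#'   `Ave`; shares are reported for the others).
#' @param n_shuffle unit-identity shuffles per regressor.
#' @return data.frame: regressor, share, percentile (vs shuffle).
#' @export
regression_variance_explained <- function(post, regressors, n_shuffle = 1000) {
  stopifnot("Ave" %in% names(regressors))
  y <- as.vector(t(post))
  X <- do.call(cbind, lapply(regressors, function(m) as.vector(t(m))))
  colnames(X) <- names(regressors)
  if (qr(cbind(1, X))$rank < ncol(X) + 1) {
    stop("rank-deficient design; drop or merge collinear regressors")
  }
  resid_norm <- function(Xm) {
    fit <- stats::lm.fit(cbind(1, Xm), y)
    sqrt(sum(fit$residuals^2))
  }
  res_full <- resid_norm(X)
  nu <- nrow(post); nb <- ncol(post)
  of_interest <- setdiff(names(regressors), "Ave")
  out <- NULL
  for (r in of_interest) {
    res_r <- resid_norm(X[, setdiff(colnames(X), r), drop = FALSE])
    share <- (res_r - res_full) / res_full
    sh <- vapply(seq_len(n_shuffle), function(b) {
      Xs <- X
      perm <- sample.int(nu)
      m <- matrix(X[, r], nu, nb, byrow = TRUE)[perm, , drop = FALSE]
      Xs[, r] <- as.vector(t(m))
      res_rs <- resid_norm(Xs[, setdiff(colnames(X), r), drop = FALSE])
      (res_rs - resid_norm(Xs)) / resid_norm(Xs)
    }, numeric(1))
    out <- rbind(out, data.frame(regressor = r, share = share,
                                 percentile = 100 * mean(sh < share)))
  }
  out
}

#' Predict Run4 drift vs stable place-map sequences from sleep models
#'
#' Units with Run4 peak rate above `peak_min` are split into stable
#' (Run1-Run4 map correlation > `threshold`) and drift (< `threshold`)
#' groups, ordered by Run4 peak location, and each group's sequence is scored
#' under the Sleep1 and Sleep3 transition models (geometric-mean-normalized
#' Eq-4 probability plus random-sequence percentile).
#'
#' @param run4_maps,run1_maps units x bins rate matrices (same units).
#' @param model_sleep1,model_sleep3 `transition_model`s.
#' @param threshold drift/stable map-correlation cut.
#' @param peak_min Run4 peak-rate inclusion (Hz).
#' @param n_shuffles random sequences per percentile.
#' @return data.frame: group (stable/drift), model (sleep1/sleep3), n_units,
#'   normalized_prob, percentile. Empty groups yield zero rows with a
#'   message.
#' @export
drift_stable_prediction <- function(run4_maps, run1_maps, model_sleep1,
                                    model_sleep3, threshold = 0.3,
                                    peak_min = 2, n_shuffles = 10000) {
  pk <- apply(run4_maps, 1, max, na.rm = TRUE)
  cc <- vapply(seq_len(nrow(run4_maps)), function(i) {
    a <- run1_maps[i, ]; b <- run4_maps[i, ]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 3 || stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
      return(NA_real_)
    }
    stats::cor(a[ok], b[ok])
  }, numeric(1))
  inc <- pk > peak_min & !is.na(cc)
  groups <- list(stable = which(inc & cc > threshold),
                 drift = which(inc & cc < threshold))
  out <- NULL
  for (g in names(groups)) {
    ix <- groups[[g]]
    if (length(ix) < 2) {
      message("group '", g, "' has < 2 units; skipped")
      next
    }
    seq_g <- rownames(run4_maps)[ix][order(apply(run4_maps[ix, , drop = FALSE],
                                                 1, which.max))]
    for (mn in c("sleep1", "sleep3")) {
      model <- if (mn == "sleep1") model_sleep1 else model_sleep3
      seq_use <- seq_g[seq_g %in% model$units]
      if (length(seq_use) < 2) next
      pr <- sequence_probability(model, seq_use)
      sig <- sequence_significance(model, seq_use, n_shuffles)
      out <- rbind(out, data.frame(group = g, model = mn,
                                   n_units = length(seq_use),
                                   normalized_prob = pr$normalized,
                                   percentile = sig$percentile))
    }
  }
  out
}
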