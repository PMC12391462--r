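#' @title Place maps, spatial information, stability and remapping metrics
#' @name place_fields
NULL

gauss_kernel <- function(sigma_bins, radius = ceiling(4 * sigma_bins)) {
  if (sigma_bins <= 0) return(1)
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma_bins^2))
  k / sum(k)
}

smooth_vec <- function(v, kernel) {
  if (length(kernel) == 1) return(v)
  ## convolution with kernel renormalized at the edges (no padding bias)
  n <- length(v)
  num <- stats::convolve(v, rev(kernel), type = "open")
  den <- stats::convolve(rep(1, n), rev(kernel), type = "open")
  r <- (length(kernel) - 1) / 2
  (num / den)[(r + 1):(r + n)]
}

#' Occupancy-normalized place maps
#'
#' Rate = smoothed spike counts / smoothed occupancy on 2 cm bins, computed
#' from velocity-filtered samples (> 10 cm/s). Counts and occupancy are
#' smoothed separately with a Gaussian kernel, then divided. Bins with raw
#' occupancy below `min_occupancy` are masked.
#'
#' @param spikes a `spike_ensemble`.
#' @param trajectory a `trajectory_session`.
#' @param direction optional `"dir1"`/`"dir2"` filter.
#' @param bin_width spatial bin width (cm).
#' @param sigma Gaussian smoothing sd (cm); 0 disables smoothing.
#' @param speed_min velocity filter (cm/s).
#' @param min_occupancy raw-occupancy mask threshold (s).
#' @param lap optional integer lap filter.
#' @return object of class `place_map_set`: `rate` (units x bins, Hz),
#'   `counts`, `occupancy` (s), `valid` mask, `bin_centers`, `segment` label
#'   per bin, plus parameters.
#' @export
compute_place_maps <- function(spikes, trajectory, direction = NULL,
                               bin_width = 2, sigma = 2, speed_min = 10,
                               min_occupancy = 0.1, lap = NULL) {
  keep <- trajectory$velocity > speed_min & trajectory$valid
  if (!is.null(direction)) keep <- keep & trajectory$direction == direction
  if (!is.null(lap)) keep <- keep & trajectory$lap %in% lap
  if (!any(keep)) stop("no running samples")
  tr <- trajectory[keep, , drop = FALSE]
  maze <- attr(trajectory, "maze")
  L <- maze$total_length
  edges <- seq(0, L + bin_width - 1e-9, by = bin_width)
  nb <- length(edges) - 1L
  ctr <- edges[-length(edges)] + bin_width / 2
  dt <- stats::median(diff(trajectory$t))
  occ_raw <- graphics::hist(tr$lin, breaks = edges, plot = FALSE)$counts * dt

  ## spikes are assigned the interpolated position at their time, then gated
  ## by whether the nearest trajectory sample passed the filters
  near <- function(st) findInterval(st, trajectory$t, all.inside = TRUE)
  ids <- unit_ids(spikes)
  counts <- matrix(0, length(ids), nb, dimnames = list(ids, NULL))
  for (i in seq_along(ids)) {
    st <- spikes[[ids[i]]]$times
    if (!length(st)) next
    j <- near(st)
    ok <- keep[j]
    if (!any(ok)) next
    pos <- stats::approx(trajectory$t, trajectory$lin, st[ok], rule = 2)$y
    counts[i, ] <- graphics::hist(pmin(pmax(pos, 0), L - 1e-9),
                                  breaks = edges, plot = FALSE)$counts
  }
  kern <- gauss_kernel(sigma / bin_width)
  occ_s <- smooth_vec(occ_raw, kern)
  rate <- t(apply(counts, 1, function(cc) smooth_vec(cc, kern))) /
    rep(pmax(occ_s, 1e-12), each = length(ids))
  if (length(ids) == 1) rate <- matrix(rate, nrow = 1, dimnames = list(ids, NULL))
  valid <- occ_raw >= min_occupancy
  rate[, !valid] <- NA_real_
  xy_ctr <- lin_to_xy(ctr, maze)
  bin_info <- linearize(xy_ctr[, 1], xy_ctr[, 2], maze)
  structure(list(rate = rate, counts = counts, occupancy = occ_raw,
                 occupancy_smooth = occ_s, valid = valid, bin_centers = ctr,
                 segment = bin_info$segment, track = bin_info$track,
                 track_offsets = maze$offsets,
                 bin_width = bin_width, sigma = sigma,
                 direction = direction),
            class = "place_map_set")
}

#' Spatial information (bits/spike)
#'
#' SI = sum_b p_b (f_b/F) log2(f_b/F) with p_b the occupancy fraction and F
#' the occupancy-weighted mean rate; 0 for a flat map, undefined (NA) when
#' the mean rate is 0.
#'
#' @param rate rate per bin (Hz), NA for masked bins.
#' @param occupancy occupancy per bin (s).
#' @return bits per spike.
#' @export
spatial_information <- function(rate, occupancy) {
  ok <- !is.na(rate) & occupancy > 0
  if (!any(ok)) return(NA_real_)
  p <- occupancy[ok] / sum(occupancy[ok])
  f <- rate[ok]
  F <- sum(p * f)
  if (F <= 0) return(NA_real_)
  r <- f / F
  sum(p * r * log2(ifelse(r > 0, r, 1)))
}

lap_maps <- function(spikes, trajectory, unit, laps, ...) {
  ## single-lap occupancy rarely reaches the session-level 0.1 s mask, so
  ## per-lap maps are computed unmasked unless the caller overrides it
  args <- list(...)
  if (is.null(args$min_occupancy)) args$min_occupancy <- 0
  lapply(laps, function(l) {
    m <- do.call(compute_place_maps,
                 c(list(spikes, trajectory, lap = l), args))
    m$rate[unit, ]
  })
}

#' Within-session place-map stability
#'
#' Laps are randomly bipartitioned; the cosine similarity of the two
#' lap-averaged maps is averaged over `n_repeats` repartitions.
#'
#' @param spikes a `spike_ensemble`.
#' @param trajectory a `trajectory_session` with a `lap` column.
#' @param unit unit id.
#' @param n_repeats number of random bipartitions.
#' @param ... passed to [compute_place_maps()].
#' @return mean split-half cosine similarity.
#' @export
within_session_stability <- function(spikes, trajectory, unit,
                                     n_repeats = 100, ...) {
  if (is.null(trajectory$lap)) stop("trajectory has no lap column")
  laps <- sort(unique(trajectory$lap))
  if (length(laps) < 2) stop("need >= 2 laps")
  maps <- lap_maps(spikes, trajectory, unit, laps, ...)
  M <- do.call(rbind, maps)
  M[is.na(M)] <- 0
  sims <- vapply(seq_len(n_repeats), function(r) {
    g1 <- sample(length(laps), floor(length(laps) / 2))
    a <- colMeans(M[g1, , drop = FALSE])
    b <- colMeans(M[-g1, , drop = FALSE])
    cosine_sim(a, b)
  }, numeric(1))
  mean(sims, na.rm = TRUE)
}

#' Cosine similarity of two vectors
#' @param a,b numeric vectors (NAs pairwise-dropped).
#' @return cosine similarity, NA if either vector has zero norm.
#' @export
cosine_sim <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

shift_cor <- function(a, b, max_shift) {
  best <- NA_real_
  n <- length(a)
  for (s in -max_shift:max_shift) {
    ia <- seq_len(n)
    ib <- ia + s
    ok <- ib >= 1 & ib <= n
    x <- a[ia[ok]]; y <- b[ib[ok]]
    ok2 <- !is.na(x) & !is.na(y)
    if (sum(ok2) < 3) next
    if (stats::sd(x[ok2]) == 0 || stats::sd(y[ok2]) == 0) next
    r <- stats::cor(x[ok2], y[ok2])
    if (is.na(best) || r > best) best <- r
  }
  best
}

#' Per-unit segment-pair place-map similarity vs cell-ID shuffle
#'
#' Pearson correlation of the two segment maps per unit, maximized over
#' spatial shifts of up to `max_shift_bins`, restricted to units with peak
#' rate above `peak_min` on at least one segment, and compared against a
#' cell-ID shuffle where across-segment identities are mismatched.
#'
#' @param maps_A,maps_B units x bins rate matrices (same units; lengths must
#'   match after any resolution matching done by the caller).
#' @param max_shift_bins maximum shift (bins).
#' @param peak_min inclusion threshold on the peak rate (Hz).
#' @param n_shuffle cell-ID shuffles.
#' @param config label recorded in the result.
#' @return list of class `remapping_result`: per-unit `cor`, `shuffle` values,
#'   two-sided rank-sum `p_value` data vs shuffle, `config`.
#' @export
segment_pair_similarity <- function(maps_A, maps_B, max_shift_bins = 2,
                                    peak_min = 2, n_shuffle = 1000,
                                    config = "") {
  if (ncol(maps_A) != ncol(maps_B)) {
    stop("segment lengths/bins differ; match resolution first")
  }
  pk <- pmax(apply(maps_A, 1, max, na.rm = TRUE),
             apply(maps_B, 1, max, na.rm = TRUE))
  inc <- which(pk > peak_min)
  cors <- vapply(inc, function(i) shift_cor(maps_A[i, ], maps_B[i, ],
                                            max_shift_bins), numeric(1))
  shuf <- numeric(0)
  if (length(inc) >= 2) {
    shuf <- vapply(seq_len(n_shuffle), function(s) {
      i <- sample(inc, 1)
      j <- sample(setdiff(inc, i), 1)
      shift_cor(maps_A[i, ], maps_B[j, ], max_shift_bins)
    }, numeric(1))
  }
  p <- if (length(cors) >= 2 && length(shuf) >= 2) {
    stats::wilcox.test(cors, shuf)$p.value
  } else NA_real_
  structure(list(cor = cors, units = inc, shuffle = shuf, p_value = p,
                 n_shuffle = n_shuffle, config = config),
            class = "remapping_result")
}

#' Rebin a rate map to a coarser resolution
#'
#' Used to compare the 150 cm detour segment at 6 cm bins against the 50 cm
#' mobile segment at 2 cm bins so the bin counts match.
#'
#' @param maps units x bins matrix.
#' @param factor integer number of fine bins per coarse bin.
#' @return units x (bins/factor) matrix of bin means.
#' @export
rebin_maps <- function(maps, factor) {
  nb <- floor(ncol(maps) / factor)
  out <- matrix(NA_real_, nrow(maps), nb)
  for (k in seq_len(nb)) {
    out[, k] <- rowMeans(maps[, ((k - 1) * factor + 1):(k * factor),
                              drop = FALSE], na.rm = TRUE)
  }
  rownames(out) <- rownames(maps)
  out
}

#' Population-vector cosine similarity between two map sets
#'
#' PV(b) is the all-unit rate vector at spatial bin b; the output S[i, j] is
#' the cosine similarity between PV_A(i) and PV_B(j). Zero-vector bins are
#' masked (NA).
#'
#' @param maps_A,maps_B units x bins matrices over the same unit registry.
#' @return bins_A x bins_B similarity matrix.
#' @export
population_vector_similarity <- function(maps_A, maps_B) {
  stopifnot(nrow(maps_A) == nrow(maps_B))
  A <- maps_A; B <- maps_B
  A[is.na(A)] <- 0; B[is.na(B)] <- 0
  na <- sqrt(colSums(A^2)); nb <- sqrt(colSums(B^2))
  S <- crossprod(A, B) / outer(na, nb)
  S[na == 0, ] <- NA_real_
  S[, nb == 0] <- NA_real_
  S
}

#' Spearman rank correlation of place-map peak orderings
#'
#' Units are ordered by peak-rate location in the reference maps; the rank
#' correlation against their ordering in the test maps measures sequence
#' preservation.
#'
#' @param maps_ref,maps_test units x bins matrices (same units).
#' @param peak_min inclusion threshold on peak rate (Hz) in both map sets.
#' @return list with `rho`, `p_value`, `n`.
#' @export
sequence_rank_correlation <- function(maps_ref, maps_test, peak_min = 2) {
  pk_r <- apply(maps_ref, 1, max, na.rm = TRUE)
  pk_t <- apply(maps_test, 1, max, na.rm = TRUE)
  inc <- which(pk_r > peak_min & pk_t > peak_min)
  if (length(inc) < 3) return(list(rho = NA_real_, p_value = NA_real_, n = length(inc)))
  pr <- apply(maps_ref[inc, , drop = FALSE], 1, which.max)
  pt <- apply(maps_test[inc, , drop = FALSE], 1, which.max)
  ct <- suppressWarnings(stats::cor.test(pr, pt, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(inc))
}

#' Bidirectionality of a unit's tuning
#'
#' Cosine similarity between the two directional maps of one unit.
#'
#' @param map_dir1,map_dir2 rate vectors for the two running directions.
#' @return cosine similarity in \[0, 1\] for nonnegative maps.
#' @export
bidirectionality <- function(map_dir1, map_dir2) cosine_sim(map_dir1, map_dir2)
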