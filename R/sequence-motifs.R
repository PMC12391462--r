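#' @title First-order Markov sequence model, tuplets and order consistency
#'
#' @description Sleep frames are reduced to unit sequences ordered by the
#' center of mass of each unit's spikes within the frame. A first-order
#' Markov model over unit identities is estimated from those sequences by
#' maximum likelihood; sequence probabilities under the model are compared
#' against same-length random sequences to obtain percentiles. Tuplets are
#' short (2-3 unit) ordered motifs repeated across frames significantly more
#' often than in rate-matched shuffled sleep.
#' @name sequence_motifs
NULL

#' Unit sequence of a frame or theta cycle
#'
#' Units ordered by the center of mass of their spike times within the event;
#' each unit appears once. Center-of-mass ties are broken by unit id.
#'
#' @param ev data.frame with `unit` and `time` columns ([frame_spikes()]).
#' @return character vector of unit ids (length >= 0).
#' @export
frame_sequence <- function(ev) {
  if (!nrow(ev)) return(character(0))
  com <- tapply(ev$time, ev$unit, mean)
  names(com)[order(com, names(com))]
}

#' Fit a first-order Markov transition model from sleep sequences
#'
#' Maximum-likelihood estimates: P2(x_i | x_{i-1}) = n(x_{i-1} x_i) /
#' n(x_{i-1} .), accumulated across frames, and P1(x) = n(x) / N with N the
#' total sequence length. Zero entries of the transition matrix are reset to
#' its minimum non-zero value and ones to its maximum non-one value, so no
#' finite-sample zero annihilates a long-sequence probability.
#'
#' @param seqs list of unit-id character vectors (length >= 2 each counts
#'   toward transitions).
#' @param units unit registry (defaults to the union of sequence members).
#' @return object of class `transition_model`: `P1`, `P2`, `logP1`, `logP2`,
#'   `counts`, `N`, `units`, `clipped` bookkeeping.
#' @export
fit_transition_model <- function(seqs, units = NULL) {
  if (is.null(units)) units <- sort(unique(unlist(seqs)))
  nu <- length(units)
  if (!any(lengths(seqs) >= 2)) stop("no transitions")
  trans <- matrix(0, nu, nu, dimnames = list(units, units))
  n1 <- stats::setNames(numeric(nu), units)
  for (s in seqs) {
    idx <- match(s, units)
    if (anyNA(idx)) stop("sequence references unit outside registry")
    n1[idx] <- n1[idx] + 1
    if (length(idx) >= 2) {
      from <- idx[-length(idx)]; to <- idx[-1]
      for (k in seq_along(from)) trans[from[k], to[k]] <- trans[from[k], to[k]] + 1
    }
  }
  N <- sum(n1)
  rs <- rowSums(trans)
  P2 <- trans / ifelse(rs > 0, rs, 1)
  clip <- clip_probs(P2)
  P1 <- n1 / N
  if (any(P1 == 0) && any(P1 > 0)) P1[P1 == 0] <- min(P1[P1 > 0])
  P1 <- P1
  structure(list(P1 = P1, P2 = clip$P, logP1 = log(P1), logP2 = log(clip$P),
                 counts = trans, n1 = n1, N = N, units = units,
                 clipped = clip$record),
            class = "transition_model")
}

clip_probs <- function(P) {
  nz <- P[P > 0]
  record <- list(n_zero = sum(P == 0), n_one = sum(P == 1),
                 min_nonzero = NA_real_, max_nonone = NA_real_)
  if (length(nz)) {
    record$min_nonzero <- min(nz)
    P[P == 0] <- record$min_nonzero
  }
  no <- P[P < 1]
  if (any(P == 1) && length(no)) {
    record$max_nonone <- max(no)
    P[P == 1] <- record$max_nonone
  }
  list(P = P, record = record)
}

#' Probability of a sequence under the Markov model
#'
#' Pr(x) = P1(x_1) * prod_{i=2}^{n} P2(x_i | x_{i-1}), accumulated in log
#' space; the normalized probability is the geometric mean Pr^(1/n).
#'
#' @param model a `transition_model`.
#' @param seq unit-id character vector.
#' @param normalized return the geometric-mean-normalized probability too.
#' @return list: `prob`, `log_prob` (natural log), `normalized`.
#' @export
sequence_probability <- function(model, seq, normalized = TRUE) {
  idx <- match(seq, model$units)
  if (anyNA(idx)) stop("sequence references unit outside model support")
  lp <- model$logP1[idx[1]]
  if (length(idx) >= 2) {
    lp <- lp + sum(model$logP2[cbind(idx[-length(idx)], idx[-1])])
  }
  lp <- unname(lp)
  list(prob = exp(lp), log_prob = lp,
       normalized = if (normalized) exp(lp / length(idx)) else NULL)
}

seq_logprob_matrix <- function(model, mat) {
  ## mat: rows are sequences of unit indices (same length)
  lp <- model$logP1[mat[, 1]]
  if (ncol(mat) >= 2) {
    for (k in 2:ncol(mat)) {
      lp <- lp + model$logP2[cbind(mat[, k - 1], mat[, k])]
    }
  }
  unname(lp)
}

random_seq_matrix <- function(nu, len, n) {
  t(vapply(seq_len(n), function(i) sample.int(nu, len), integer(len)))
}

#' Shuffle-percentile significance of a sequence
#'
#' The sequence's probability is ranked against `n_shuffles` uniformly random
#' unit sequences of the same length (without within-sequence repeats,
#' matching the one-appearance-per-unit structure of frame sequences).
#' Significant if above the 95th percentile.
#'
#' @param model a `transition_model`.
#' @param seq unit-id character vector.
#' @param n_shuffles number of random comparison sequences.
#' @return list: `percentile` (0-100), `significant` (> 95), `log_prob`.
#' @export
sequence_significance <- function(model, seq, n_shuffles = 10000) {
  lp <- sequence_probability(model, seq, normalized = FALSE)$log_prob
  mat <- random_seq_matrix(length(model$units), length(seq), n_shuffles)
  sh <- seq_logprob_matrix(model, mat)
  pct <- 100 * mean(sh < lp)
  list(percentile = pct, significant = pct > 95, log_prob = lp)
}

#' Batch shuffle-percentile significance
#'
#' Vectorized evaluation for many sequences: sequences are processed in
#' chunks; within a chunk one freshly drawn pool of `n_shuffles` random
#' sequences per distinct length serves every sequence of that length.
#'
#' @param model a `transition_model`.
#' @param seqs list of unit-id character vectors.
#' @param n_shuffles random sequences per length per chunk.
#' @param chunk sequences per chunk (pool regeneration interval).
#' @return data.frame: `length`, `log_prob`, `percentile`, `significant`.
#' @export
sequence_significance_batch <- function(model, seqs, n_shuffles = 10000,
                                        chunk = 100) {
  nu <- length(model$units)
  lens <- lengths(seqs)
  lp <- vapply(seqs, function(s) {
    sequence_probability(model, s, normalized = FALSE)$log_prob
  }, numeric(1))
  pct <- numeric(length(seqs))
  idx_chunks <- split(seq_along(seqs), (seq_along(seqs) - 1) %/% chunk)
  for (ch in idx_chunks) {
    for (L in unique(lens[ch])) {
      pool <- sort(seq_logprob_matrix(model, random_seq_matrix(nu, L, n_shuffles)))
      sel <- ch[lens[ch] == L]
      pct[sel] <- 100 * findInterval(lp[sel] - 1e-12, pool) / n_shuffles
    }
  }
  data.frame(length = lens, log_prob = lp, percentile = pct,
             significant = pct > 95)
}

#' Cell-ID shuffle of a transition model
#'
#' Permutes unit identities in both P1 and P2, destroying any correspondence
#' between the model and a particular sequence while preserving the model's
#' value distribution.
#'
#' @param model a `transition_model`.
#' @return a `transition_model` with permuted unit identities.
#' @export
shuffle_model_ids <- function(model) {
  p <- sample.int(length(model$units))
  m <- model
  m$P1 <- stats::setNames(model$P1[p], model$units)
  m$logP1 <- log(m$P1)
  m$P2 <- model$P2[p, p]
  dimnames(m$P2) <- list(model$units, model$units)
  m$logP2 <- log(m$P2)
  m
}

#' Fraction of theta cycles predicted by a sleep model
#'
#' Each cycle's sequence percentile is computed with
#' [sequence_significance_batch()]; the significant fraction (> 95th
#' percentile) is tested against the 5% chance level with a one-sided
#' binomial test.
#'
#' @param model a `transition_model` (fit on selected sleep frames).
#' @param cycle_seqs list of cycle unit sequences (> 3 active units each).
#' @param n_shuffles random sequences per cycle.
#' @param chance chance level.
#' @return list: `fraction`, `n`, `p_value`, `percentiles`.
#' @export
predict_theta_cycles <- function(model, cycle_seqs, n_shuffles = 10000,
                                 chance = 0.05) {
  res <- sequence_significance_batch(model, cycle_seqs, n_shuffles)
  x <- sum(res$significant)
  n <- nrow(res)
  bt <- stats::binom.test(x, n, chance, alternative = "greater")
  list(fraction = x / n, n = n, p_value = bt$p.value,
       percentiles = res$percentile)
}

sub_sequences <- function(s, len, contiguous = TRUE) {
  n <- length(s)
  if (n < len) return(character(0))
  if (contiguous) {
    vapply(seq_len(n - len + 1), function(i) {
      paste(s[i:(i + len - 1)], collapse = "|")
    }, character(1))
  } else {
    cmb <- utils::combn(n, len)
    apply(cmb, 2, function(ix) paste(s[ix], collapse = "|"))
  }
}

count_subseqs <- function(seqs, lens, contiguous) {
  tab <- table(unlist(lapply(seqs, function(s) {
    unlist(lapply(lens, sub_sequences, s = s, contiguous = contiguous))
  })))
  if (!length(tab)) return(stats::setNames(integer(0), character(0)))
  tab
}

shuffle_sleep <- function(seqs, units, weights) {
  lapply(seqs, function(s) {
    k <- length(s)
    units[sample.int(length(units), k, prob = weights)]
  })
}

#' Extract significantly repeated tuplets from sleep frames
#'
#' All contiguous ordered 2- and 3-unit sub-sequences of the frames' unit
#' orders with at least two repeats are candidates. Shuffled sleeps preserve
#' the per-frame unit count and sample units without replacement weighted by
#' each unit's overall frame participation, destroying order and co-firing.
#' A candidate is a tuplet if its repeat count exceeds the 95th percentile of
#' its counts across the shuffled sleeps. Reversed orders are independently
#' eligible.
#'
#' @param frame_seqs list of frame unit sequences.
#' @param n_shuffle_sleeps number of shuffled sleeps.
#' @param contiguous contiguous sub-sequences only (default) or all ordered
#'   sub-sequences.
#' @param n_keep_shuffle_sets how many shuffle sleeps to also score for
#'   tuplets (for recruitment controls).
#' @return list of class `tuplet_set`: data.frame `tuplets` (`id`, `length`,
#'   `count`, `shuffle_q95`, `significant`) and `shuffle_tuplets` (list of
#'   tuplet-id sets from scored shuffle sleeps).
#' @export
extract_tuplets <- function(frame_seqs, n_shuffle_sleeps = 500,
                            contiguous = TRUE, n_keep_shuffle_sets = 0) {
  empty <- structure(list(
    tuplets = data.frame(id = character(0), length = integer(0),
                         count = integer(0), shuffle_q95 = numeric(0),
                         significant = logical(0)),
    shuffle_tuplets = list()), class = "tuplet_set")
  if (!length(frame_seqs)) return(empty)
  units <- sort(unique(unlist(frame_seqs)))
  w <- table(factor(unlist(frame_seqs), levels = units))
  obs <- count_subseqs(frame_seqs, 2:3, contiguous)
  cand <- names(obs)[obs >= 2]
  if (!length(cand)) return(empty)
  sh_counts <- matrix(0L, length(cand), n_shuffle_sleeps,
                      dimnames = list(cand, NULL))
  sh_seqs_kept <- vector("list", n_keep_shuffle_sets)
  for (b in seq_len(n_shuffle_sleeps)) {
    ss <- shuffle_sleep(frame_seqs, units, as.numeric(w))
    tab <- count_subseqs(ss, 2:3, contiguous)
    hit <- intersect(cand, names(tab))
    sh_counts[hit, b] <- as.integer(tab[hit])
    if (b <= n_keep_shuffle_sets) sh_seqs_kept[[b]] <- ss
  }
  q95 <- apply(sh_counts, 1, stats::quantile, probs = 0.95, names = FALSE)
  tuplets <- data.frame(id = cand,
                        length = lengths(strsplit(cand, "|", fixed = TRUE)),
                        count = as.integer(obs[cand]),
                        shuffle_q95 = q95,
                        significant = as.integer(obs[cand]) > q95,
                        stringsAsFactors = FALSE)
  shuffle_tuplets <- lapply(sh_seqs_kept, function(ss) {
    tab <- count_subseqs(ss, 2:3, contiguous)
    cc <- names(tab)[tab >= 2]
    if (!length(cc)) return(character(0))
    keep <- vapply(cc, function(id) {
      ref <- if (id %in% cand) sh_counts[id, ] else rep(0L, n_shuffle_sleeps)
      tab[id] > stats::quantile(ref, 0.95, names = FALSE)
    }, logical(1))
    cc[keep]
  })
  structure(list(tuplets = tuplets, shuffle_tuplets = shuffle_tuplets),
            class = "tuplet_set")
}

#' Recruitment of sleep tuplets into theta cycles
#'
#' The fraction of the cycles' 2/3-unit sub-sequences that are significant
#' sleep tuplets, compared with the fractions obtained from shuffle-sleep
#' tuplet sets.
#'
#' @param tuplet_set a `tuplet_set` from [extract_tuplets()].
#' @param cycle_seqs list of theta-cycle unit sequences.
#' @param contiguous match the extraction convention.
#' @return list: `recruited_fraction`, `n_candidates`, `shuffle_fractions`.
#' @export
tuplet_recruitment <- function(tuplet_set, cycle_seqs, contiguous = TRUE) {
  cyc <- unlist(lapply(cycle_seqs, function(s) {
    unlist(lapply(2:3, sub_sequences, s = s, contiguous = contiguous))
  }))
  if (!length(cyc)) {
    return(list(recruited_fraction = 0, n_candidates = 0,
                shuffle_fractions = numeric(0)))
  }
  sig <- tuplet_set$tuplets$id[tuplet_set$tuplets$significant]
  frac <- mean(cyc %in% sig)
  shf <- vapply(tuplet_set$shuffle_tuplets, function(ts) mean(cyc %in% ts),
                numeric(1))
  list(recruited_fraction = frac, n_candidates = length(cyc),
       shuffle_fractions = shf)
}

#' Antisymmetric pairwise order-probability matrix
#'
#' P\[i, j\] = (frames where both i and j are active and i's center of mass
#' precedes j's) / (frames where both are active); P\[j, i\] = 1 - P\[i, j\].
#' NA where a pair never co-occurs.
#'
#' @param seqs list of frame unit sequences.
#' @param units unit registry (default union of members).
#' @return units x units matrix with attribute `n_co` (co-occurrence counts).
#' @export
pairwise_order_matrix <- function(seqs, units = NULL) {
  if (is.null(units)) units <- sort(unique(unlist(seqs)))
  nu <- length(units)
  before <- matrix(0, nu, nu, dimnames = list(units, units))
  both <- matrix(0, nu, nu, dimnames = list(units, units))
  for (s in seqs) {
    idx <- match(s, units)
    if (length(idx) < 2) next
    ord <- outer(seq_along(idx), seq_along(idx), "<")
    before[idx, idx] <- before[idx, idx] + ord
    both[idx, idx] <- both[idx, idx] + (ord | t(ord))
  }
  P <- before / ifelse(both > 0, both, NA)
  diag(P) <- NA
  attr(P, "n_co") <- both
  P
}

#' Mean order-probability score of cycles against a sleep order matrix
#'
#' For each cycle, the observed ordered pairs are looked up in the order
#' matrix; the score is the mean probability minus the 0.5 chance level.
#'
#' @param P order matrix from [pairwise_order_matrix()].
#' @param cycle_seqs list of cycle unit sequences.
#' @return list: `score` (mean prob - 0.5 over all pairs), `mean_prob`,
#'   `per_cycle` scores, `n_pairs`.
#' @export
score_cycle_orders <- function(P, cycle_seqs) {
  units <- rownames(P)
  all_p <- c(); per <- rep(NA_real_, length(cycle_seqs))
  for (k in seq_along(cycle_seqs)) {
    idx <- match(cycle_seqs[[k]], units)
    idx <- idx[!is.na(idx)]
    if (length(idx) < 2) next
    pr <- utils::combn(seq_along(idx), 2)
    v <- P[cbind(idx[pr[1, ]], idx[pr[2, ]])]
    v <- v[!is.na(v)]
    if (!length(v)) next
    per[k] <- mean(v) - 0.5
    all_p <- c(all_p, v)
  }
  list(score = mean(all_p) - 0.5, mean_prob = mean(all_p), per_cycle = per,
       n_pairs = length(all_p))
}

#' Rank-order correlation between frame and cycle sequences
#'
#' For every frame-cycle pair with at least `min_common` common active units
#' (guaranteeing factorial(min_common) independent orderings), the Spearman
#' correlation of the common units' orderings is compared with `n_perm`
#' permutations; a pair is significant if its correlation exceeds 95% of the
#' permutations. The significant fraction is reported against the 5% chance
#' level.
#'
#' @param frame_seqs,cycle_seqs lists of unit sequences.
#' @param min_common minimum common active units.
#' @param n_perm permutations per pair.
#' @return list: `fraction_significant`, `n_pairs`, `pairs` data.frame,
#'   `p_value` (one-sided binomial vs 5%), `min_orderings`.
#' @export
frame_cycle_rank_correlation <- function(frame_seqs, cycle_seqs,
                                         min_common = 5, n_perm = 500) {
  rows <- NULL
  for (i in seq_along(frame_seqs)) {
    for (j in seq_along(cycle_seqs)) {
      common <- intersect(frame_seqs[[i]], cycle_seqs[[j]])
      if (length(common) < min_common) next
      r1 <- match(common, frame_seqs[[i]])
      r2 <- match(common, cycle_seqs[[j]])
      rho <- stats::cor(r1, r2, method = "spearman")
      perm <- vapply(seq_len(n_perm), function(b) {
        stats::cor(r1, sample(r2), method = "spearman")
      }, numeric(1))
      rows <- rbind(rows, data.frame(
        frame = i, cycle = j, n_common = length(common), rho = rho,
        significant = rho > stats::quantile(perm, 0.95, names = FALSE)))
    }
  }
  if (is.null(rows)) {
    return(list(fraction_significant = NA_real_, n_pairs = 0, pairs = NULL,
                p_value = NA_real_, min_orderings = factorial(min_common)))
  }
  x <- sum(rows$significant); n <- nrow(rows)
  bt <- stats::binom.test(x, n, 0.05, alternative = "greater")
  list(fraction_significant = x / n, n_pairs = n, pairs = rows,
       p_value = bt$p.value, min_orderings = factorial(min_common))
}
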