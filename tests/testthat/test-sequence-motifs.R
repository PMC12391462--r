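test_that("frame sequences order units by center of mass with id tie-break", {
  ev <- data.frame(unit = c("b", "a", "b", "c"),
                   time = c(0.1, 0.2, 0.3, 0.15))
  # com: b = 0.2, a = 0.2, c = 0.15 -> c first, then a before b by id
  expect_identical(frame_sequence(ev), c("c", "a", "b"))
  expect_identical(frame_sequence(ev[0, ]), character(0))
})

test_that("transition-model counts follow maximum likelihood with clipping", {
  m <- fit_transition_model(list(c("A", "B"), c("A", "C")))
  expect_equal(m$P2["A", "B"], 0.5)
  expect_equal(m$P2["A", "C"], 0.5)
  expect_equal(sum(m$P1), 1)
  # single repeated pair: P2(B|A) = 1 stays 1 when no non-one value exists
  m2 <- fit_transition_model(rep(list(c("A", "B")), 10), units = c("A", "B"))
  expect_equal(m2$P2["A", "B"], 1)
  expect_true(is.na(m2$clipped$max_nonone) || m2$clipped$max_nonone < 1)
  # zero entries are reset to the minimum non-zero value
  m3 <- fit_transition_model(list(c("A", "B"), c("B", "C"), c("A", "B")))
  expect_gt(min(m3$P2), 0)
  expect_error(fit_transition_model(list("A", "B")), "no transitions")
})

test_that("planted Markov chains are recovered from many frames", {
  units <- sprintf("u%02d", 1:12)
  # ring chain: each unit strongly prefers its successor
  set.seed(20)
  seqs <- replicate(2000, {
    start <- sample(12, 1)
    len <- sample(4:8, 1)
    idx <- ((start + 0:(len - 1) - 1) %% 12) + 1
    # occasional random transposition keeps transitions off the boundary
    if (runif(1) < 0.3) idx <- sample(idx)
    units[idx]
  }, simplify = FALSE)
  m <- fit_transition_model(seqs, units)
  succ <- m$P2[cbind(1:12, c(2:12, 1))]
  truth_succ <- mean(succ)
  expect_gt(truth_succ, 0.5)
  off <- m$P2[cbind(1:12, c(3:12, 1, 2))]
  expect_lt(mean(off), truth_succ)
})

test_that("sequence probability matches a naive product oracle to 1e-12", {
  set.seed(21)
  units <- sprintf("u%02d", 1:15)
  seqs <- replicate(100, sample(units, sample(3:8, 1)), simplify = FALSE)
  m <- fit_transition_model(seqs, units)
  for (r in 1:20) {
    s <- sample(units, 6)
    got <- sequence_probability(m, s)
    naive <- log(m$P1[s[1]])
    for (k in 2:6) naive <- naive + log(m$P2[s[k - 1], s[k]])
    expect_lt(abs(got$log_prob - unname(naive)), 1e-12)
    expect_equal(got$normalized, exp(got$log_prob / 6), tolerance = 1e-12)
  }
  # toy values: P1(A) = 0.5, P2(B|A) = 0.5 -> Pr([A,B]) = 0.25, norm = 0.5
  mt <- fit_transition_model(list(c("A", "B"), c("A", "C")),
                             units = c("A", "B", "C"))
  expect_equal(mt$P1[["A"]], 0.5)
  pr <- sequence_probability(mt, c("A", "B"))
  expect_equal(pr$prob, 0.25)
  expect_equal(pr$normalized, 0.5)
  # length-1 sequence reduces to P1
  expect_equal(sequence_probability(mt, "A")$prob, 0.5)
})

test_that("random sequences earn uniform percentiles; planted chains exceed 95", {
  set.seed(22)
  units <- sprintf("u%02d", 1:20)
  seqs <- replicate(400, sample(units, sample(4:8, 1)), simplify = FALSE)
  m <- fit_transition_model(seqs, units)
  pct <- replicate(200, {
    sequence_significance(m, sample(units, 5), n_shuffles = 400)$percentile
  })
  frac_sig <- mean(pct > 95)
  expect_gt(frac_sig, 0.01)
  expect_lt(frac_sig, 0.12)
  # a planted high-probability chain scores above the 95th percentile
  chain <- replicate(300, units[1:6], simplify = FALSE)
  mc <- fit_transition_model(c(seqs, chain), units)
  expect_gt(sequence_significance(mc, units[1:6], 2000)$percentile, 95)
})

test_that("batch significance equals the single-sequence evaluator's ranks", {
  set.seed(23)
  units <- sprintf("u%02d", 1:15)
  m <- fit_transition_model(replicate(200, sample(units, 6),
                                      simplify = FALSE), units)
  cyc <- replicate(50, sample(units, sample(4:6, 1)), simplify = FALSE)
  res <- sequence_significance_batch(m, cyc, n_shuffles = 4000)
  lp <- vapply(cyc, function(s) sequence_probability(m, s)$log_prob,
               numeric(1))
  expect_equal(res$log_prob, lp)
  expect_true(all(res$percentile >= 0 & res$percentile <= 100))
})

test_that("theta-cycle prediction hits its ceiling and its chance floor", {
  set.seed(24)
  units <- sprintf("u%02d", 1:20)
  cyc <- replicate(150, units[sort(sample(1:8, 5))], simplify = FALSE)
  m_self <- fit_transition_model(cyc, units)
  self_pred <- predict_theta_cycles(m_self, cyc, n_shuffles = 2000)
  expect_gt(self_pred$fraction, 0.5)        # self-consistency ceiling
  # cell-ID shuffled model falls to the 5% chance level
  shuf_pred <- predict_theta_cycles(shuffle_model_ids(m_self),
                                    replicate(400, sample(units, 5),
                                              simplify = FALSE),
                                    n_shuffles = 2000)
  se <- sqrt(0.05 * 0.95 / 400)
  expect_lt(abs(shuf_pred$fraction - 0.05), 4 * se)
})

test_that("tuplet extraction finds planted motifs and enumerates candidates", {
  set.seed(25)
  units <- sprintf("u%02d", 1:20)
  # 50 frames each containing A -> B in order plus random background
  frames <- replicate(50, {
    bg <- sample(units[3:20], 4)
    c("u01", "u02", bg)
  }, simplify = FALSE)
  ts <- extract_tuplets(frames, n_shuffle_sleeps = 150)
  tab <- ts$tuplets
  expect_true(tab$significant[tab$id == "u01|u02"])
  rev_row <- tab[tab$id == "u02|u01", ]
  expect_true(nrow(rev_row) == 0 || !rev_row$significant)
  # candidate enumeration: [A,B,C] twice yields the three contiguous motifs
  ts2 <- extract_tuplets(rep(list(c("A", "B", "C")), 2),
                         n_shuffle_sleeps = 50)
  expect_setequal(ts2$tuplets$id, c("A|B", "B|C", "A|B|C"))
  expect_identical(nrow(extract_tuplets(list(), 10)$tuplets), 0L)
})

test_that("order-free sleep yields about 5% significant tuplets", {
  # enough frames that candidate motifs have expected counts of order one;
  # below that regime the two-repeat candidate gate conditions on outliers
  # and inflates the apparent significance of 3-unit motifs
  set.seed(26)
  units <- sprintf("u%02d", 1:15)
  frames <- replicate(600, sample(units, sample(5:8, 1)), simplify = FALSE)
  ts <- extract_tuplets(frames, n_shuffle_sleeps = 200)
  tab <- ts$tuplets
  expect_lt(mean(tab$significant[tab$length == 2]), 0.15)
  expect_lt(mean(tab$significant), 0.20)
})

test_that("tuplet recruitment separates template cycles from independent ones", {
  set.seed(27)
  units <- sprintf("u%02d", 1:20)
  frames <- replicate(60, {
    c(units[1:4], sample(units[5:20], 3))
  }, simplify = FALSE)
  ts <- extract_tuplets(frames, n_shuffle_sleeps = 150,
                        n_keep_shuffle_sets = 20)
  cyc_tpl <- replicate(30, c(units[1:4], sample(units[5:20], 2)),
                       simplify = FALSE)
  rec <- tuplet_recruitment(ts, cyc_tpl)
  expect_gt(rec$recruited_fraction, max(rec$shuffle_fractions))
  cyc_ind <- replicate(30, sample(units, 6), simplify = FALSE)
  rec0 <- tuplet_recruitment(ts, cyc_ind)
  expect_lt(rec0$recruited_fraction,
            mean(rec$shuffle_fractions) + 3 * stats::sd(rec$shuffle_fractions)
            + 0.05)
  expect_equal(tuplet_recruitment(ts, list())$recruited_fraction, 0)
})

test_that("pairwise order matrix is antisymmetric and scores match chance", {
  om <- pairwise_order_matrix(list(c("A", "B"), c("A", "B"), c("B", "C")))
  expect_equal(om["A", "B"], 1)
  expect_equal(om["B", "A"], 0)
  # antisymmetry P(i, j) + P(j, i) = 1 on observed pairs
  set.seed(28)
  units <- sprintf("u%02d", 1:12)
  seqs <- replicate(150, sample(units, sample(4:8, 1)), simplify = FALSE)
  P <- pairwise_order_matrix(seqs, units)
  obs <- which(!is.na(P) & !is.na(t(P)), arr.ind = TRUE)
  expect_true(all(abs(P[obs] + t(P)[obs] - 1) < 1e-12))
  # random orders score at the 50% chance level
  cycles <- replicate(800, sample(units, 5), simplify = FALSE)
  sc <- score_cycle_orders(P, cycles)
  expect_lt(abs(sc$mean_prob - 0.5), 0.02)
  # consistent ordering sleep -> run scores positive
  ordered <- replicate(100, units[sort(sample(1:12, 6))], simplify = FALSE)
  Po <- pairwise_order_matrix(ordered, units)
  sco <- score_cycle_orders(Po, replicate(50, units[sort(sample(1:12, 5))],
                                          simplify = FALSE))
  expect_gt(sco$score, 0.2)
})

test_that("frame-cycle rank correlation gates on common units and calibrates", {
  units <- sprintf("u%02d", 1:10)
  # identical orderings: significant, with the analytic permutation floor
  r <- frame_cycle_rank_correlation(list(units[1:6]), list(units[1:6]),
                                    n_perm = 300)
  expect_equal(r$n_pairs, 1)
  expect_true(r$pairs$significant[1])
  expect_equal(r$min_orderings, 120)
  # fewer than 5 common units: pair excluded
  r2 <- frame_cycle_rank_correlation(list(units[1:4]), list(units[1:4]))
  expect_equal(r2$n_pairs, 0)
  # independent orders: significant fraction near 5%
  set.seed(29)
  fs <- replicate(12, sample(units, 7), simplify = FALSE)
  cs <- replicate(12, sample(units, 7), simplify = FALSE)
  r3 <- frame_cycle_rank_correlation(fs, cs, n_perm = 200)
  expect_lt(r3$fraction_significant, 0.2)
})
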