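test_that("quadrant ratio has its closed-form values and scale invariance", {
  x <- seq(-40, 40, 10)
  Q <- matrix(0, length(x), 4)
  Q[x > 0, 3:4] <- 1                     # all mass ahead, late half = Q1
  expect_equal(quadrant_ratio(Q, x = x, current_x = 0), 1)
  expect_equal(quadrant_ratio(matrix(1, 9, 4), x = x, current_x = 0), 0)
  # toy quadrant masses (0.4, 0.1, 0.4, 0.1)
  Q2 <- matrix(0, 2, 2)
  x2 <- c(-10, 10)
  Q2[2, 2] <- 0.4; Q2[1, 1] <- 0.4; Q2[2, 1] <- 0.1; Q2[1, 2] <- 0.1
  expect_equal(quadrant_ratio(Q2, x = x2, current_x = 0), 0.6)
  expect_equal(quadrant_ratio(5 * Q2, x = x2, current_x = 0), 0.6)
  # direction flip mirrors the spatial axis: the same posterior reads as a
  # reverse sweep, and mirroring the posterior restores the forward reading
  expect_equal(quadrant_ratio(Q2, x = x2, current_x = 0, direction = -1), -0.6)
  expect_equal(quadrant_ratio(Q2[2:1, ], x = x2, current_x = 0,
                              direction = -1), 0.6)
  # all mass outside the window: cycle dropped
  expect_true(is.na(quadrant_ratio(Q2, x = c(-100, 100), current_x = 0)))
})

test_that("theta sequences are detected on generated runs, not on symmetric nulls", {
  run <- fix_run()
  qt <- theta_cycle_quadrants(run, run$maps)
  expect_gt(nrow(qt), 50)
  ts <- theta_sequence_test(qt$qr, alpha = 0.01)
  expect_true(ts$significant)
  expect_gt(ts$median, 0)
  set.seed(11)
  sym <- c(rnorm(200, 0, 0.3))
  expect_false(theta_sequence_test(sym - stats::median(sym), 0.01)$significant)
})

test_that("column-shuffled cycles reject at no more than the nominal rate", {
  set.seed(12)
  sc <- synthetic_cycle_posteriors(1500)
  cal <- qr_shuffle_calibration(sc$posteriors, sc$x, n_subpop = 200,
                                subpop_size = 150, alpha = 0.05)
  se <- sqrt(0.05 * 0.95 / 200)
  expect_lte(cal$fpr, 0.05 + 3 * se)
})

test_that("phase locking detects concentration and respects uniformity", {
  set.seed(13)
  tight <- rep(1.2, 50) + rnorm(50, 0, 0.05)
  pl <- phase_locking(tight)
  expect_lt(pl$p_value, 1e-6)
  expect_lt(abs(pl$preferred_phase - 1.2), 20 * pi / 180)
  unif <- runif(200, 0, 2 * pi)
  expect_gt(phase_locking(unif)$p_value, 0.05)
  # von Mises kappa = 1 sample, n = 200 (rejection sampler as oracle)
  rvm <- function(n, mu, kappa) {
    out <- numeric(0)
    while (length(out) < n) {
      th <- runif(n, 0, 2 * pi)
      keep <- runif(n) < exp(kappa * (cos(th - mu) - 1))
      out <- c(out, th[keep])
    }
    out[1:n]
  }
  vm <- rvm(200, 4.0, 1)
  plv <- phase_locking(vm)
  expect_lt(plv$p_value, 0.05)
  # the circular mean is the precise location estimate at this concentration;
  # the 20-degree histogram peak is coarser
  rm_d <- abs(rayleigh_test(vm)$mean_phase - 4.0)
  expect_lt(min(rm_d, 2 * pi - rm_d), 20 * pi / 180)
  d <- abs(plv$preferred_phase - 4.0)
  expect_lt(min(d, 2 * pi - d), 45 * pi / 180)
})

test_that("phase precession is found in generated fields and not in nulls", {
  # perfectly linear phase decrease
  pos <- seq(0, 1, length.out = 50)
  expect_equal(phase_precession(5 - 3 * pos, pos)$r, -1)
  run <- fix_run()
  tp <- theta_phase(run$lfp)
  traj <- run$trajectory
  # precession advances with distance traveled into the field, so the
  # in-field coordinate is oriented by the running direction before pooling
  dirof <- function(tt) {
    traj$direction[pmin(pmax(findInterval(tt, traj$t), 1), nrow(traj))]
  }
  ctr <- run$truth$centers
  sig <- 0; n <- 0
  for (i in seq_len(run$spec$n_units)) {
    st <- run$spikes[[i]]$times
    d <- dirof(st)
    pos_i <- stats::approx(traj$t, traj$lin, st, rule = 2)$y
    s <- run$spec$field_sigma
    infield <- abs(pos_i - ctr[i]) < 2 * s
    pn <- ifelse(d == "dir1", (pos_i - (ctr[i] - 2 * s)) / (4 * s),
                 ((ctr[i] + 2 * s) - pos_i) / (4 * s))
    if (sum(infield) < 30) next
    pp <- phase_precession(phase_at(tp, st[infield]), pn[infield])
    n <- n + 1
    if (pp$p_value < 0.05 && pp$r < 0) sig <- sig + 1
  }
  expect_gte(sig / n, 0.8)
  # no-coupling null: mean |r| small
  set.seed(14)
  rs <- replicate(50, phase_precession(runif(80, 0, 2 * pi), runif(80))$r)
  expect_lt(mean(abs(rs)), 0.15)
})

test_that("jittering is identity at zero and uniform at 50 ms", {
  tt <- sort(runif(500, 0, 100))
  expect_identical(jitter_spikes(tt, 0), tt)
  set.seed(15)
  j <- jitter_spikes(tt, 0.05)
  d <- j - tt
  expect_gt(stats::ks.test(d, "punif", -0.05, 0.05)$p.value, 0.05)
  # ensemble jitter preserves mean rates
  run <- fix_run()
  je <- jitter_ensemble(run$spikes, 0.075)
  expect_identical(vapply(je, function(u) length(u$times), integer(1)),
                   vapply(run$spikes, function(u) length(u$times), integer(1)))
})

test_that("theta-sequence strength collapses under spike-time jitter", {
  # jitter wider than half a theta cycle removes the phase-coded sweep; a
  # small residual sweep from the animal's own movement within each cycle
  # (~4 cm at 30 cm/s) keeps the jittered quadrant ratio slightly above zero,
  # so the tested property is the collapse of the effect size
  run <- fix_run()
  grid <- c(0, 0.035, 0.075)
  set.seed(16)
  med <- vapply(grid, function(h) {
    r <- run
    r$spikes <- jitter_ensemble(run$spikes, h)
    qt <- theta_cycle_quadrants(r, run$maps)
    stats::median(qt$qr, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(med) < 0))
  expect_gt(med[1], 2 * med[3])
})

test_that("CCG temporal bias is exactly antisymmetric and reads lag structure", {
  set.seed(18)
  ti <- seq(0.5, 290, by = 1)                  # sparse, regular events
  tj <- ti + 0.05                              # j always fires 50 ms after i
  b <- ccg_bias(ti, tj, window = 0.2)
  expect_equal(b$bias, 0.05)
  # antisymmetry holds exactly for arbitrary trains
  ta <- sort(runif(200, 0, 100)); tb <- sort(runif(180, 0, 100))
  expect_identical(ccg_bias(ta, tb, 0.2)$bias, -ccg_bias(tb, ta, 0.2)$bias)
  # independent Poisson pairs: bias near zero on average
  biases <- replicate(30, {
    a <- sort(runif(150, 0, 100)); b2 <- sort(runif(150, 0, 100))
    ccg_bias(a, b2, 0.2)$bias
  })
  expect_lt(abs(mean(biases)), 0.01)
})

test_that("compressed CCG bias sign matches the field order within a direction", {
  # tuning is bidirectional, so the temporal order of a pair flips with the
  # running direction; the bias is therefore computed per direction
  run <- fix_run()
  traj <- run$trajectory
  dir1 <- function(tt) {
    traj$direction[pmin(pmax(findInterval(tt, traj$t), 1), nrow(traj))] ==
      "dir1"
  }
  ctr <- run$truth$centers
  ord <- order(ctr)
  # pairs with overlapping fields (4-20 cm apart), as the method prescribes
  pairs <- NULL
  for (a in 1:39) {
    for (b in (a + 1):40) {
      dc <- ctr[ord[b]] - ctr[ord[a]]
      if (dc >= 4 && dc <= 20) pairs <- rbind(pairs, c(ord[a], ord[b]))
    }
  }
  sgn <- apply(pairs, 1, function(pr) {
    ti <- run$spikes[[pr[1]]]$times; tj <- run$spikes[[pr[2]]]$times
    b <- ccg_bias(ti[dir1(ti)], tj[dir1(tj)], 0.2)
    if (b$n_pairs < 50) NA else sign(b$bias)
  })
  expect_gt(mean(sgn > 0, na.rm = TRUE), 0.8)
  cc <- ccg_curve(run$spikes[[pairs[1, 1]]]$times,
                  run$spikes[[pairs[1, 2]]]$times,
                  window = 1, bin = 0.01, lp_cutoff = 30)
  expect_length(cc$curve, length(cc$lag))
})

test_that("theta sequences become significant before replay in a seeded scenario", {
  set.seed(19)
  # cycles express sequences from lap 1
  cycles <- data.frame(time = sort(runif(300, 0, 600)),
                       qr = rnorm(300, 0.25, 0.3))
  cycles$lap <- ceiling(cycles$time / 100)
  # waking-rest frames: incoherent during laps 1-3, trajectory-like after
  mk_noise <- function() {
    P <- matrix(rexp(20 * 8), 20, 8); sweep(P, 2, colSums(P), "/")
  }
  mk_diag <- function() {
    P <- matrix(1e-3, 20, 8)
    for (b in 1:8) P[2 * b + 1, b] <- 1
    sweep(P, 2, colSums(P), "/")
  }
  frame_times <- seq(50, 550, by = 50)
  frame_laps <- ceiling(frame_times / 100)
  frames <- lapply(seq_along(frame_times), function(k) {
    if (frame_laps[k] <= 3) mk_noise() else mk_diag()
  })
  em <- emergence_comparison(cycles, frames, frame_times, frame_laps,
                             alpha = 0.01, n_shuffles = 100)
  expect_false(is.na(em$theta_lap))
  expect_false(is.na(em$replay_lap))
  expect_lt(em$theta_lap, em$replay_lap)
  expect_lte(em$alpha_used, max(em$replay_fpr, 1e-6) + 1e-12)
  # null scenario: no sequence structure anywhere
  cyc0 <- data.frame(time = sort(runif(200, 0, 600)), qr = rnorm(200, 0, 0.3))
  cyc0$lap <- ceiling(cyc0$time / 100)
  frames0 <- replicate(8, mk_noise(), simplify = FALSE)
  em0 <- emergence_comparison(cyc0, frames0, seq(50, 400, by = 50),
                              rep(1:4, each = 2), alpha = 0.01,
                              n_shuffles = 100)
  expect_true(is.na(em0$theta_lap))
  expect_false(any(em0$replay_significant))
})
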