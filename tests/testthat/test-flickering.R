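five_templates <- function(spec, seed = 40) {
  set.seed(seed)
  mk <- function(len) {
    bins <- seq(1, len - 1, by = 2)
    gaussian_tuning(runif(spec$n_units, 0, len), bins, spec)
  }
  list(first_stationary = mk(50), current = mk(150), last_stationary = mk(50),
       alternative = mk(50), control = mk(50))
}

test_that("flicker decoding assigns local spikes to the local context", {
  spec <- generator_spec(n_units = 25)
  tmpl <- five_templates(spec)
  set.seed(41)
  lam <- tmpl$current[, 30] * 0.04
  cnt <- matrix(rpois(25 * 40, lam), 25, 40)
  attr(cnt, "t") <- (1:40 - 0.5) * 0.04
  P <- flicker_decode(cnt, tmpl, 0.04)
  cp <- attr(P, "context_prob")
  expect_true(all(abs(colSums(cp) - 1) < 1e-9))
  expect_gt(mean(cp["current", ]), 0.7)
  expect_lt(mean(cp["alternative", ]), 0.15)
})

test_that("epoch finding respects the 0.5 threshold and speed gate", {
  t <- (1:100 - 0.5) * 0.04
  v <- rep(30, 100)
  ep <- find_epochs(rep(0.6, 100), t, v)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$duration, 4, tolerance = 0.05)
  expect_equal(nrow(find_epochs(rep(0.4, 100), t, v)), 0)
  # boundary bins below threshold are excluded
  p <- rep(0.3, 100); p[40:60] <- 0.8
  ep2 <- find_epochs(p, t, v)
  expect_equal(nrow(ep2), 1)
  expect_gt(ep2$start, t[38])
  expect_lt(ep2$stop, t[62])
  # immobile samples cannot form epochs
  v2 <- v; v2[45:50] <- 0
  ep3 <- find_epochs(p, t, v2)
  expect_equal(nrow(ep3), 2)
})

test_that("injected flicker epochs are recovered with Jaccard >= 0.5", {
  spec <- generator_spec(n_units = 30, n_laps = 6)
  mz <- maze_config()
  run <- generate_run_session(spec, mz, seed = 43)
  alt_range <- c(500, 550)                   # mobile segment of track 4
  local_range <- c(200, 250)                 # mobile segment of track 2
  run_f <- inject_flicker(run, run$truth$maps$rate, run$truth$maps$bin_centers,
                          alt_range, local_range, fraction = 0.10,
                          epoch_dur = 0.15, gain = 3, seed = 44)
  tmpl_bins <- function(lo, hi) {
    ix <- run$truth$maps$bin_centers > lo & run$truth$maps$bin_centers < hi
    run$truth$maps$rate[, ix]
  }
  tmpl <- list(first_stationary = tmpl_bins(150, 200),
               current = tmpl_bins(200, 250),
               last_stationary = tmpl_bins(250, 300),
               alternative = tmpl_bins(500, 550),
               control = tmpl_bins(350, 400))
  tau <- 0.04
  cnt <- bin_spikes(run_f$spikes, 0, run_f$duration, tau)
  P <- flicker_decode(cnt, tmpl, tau)
  tb <- attr(P, "t")
  v <- stats::approx(run$trajectory$t, run$trajectory$velocity, tb,
                     rule = 2)$y
  pos <- stats::approx(run$trajectory$t, run$trajectory$lin, tb, rule = 2)$y
  on_local <- pos > local_range[1] & pos < local_range[2]
  prob_alt <- attr(P, "context_prob")["alternative", ]
  prob_alt[!on_local] <- 0
  ep <- find_epochs(prob_alt, tb, v)
  truth <- run_f$truth$flicker_epochs
  in_any <- function(t0, tab) {
    vapply(t0, function(x) any(x >= tab$start & x <= tab$stop), logical(1))
  }
  grid <- seq(0, run_f$duration, by = 0.01)
  a <- in_any(grid, ep); b <- in_any(grid, truth)
  jac <- sum(a & b) / sum(a | b)
  expect_gte(jac, 0.5)
  # without injection the alternative context stays at the control level
  cnt0 <- bin_spikes(run$spikes, 0, run$duration, tau)
  P0 <- flicker_decode(cnt0, tmpl, tau)
  cp0 <- attr(P0, "context_prob")
  tb0 <- attr(P0, "t")
  pos0 <- stats::approx(run$trajectory$t, run$trajectory$lin, tb0, rule = 2)$y
  onl <- pos0 > local_range[1] & pos0 < local_range[2]
  expect_lt(mean(cp0["alternative", onl]) - mean(cp0["control", onl]), 0.05)
})

test_that("theta-peak-locked flicker shows phase concentration near 0", {
  spec <- generator_spec(n_units = 30, n_laps = 6)
  run <- generate_run_session(spec, maze_config(), seed = 45)
  run_f <- inject_flicker(run, run$truth$maps$rate, run$truth$maps$bin_centers,
                          c(500, 550), c(200, 250), fraction = 0.15,
                          lock_phase = TRUE, gain = 4, seed = 46)
  truth <- run_f$truth$flicker_epochs
  tp <- theta_phase(run_f$lfp)
  mid <- (truth$start + truth$stop) / 2
  ph <- phase_at(tp, mid)
  ray <- rayleigh_test(ph)
  expect_lt(ray$p_value, 0.05)
  d <- abs(ray$mean_phase)
  expect_lt(min(d, 2 * pi - d), pi / 3)
  # phase_modulation on synthetic probabilities reproduces the curve peak
  set.seed(47)
  phases <- runif(4000, 0, 2 * pi)
  prob <- 0.2 + 0.5 * (cos(phases) > 0.8) + rnorm(4000, 0, 0.02)
  pm <- phase_modulation(prob, phases, strong_threshold = 0.6)
  pk <- pm$curve$phase[which.max(pm$curve$mean)]
  expect_lt(min(pk, 2 * pi - pk), pi / 4)
  expect_lt(pm$rayleigh$p_value, 0.05)
  # phase-uniform strong bins pass the uniformity test
  pm0 <- phase_modulation(runif(2000, 0.85, 1), runif(2000, 0, 2 * pi))
  expect_gt(pm0$rayleigh$p_value, 0.01)
})

test_that("spatiotemporal pattern finds corner-locked decaying structure", {
  set.seed(48)
  laps <- rep(1:8, each = 200)
  pos <- rep(seq(0, 150, length.out = 200), 8)
  corner_pos <- c(50, 100)                      # segment-entry corners
  dcorner <- pmin(abs(pos - 50), abs(pos - 100))
  prob <- exp(-dcorner / 10) * exp(-(laps - 1) / 3) + rnorm(1600, 0, 0.02)
  sp <- spatiotemporal_pattern(prob, laps, pos, corner_pos)
  expect_gt(sp$corner_contrast, 0)
  expect_lt(stats::cor(sp$pc1_temporal, 1:8), 0)
  # uniform injection: flat spatial profile
  sp0 <- spatiotemporal_pattern(rep(0.3, 1600) + rnorm(1600, 0, 0.01),
                                laps, pos, corner_pos)
  expect_lt(abs(sp0$corner_contrast), abs(sp$corner_contrast) / 3)
  expect_error(spatiotemporal_pattern(prob[laps == 1], laps[laps == 1],
                                      pos[laps == 1], corner_pos),
               ">= 2 laps")
})

test_that("flicker-cell classification follows in-epoch spike preference", {
  nl <- data.frame(start = c(1, 5), stop = c(2, 6))
  lc <- data.frame(start = 10, stop = 12)
  sp <- spike_ensemble(list(
    spike_train("a", c(1.2, 1.5, 5.5)),       # only non-local epochs
    spike_train("b", c(1.1, 10.5, 11, 11.5)), # mostly local
    spike_train("c", c(20, 21))))             # no in-epoch spikes
  cls <- classify_flicker_cells(sp, nl, lc)
  expect_identical(cls$class[cls$unit == "a"], "nonlocal")
  expect_identical(cls$class[cls$unit == "b"], "local")
  expect_true(is.na(cls$class[cls$unit == "c"]))
})

test_that("sleep models rank non-local epochs when they seeded them", {
  set.seed(49)
  units <- sprintf("u%02d", 1:20)
  motif <- units[1:6]
  sleep <- c(replicate(120, motif, simplify = FALSE),
             replicate(120, sample(units, 6), simplify = FALSE))
  m <- fit_transition_model(sleep, units)
  nonlocal <- replicate(25, motif[1:5], simplify = FALSE)
  local <- replicate(25, sample(units, 5), simplify = FALSE)
  r <- flicker_sleep_prediction(m, nonlocal, local, n_shuffles = 1000)
  expect_lt(r$p_value, 0.01)
  # identical sources: no difference
  r0 <- flicker_sleep_prediction(m, local,
                                 replicate(25, sample(units, 5),
                                           simplify = FALSE),
                                 n_shuffles = 1000)
  expect_gt(r0$p_value, 0.01)
  # epochs with < 2 units are excluded
  r1 <- flicker_sleep_prediction(m, list(units[1]), local, n_shuffles = 500)
  expect_null(r1$nonlocal)
})
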