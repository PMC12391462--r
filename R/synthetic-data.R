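#' @title Synthetic session generator
#'
#' @description Generates run and sleep sessions with the statistical
#' structure the downstream analyses assume — Gaussian place fields on the
#' square maze, theta-modulated phase-precessing spiking, sinusoid-plus-noise
#' theta LFP, sleep burst frames embedding ordered sequence motifs, remapping
#' plans with controllable plastic/elastic fractions, and injected
#' alternate-context (flicker) epochs — together with the ground truth needed
#' to test every stage. A single RNG seed per generation call makes outputs
#' bit-reproducible.
#' @name synthetic_data
NULL

#' Generator parameters
#'
#' Defaults describe the emulated recordings: ~40 pyramidal units with 10 cm
#' (sigma) Gaussian fields peaking near 15 Hz, runs at 30 cm/s for 10
#' alternating-direction laps, 8 Hz theta with phase precession across the
#' field, sleep background 0.5 Hz/unit with ~6 burst frames per minute of
#' 100-1200 ms embedding ordered motifs at ~10x background rate.
#'
#' @param n_units number of pyramidal units.
#' @param field_sigma Gaussian place-field sigma (cm).
#' @param peak_rate in-field peak rate (Hz).
#' @param baseline_rate out-of-field rate (Hz).
#' @param speed mean running speed (cm/s).
#' @param speed_cv slow sinusoidal speed variability (fractional amplitude);
#'   real running speed fluctuates, which prevents artifactual standing
#'   interference fringes between theta modulation and position.
#' @param n_laps laps per run session (a lap is one full traversal; directions
#'   alternate).
#' @param theta_freq LFP theta frequency (Hz), 7-10.
#' @param theta_mod depth of theta rate modulation in \[0,1\].
#' @param precession_slope phase-precession slope (deg/cm, negative =
#'   phase advances earlier across the field).
#' @param onset_phase phase (deg) at field entry.
#' @param lfp_rate LFP sampling rate (Hz).
#' @param lfp_noise_sd LFP white-noise sd relative to unit theta amplitude.
#' @param sleep_background_rate per-unit background rate during sleep (Hz).
#' @param frame_rate_per_min injected frame rate (per minute).
#' @param frame_unit_lag within-frame lag between successive units (s).
#' @param frame_jitter_sd within-frame spike-time jitter sd (s).
#' @param participation_prob probability each template unit joins a frame.
#' @param spikes_per_slot spikes emitted per participating unit per frame.
#' @return list of class `generator_spec`.
#' @export
generator_spec <- function(n_units = 40, field_sigma = 10, peak_rate = 15,
                           baseline_rate = 0.1, speed = 30, speed_cv = 0.25,
                           n_laps = 10,
                           theta_freq = 8, theta_mod = 0.7,
                           precession_slope = -6.5, onset_phase = 300,
                           lfp_rate = 1250, lfp_noise_sd = 0.2,
                           sleep_background_rate = 0.5,
                           frame_rate_per_min = 20,
                           frame_unit_lag = 0.03, frame_jitter_sd = 0.005,
                           participation_prob = 0.9, spikes_per_slot = 2) {
  spec <- as.list(environment())
  stopifnot(spec$n_units >= 1, spec$peak_rate >= 0, spec$theta_freq >= 1)
  class(spec) <- "generator_spec"
  spec
}

#' Map a linear maze coordinate back to 2D
#' @param lin linear positions (cm).
#' @param maze a `maze_config`.
#' @return matrix with columns x, y.
#' @export
lin_to_xy <- function(lin, maze) {
  out <- matrix(NA_real_, length(lin), 2)
  for (k in 1:4) {
    lo <- maze$offsets[k]
    hi <- lo + maze$tracks[[k]]$length
    idx <- which(lin >= lo - 1e-9 & (lin < hi | (k == 4 & lin <= hi + 1e-9)))
    if (!length(idx)) next
    pl <- maze$tracks[[k]]$polyline
    seg_len <- sqrt(rowSums((pl[-1, , drop = FALSE] - pl[-nrow(pl), , drop = FALSE])^2))
    cs <- cumsum(c(0, seg_len))
    s <- pmin(pmax(lin[idx] - lo, 0), cs[length(cs)] - 1e-9)
    j <- findInterval(s, cs)
    frac <- (s - cs[j]) / seg_len[j]
    out[idx, 1] <- pl[j, 1] + frac * (pl[j + 1, 1] - pl[j, 1])
    out[idx, 2] <- pl[j, 2] + frac * (pl[j + 1, 2] - pl[j, 2])
  }
  colnames(out) <- c("x", "y")
  out
}

#' Evaluate Gaussian tuning curves on spatial bins
#'
#' @param centers field centers (cm) per unit.
#' @param positions positions at which to evaluate (cm).
#' @param spec a `generator_spec`.
#' @return matrix units x positions of rates (Hz).
#' @export
gaussian_tuning <- function(centers, positions, spec) {
  r <- vapply(centers, function(ci) {
    spec$baseline_rate +
      spec$peak_rate * exp(-(positions - ci)^2 / (2 * spec$field_sigma^2))
  }, numeric(length(positions)))
  t(matrix(r, nrow = length(positions)))
}

#' True place maps on 2-cm bins
#' @param centers field centers per unit.
#' @param maze a `maze_config`.
#' @param spec a `generator_spec`.
#' @param bin_width spatial bin (cm).
#' @return list with `rate` (units x bins) and `bin_centers`.
#' @export
true_place_maps <- function(centers, maze, spec, bin_width = 2) {
  edges <- seq(0, maze$total_length, by = bin_width)
  ctr <- edges[-length(edges)] + bin_width / 2
  list(rate = gaussian_tuning(centers, ctr, spec), bin_centers = ctr)
}

sample_inhomogeneous <- function(rate, dt, t0 = 0) {
  ## rate: vector of instantaneous rates on a dt grid; thinning via per-bin
  ## Poisson counts with uniform placement inside the bin
  n <- stats::rpois(length(rate), rate * dt)
  idx <- rep.int(seq_along(rate), n)
  if (!length(idx)) return(numeric(0))
  sort(t0 + (idx - 1) * dt + stats::runif(length(idx)) * dt)
}

#' Generate a run session
#'
#' Constant-speed ping-pong laps along the full maze, inhomogeneous-Poisson
#' spikes with rate = place tuning x theta modulation, phase precession
#' implemented by advancing the preferred phase linearly across the field,
#' and a sinusoid + white-noise theta LFP.
#'
#' @param spec a `generator_spec`.
#' @param maze a `maze_config`.
#' @param session_id session name.
#' @param seed RNG seed (mandatory; recorded in the truth).
#' @param centers optional field centers (cm); drawn uniformly if `NULL`.
#' @param flicker optional flicker injection plan, see [inject_flicker()].
#' @return session list with `spikes`, `trajectory`, `lfp`, `maze`, `truth`.
#' @export
generate_run_session <- function(spec, maze, session_id = "Run1", seed,
                                 centers = NULL, flicker = NULL) {
  stopifnot(inherits(spec, "generator_spec"), !missing(seed))
  if (spec$n_laps < 1) stop("config error: zero-occupancy track (n_laps < 1)")
  set.seed(seed)
  L <- maze$total_length
  if (is.null(centers)) centers <- stats::runif(spec$n_units, 0, L)
  ## ping-pong laps at slowly varying speed; distance run s(t) folds onto the
  ## track, so lap boundaries are where s crosses multiples of L
  ts_full <- seq(0, spec$n_laps * L / spec$speed * 2, by = 1 / 30)
  ph_speed <- stats::runif(1, 0, 2 * pi)
  v_t <- spec$speed * (1 + spec$speed_cv * sin(2 * pi * 0.15 * ts_full +
                                                 ph_speed))
  s_t <- cumsum(v_t) / 30
  keep <- s_t < spec$n_laps * L
  ts <- ts_full[keep]
  s <- s_t[keep]
  duration <- max(ts) + 1 / 30
  fold <- (s / L) %% 2
  lin <- ifelse(fold < 1, fold, 2 - fold) * L
  lin <- pmin(pmax(lin, 0), L - 1e-9)
  lap <- pmin(floor(s / L) + 1L, spec$n_laps)
  xy <- lin_to_xy(lin, maze)
  traj <- trajectory_session(ts, xy[, 1], xy[, 2], maze, lap = lap)

  dt <- 0.001
  tg <- seq(0, duration - dt, by = dt)
  ling <- stats::approx(ts, lin, tg, rule = 2)$y
  sg <- stats::approx(ts, s, tg, rule = 2)$y
  dirg <- ifelse((sg / L) %% 2 < 1, 1, -1)           # travel direction sign
  phig <- (2 * pi * spec$theta_freq * tg) %% (2 * pi)
  slope <- spec$precession_slope * pi / 180
  onset <- spec$onset_phase * pi / 180
  trains <- vector("list", spec$n_units)
  for (i in seq_len(spec$n_units)) {
    f <- spec$baseline_rate +
      spec$peak_rate * exp(-(ling - centers[i])^2 / (2 * spec$field_sigma^2))
    ## preferred phase advances with distance traveled into the field,
    ## measured along the current direction of travel
    d_in <- dirg * (ling - centers[i]) + 2 * spec$field_sigma
    pref <- onset + slope * d_in
    rate <- f * (1 + spec$theta_mod * cos(phig - pref))
    st <- sample_inhomogeneous(rate, dt)
    trains[[i]] <- spike_train(sprintf("u%02d", i), st)
  }
  spikes <- spike_ensemble(trains)

  nl <- round(duration * spec$lfp_rate)
  tl <- (seq_len(nl) - 1) / spec$lfp_rate
  lfp <- lfp_channel(cos(2 * pi * spec$theta_freq * tl) +
                       stats::rnorm(nl, 0, spec$lfp_noise_sd), spec$lfp_rate)

  out <- list(name = session_id, type = "run", spikes = spikes,
              trajectory = traj, lfp = lfp, maze = maze, duration = duration,
              truth = list(seed = seed, centers = centers,
                           maps = true_place_maps(centers, maze, spec),
                           theta_freq = spec$theta_freq, spec = spec))
  if (!is.null(flicker)) out <- do.call(inject_flicker, c(list(out), flicker))
  out
}

#' Generate a sleep session with burst frames embedding motifs
#'
#' Background low-rate Poisson spiking plus frames: bursts in which a subset
#' of a template fires in order with jitter. Injected frames have >= 5
#' distinct units and durations within 100-1200 ms by construction.
#'
#' @param spec a `generator_spec`.
#' @param templates list of unit-id character vectors (ordered motifs); if
#'   empty, frames use random unit subsets in random order.
#' @param duration session duration (s).
#' @param seed RNG seed.
#' @param session_id session name.
#' @return session list with `spikes`, `lfp` (NULL), `truth$frames`.
#' @export
generate_sleep_session <- function(spec, templates = list(), duration = 300,
                                   seed, session_id = "Sleep1") {
  stopifnot(inherits(spec, "generator_spec"), !missing(seed))
  set.seed(seed)
  ids <- sprintf("u%02d", seq_len(spec$n_units))
  for (tp in templates) {
    if (!all(tp %in% ids)) stop("config error: template references unknown unit")
  }
  n_frames <- stats::rpois(1, spec$frame_rate_per_min * duration / 60)
  starts <- sort(stats::runif(n_frames, 1, duration - 2))
  starts <- starts[c(TRUE, diff(starts) > 1.6)]       # keep frames separated
  n_frames <- length(starts)
  spk <- stats::setNames(vector("list", spec$n_units), ids)
  truth <- NULL
  for (k in seq_len(n_frames)) {
    if (length(templates)) {
      tid <- ((k - 1L) %% length(templates)) + 1L
      tpl <- templates[[tid]]
      part <- tpl[stats::runif(length(tpl)) < spec$participation_prob]
      while (length(unique(part)) < 5) {
        extra <- setdiff(tpl, part)
        if (!length(extra)) extra <- setdiff(ids, part)
        part <- c(part, extra[1])
      }
    } else {
      tid <- NA_integer_
      part <- sample(ids, max(5, min(spec$n_units, stats::rpois(1, 8))))
    }
    slot <- seq_along(part) - 1
    t_units <- starts[k] + 0.02 + slot * spec$frame_unit_lag
    dur <- max(0.1, min(1.2, max(t_units) - starts[k] + 0.06))
    for (j in seq_along(part)) {
      n_s <- max(1, stats::rpois(1, spec$spikes_per_slot))
      tt <- t_units[j] + stats::rnorm(n_s, 0, spec$frame_jitter_sd)
      tt <- pmin(pmax(tt, starts[k] + 0.001), starts[k] + dur - 0.001)
      spk[[part[j]]] <- c(spk[[part[j]]], tt)
    }
    truth <- rbind(truth, data.frame(start = starts[k], stop = starts[k] + dur,
                                     template = tid,
                                     order = paste(part, collapse = " "),
                                     stringsAsFactors = FALSE))
  }
  for (i in ids) {                                    # background spiking
    nb <- stats::rpois(1, spec$sleep_background_rate * duration)
    spk[[i]] <- sort(c(spk[[i]], stats::runif(nb, 0, duration)))
  }
  trains <- lapply(ids, function(i) spike_train(i, spk[[i]]))
  list(name = session_id, type = "sleep", spikes = spike_ensemble(trains),
       lfp = NULL, maze = NULL, duration = duration,
       truth = list(seed = seed, frames = truth, templates = templates))
}

#' Apply a remapping plan across pre-detour / detour / post-detour maps
#'
#' Stable units keep their map in all three sessions; plastic units adopt a
#' new detour map and keep it post-detour; elastic units adopt a new detour
#' map but revert post-detour; the remainder remap randomly in both.
#'
#' @param maps_pre units x bins rate matrix for the pre-detour session.
#' @param plan list with fractions `plastic`, `elastic`, `stable` (sum <= 1).
#' @param spec a `generator_spec` (field shape for redrawn maps).
#' @param bin_centers spatial bin centers (cm) of `maps_pre`.
#' @param seed RNG seed.
#' @return list `det`, `post` (matrices) and `label` (per-unit class).
#' @export
apply_remapping_plan <- function(maps_pre, plan, spec, bin_centers, seed) {
  stopifnot(!missing(seed))
  fr <- c(plastic = plan$plastic %||% 0, elastic = plan$elastic %||% 0,
          stable = plan$stable %||% 0)
  if (sum(fr) > 1 + 1e-9) stop("plan fractions sum > 1")
  set.seed(seed)
  n <- nrow(maps_pre)
  lab <- rep("random", n)
  idx <- sample.int(n)
  cuts <- round(cumsum(fr) * n)
  lab[idx[seq_len(cuts[1])]] <- "plastic"
  if (cuts[2] > cuts[1]) lab[idx[(cuts[1] + 1):cuts[2]]] <- "elastic"
  if (cuts[3] > cuts[2]) lab[idx[(cuts[2] + 1):cuts[3]]] <- "stable"
  L <- max(bin_centers)
  new_map <- function() gaussian_tuning(stats::runif(1, 0, L), bin_centers, spec)
  det <- maps_pre; post <- maps_pre
  for (i in seq_len(n)) {
    if (lab[i] == "stable") next
    det[i, ] <- new_map()
    post[i, ] <- switch(lab[i], plastic = det[i, ], elastic = maps_pre[i, ],
                        random = new_map())
  }
  list(det = det, post = post, label = lab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Inject alternate-context (flicker) epochs into a run session
#'
#' During injected epochs, spikes are re-drawn from the alternate-context
#' tuning (the units' rates at a position mapped onto the alternate segment)
#' instead of the local tuning. Epochs can cover a fraction of run time or be
#' locked to theta-peak half-cycles.
#'
#' @param session run session from [generate_run_session()].
#' @param alt_maps units x bins alternate-context rate matrix over the full
#'   linear coordinate.
#' @param bin_centers spatial bin centers of `alt_maps`.
#' @param alt_range c(start, stop) cm of the alternate segment.
#' @param local_range c(start, stop) cm of the local segment the epochs map from.
#' @param fraction fraction of run time covered by epochs.
#' @param epoch_dur epoch duration (s).
#' @param lock_phase if `TRUE`, epochs are centred on theta peaks (phase 0)
#'   and last half a theta cycle.
#' @param gain rate multiplier for the alternate tuning during epochs.
#' @param seed RNG seed.
#' @return session with modified `spikes` and `truth$flicker_epochs`.
#' @export
inject_flicker <- function(session, alt_maps, bin_centers, alt_range,
                           local_range, fraction = 0.1, epoch_dur = 0.125,
                           lock_phase = FALSE, gain = 1.5, seed) {
  stopifnot(!missing(seed))
  set.seed(seed)
  traj <- session$trajectory
  dur <- session$duration
  in_local <- traj$lin >= local_range[1] & traj$lin <= local_range[2] &
    traj$velocity > 10
  cand <- traj$t[in_local]
  if (!length(cand)) stop("no local-segment running samples to inject into")
  n_ep <- max(1, round(fraction * dur / epoch_dur))
  if (lock_phase) {
    f <- session$truth$theta_freq
    peaks <- seq(0, dur, by = 1 / f)                  # LFP cos peaks
    ok <- peaks[vapply(peaks, function(p) any(abs(cand - p) < 0.05), logical(1))]
    ctr <- sample(ok, min(n_ep, length(ok)))
    ep <- data.frame(start = ctr - 0.25 / f, stop = ctr + 0.25 / f)
  } else {
    ctr <- sample(cand, min(n_ep, length(cand)))
    ep <- data.frame(start = ctr - epoch_dur / 2, stop = ctr + epoch_dur / 2)
  }
  ep <- ep[order(ep$start), , drop = FALSE]
  ep <- ep[c(TRUE, diff(ep$start) > epoch_dur), , drop = FALSE]

  dt <- 0.001
  tg <- seq(0, dur - dt, by = dt)
  ling <- stats::approx(traj$t, traj$lin, tg, rule = 2)$y
  in_ep <- rep(FALSE, length(tg))
  for (r in seq_len(nrow(ep))) {
    in_ep[tg >= ep$start[r] & tg < ep$stop[r]] <- TRUE
  }
  frac_seg <- (ling - local_range[1]) / diff(local_range)
  alt_pos <- alt_range[1] + pmin(pmax(frac_seg, 0), 1) * diff(alt_range)
  bw <- bin_centers[2] - bin_centers[1]
  alt_bin <- pmin(pmax(round((alt_pos - bin_centers[1]) / bw) + 1L, 1L),
                  length(bin_centers))
  ids <- unit_ids(session$spikes)
  trains <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    keep <- session$spikes[[ids[i]]]$times
    drop <- rep(FALSE, length(keep))
    for (r in seq_len(nrow(ep))) {
      drop <- drop | (keep >= ep$start[r] & keep < ep$stop[r])
    }
    rate <- ifelse(in_ep, gain * alt_maps[i, alt_bin], 0)
    newt <- sample_inhomogeneous(rate, dt)
    trains[[i]] <- spike_train(ids[i], sort(c(keep[!drop], newt)))
  }
  session$spikes <- spike_ensemble(trains)
  session$truth$flicker_epochs <- ep
  session
}

#' Generate synthetic theta-cycle posteriors
#'
#' Each posterior is a Gaussian ridge sweeping from behind to ahead of the
#' (centered) animal position across the cycle's time bins, plus uniform
#' noise — the decoded structure of a theta sequence. Columns are normalized
#' to sum to 1. Used for detector calibrations where ground truth must be
#' known exactly.
#'
#' @param n number of cycles.
#' @param n_space spatial bins (centered: position axis is
#'   `seq(-window, window, length.out = n_space)`).
#' @param n_time time bins per cycle.
#' @param window half-width of the position axis (cm).
#' @param sweep total sweep extent (cm) across the cycle.
#' @param ridge_sd ridge width (cm).
#' @param noise uniform admixture in \[0, 1\].
#' @return list with `posteriors` (list of matrices) and `x` (position axis).
#' @export
synthetic_cycle_posteriors <- function(n, n_space = 41, n_time = 6,
                                       window = 40, sweep = 30,
                                       ridge_sd = 6, noise = 0.3) {
  x <- seq(-window, window, length.out = n_space)
  tt <- seq_len(n_time)
  ridge_pos <- seq(-sweep / 2, sweep / 2, length.out = n_time)
  posts <- lapply(seq_len(n), function(i) {
    jit <- stats::rnorm(1, 0, ridge_sd / 2)
    P <- vapply(tt, function(b) {
      p <- exp(-(x - ridge_pos[b] - jit)^2 / (2 * ridge_sd^2))
      p <- (1 - noise) * p / sum(p) + noise / n_space
      p
    }, numeric(n_space))
    sweep(P, 2, colSums(P), "/")
  })
  list(posteriors = posts, x = x)
}

#' Generate a full 8-session detour-day bundle
#'
#' Sleep1, Run1 (square), Sleep2, Run2 (detour on track 2), Sleep3, Run3
#' (detour on track 4), Sleep4, Run4 (reversal). Sleep sessions embed forward
#' motifs drawn from the following run's place-map order.
#'
#' @param spec a `generator_spec`.
#' @param seed RNG seed; sub-seeds per session are derived from it.
#' @param sleep_duration sleep session duration (s).
#' @return a `session_set`; per-session truth is kept in each session.
#' @export
generate_session_set <- function(spec, seed, sleep_duration = 180) {
  set.seed(seed)
  sub <- sample.int(2^31 - 1, 16)
  mz_sq <- maze_config()
  centers <- stats::runif(spec$n_units, 0, mz_sq$total_length)
  ids <- sprintf("u%02d", seq_len(spec$n_units))
  tpl <- list(ids[order(centers)][seq_len(min(8, spec$n_units))])
  sessions <- list()
  k <- 1L
  for (j in 1:4) {
    sessions[[k]] <- generate_sleep_session(spec, tpl, sleep_duration,
                                            seed = sub[2 * j - 1],
                                            session_id = paste0("Sleep", j))
    k <- k + 1L
    mz <- switch(j, maze_config(), maze_config(detoured_track = 2),
                 maze_config(detoured_track = 4), maze_config())
    sessions[[k]] <- generate_run_session(spec, mz,
                                          session_id = paste0("Run", j),
                                          seed = sub[2 * j], centers = centers)
    k <- k + 1L
  }
  session_set(sessions)
}
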