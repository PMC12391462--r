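#' @title Pipeline orchestration over a session set
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' Every numeric default is the analysis' stated operating point: 2 cm
#' spatial bins with 2 cm smoothing, 0.1 s occupancy mask, 10 cm/s run
#' filter, 2 Hz peak-rate inclusion, frames of 100-1200 ms with >= 5 units at
#' velocity < 2 cm/s, 20 ms decoding bins (40 ms for flicker, 200 ms for
#' validation), replay criterion |wc| > 0.6 and jump < 0.4, theta-sequence
#' alpha 0.01, 95th-percentile Markov significance, 0.3 drift/plastic cut,
#' 0.5/0.9 flicker probability cuts.
#'
#' @param seed master seed.
#' @param out_dir output directory.
#' @param stages character vector of stages to run (subset of
#'   `c("place_maps", "frames", "decoding", "theta", "motifs")`).
#' @param ... overrides for any threshold listed above.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, out_dir = tempfile("placeseq_"),
                            stages = c("place_maps", "frames", "decoding",
                                       "theta", "motifs"), ...) {
  cfg <- list(seed = seed, out_dir = out_dir, stages = stages,
              bin_width = 2, smooth_sigma = 2, min_occupancy = 0.1,
              speed_min = 10, peak_min = 2,
              frame_dur = c(0.1, 1.2), frame_min_units = 5, frame_speed = 2,
              tau_frame = 0.02, tau_flicker = 0.04, tau_validate = 0.2,
              wc_min = 0.6, jump_max = 0.4, theta_alpha = 0.01,
              markov_percentile = 95, drift_cut = 0.3,
              flicker_epoch_cut = 0.5, flicker_strong_cut = 0.9,
              n_shuffles = 200, markov_shuffles = 10000)
  dots <- list(...)
  cfg[names(dots)] <- dots
  class(cfg) <- "pipeline_config"
  cfg
}

cfg_hash <- function(cfg) {
  cfg <- cfg[setdiff(names(cfg), "out_dir")]   # hash the analysis, not paths
  s <- paste(vapply(cfg[order(names(cfg))], function(v) {
    paste(format(v, digits = 15), collapse = ",")
  }, character(1)), collapse = ";")
  ## small rolling hash; provenance marker, not cryptographic
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2^31
  sprintf("%08x", h)
}

#' Run the analysis pipeline on a session set
#'
#' Stages communicate via on-disk CSV artifacts under `config$out_dir`
#' (place maps, frame tables, trajectory scores, theta-cycle quadrant
#' ratios, transition-model prediction) plus a markdown report. Every output
#' records the config hash and seed; a rerun with the same seed is
#' byte-identical.
#'
#' @param set a `session_set`.
#' @param config a `pipeline_config`.
#' @return list of stage results (also written to `config$out_dir`).
#' @export
run_pipeline <- function(set, config = pipeline_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  prov <- c(config_hash = cfg_hash(config), seed = config$seed)
  results <- list(provenance = prov)
  stamp <- function(df) {
    df$config_hash <- prov[["config_hash"]]; df$seed <- config$seed; df
  }
  runs <- Filter(function(s) s$type == "run", set$sessions)
  sleeps <- Filter(function(s) s$type == "sleep", set$sessions)

  if ("place_maps" %in% config$stages) {
    pm <- lapply(runs, function(s) {
      compute_place_maps(s$spikes, s$trajectory,
                         bin_width = config$bin_width,
                         sigma = config$smooth_sigma,
                         speed_min = config$speed_min,
                         min_occupancy = config$min_occupancy)
    })
    results$place_maps <- pm
    for (nm in names(pm)) {
      df <- as.data.frame(pm[[nm]]$rate)
      df <- cbind(unit = rownames(pm[[nm]]$rate), df)
      utils::write.csv(stamp(df),
                       file.path(config$out_dir, paste0("maps_", nm, ".csv")),
                       row.names = FALSE)
    }
  }

  if ("frames" %in% config$stages) {
    fr <- lapply(sleeps, function(s) {
      detect_frames(s$spikes, c(0, s$duration),
                    min_units = config$frame_min_units,
                    dur_range = config$frame_dur)
    })
    results$frames <- fr
    for (nm in names(fr)) {
      utils::write.csv(stamp(as.data.frame(fr[[nm]])),
                       file.path(config$out_dir, paste0("frames_", nm, ".csv")),
                       row.names = FALSE)
    }
  }

  if ("decoding" %in% config$stages) {
    if (is.null(results$place_maps) || is.null(results$frames)) {
      stop("stage 'decoding' requires artifacts from 'place_maps' and 'frames'")
    }
    tmpl <- results$place_maps[[1]]
    scores <- NULL
    sleep1 <- sleeps[[1]]
    fr1 <- results$frames[[sleep1$name]]
    for (k in seq_len(min(nrow(fr1), 50))) {
      cnt <- bin_spikes(sleep1$spikes, fr1$start[k], fr1$stop[k],
                        config$tau_frame, units = rownames(tmpl$rate))
      P <- decode_posterior(cnt, tmpl$rate, config$tau_frame)
      ts <- time_bin_shuffle_test(P, n_shuffles = config$n_shuffles,
                                  wc_min = config$wc_min,
                                  jump_max = config$jump_max)
      scores <- rbind(scores, data.frame(frame = k, wc = ts$wc,
                                         jump = ts$jump,
                                         percentile = ts$percentile,
                                         significant = ts$significant))
    }
    results$frame_scores <- scores
    if (!is.null(scores)) {
      utils::write.csv(stamp(scores),
                       file.path(config$out_dir, "frame_scores.csv"),
                       row.names = FALSE)
    }
  }

  if ("theta" %in% config$stages) {
    if (is.null(results$place_maps)) stop("stage 'theta' requires 'place_maps'")
    s <- runs[[1]]
    qr_tab <- theta_cycle_quadrants(s, results$place_maps[[s$name]],
                                    tau = config$tau_frame)
    results$theta_cycles <- qr_tab
    utils::write.csv(stamp(qr_tab),
                     file.path(config$out_dir, "theta_cycles.csv"),
                     row.names = FALSE)
  }

  if ("motifs" %in% config$stages) {
    if (is.null(results$frames)) stop("stage 'motifs' requires 'frames'")
    sleep1 <- sleeps[[1]]
    fr1 <- results$frames[[sleep1$name]]
    seqs <- lapply(seq_len(nrow(fr1)), function(k) {
      frame_sequence(frame_spikes(sleep1$spikes, fr1$start[k], fr1$stop[k]))
    })
    seqs <- seqs[lengths(seqs) >= 2]
    if (length(seqs) >= 2) {
      model <- fit_transition_model(seqs, units = set$units)
      results$transition_model <- model
      utils::write.csv(stamp(as.data.frame(model$P2)),
                       file.path(config$out_dir, "transition_matrix.csv"),
                       row.names = TRUE)
    }
  }

  report <- c("# placeseq pipeline report", "",
              paste0("- config hash: ", prov[["config_hash"]]),
              paste0("- seed: ", config$seed),
              paste0("- sessions: ", paste(names(set$sessions), collapse = ", ")),
              paste0("- stages: ", paste(config$stages, collapse = ", ")))
  if (!is.null(results$frames)) {
    report <- c(report, paste0("- frames detected: ",
                               paste(vapply(results$frames, nrow, integer(1)),
                                     collapse = "/")))
  }
  if (!is.null(results$frame_scores)) {
    report <- c(report, paste0("- significant replay frames: ",
                               sum(results$frame_scores$significant)))
  }
  writeLines(report, file.path(config$out_dir, "report.md"))
  results
}

#' Quadrant ratios of a run session's theta cycles
#'
#' Detects theta cycles from the session LFP, decodes each cycle at 20 ms
#' bins against the session's own place maps, and scores the quadrant ratio
#' recentered on the animal's position.
#'
#' @param session run session (with `lfp`, `trajectory`, `spikes`).
#' @param maps a `place_map_set` template.
#' @param tau decoding bin (s).
#' @param min_units cycles with more than this many active units are scored.
#' @param speed_min active-behavior velocity filter (cm/s).
#' @return data.frame: cycle start/stop, lap, position, n_units, qr.
#' @export
theta_cycle_quadrants <- function(session, maps, tau = 0.02, min_units = 3,
                                  speed_min = 10) {
  tp <- theta_phase(session$lfp)
  cyc <- tp$cycles
  traj <- session$trajectory
  out <- NULL
  for (k in seq_len(nrow(cyc))) {
    mid <- (cyc$start[k] + cyc$stop[k]) / 2
    v <- stats::approx(traj$t, traj$velocity, mid, rule = 2)$y
    if (v <= speed_min) next
    cnt <- bin_spikes(session$spikes, cyc$start[k], cyc$stop[k], tau,
                      units = rownames(maps$rate))
    nu <- sum(rowSums(cnt) > 0)
    if (nu <= min_units) next
    P <- decode_posterior(cnt, maps$rate, tau)
    pos <- stats::approx(traj$t, traj$lin, mid, rule = 2)$y
    dirn <- traj$direction[which.min(abs(traj$t - mid))]
    qr <- quadrant_ratio(P, x = maps$bin_centers, current_x = pos,
                         direction = if (dirn == "dir1") 1 else -1)
    lap <- if (!is.null(traj$lap)) traj$lap[which.min(abs(traj$t - mid))] else NA
    out <- rbind(out, data.frame(start = cyc$start[k], stop = cyc$stop[k],
                                 lap = lap, position = pos, n_units = nu,
                                 qr = qr))
  }
  if (is.null(out)) out <- data.frame(start = numeric(0), stop = numeric(0),
                                      lap = integer(0), position = numeric(0),
                                      n_units = integer(0), qr = numeric(0))
  out
}
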