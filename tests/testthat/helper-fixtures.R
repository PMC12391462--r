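# Shared synthetic fixtures, built once per test run and memoized.
# All fixtures are generated from fixed seeds so every assertion is replayable.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# A run session rich enough for theta-cycle scoring: 40 units, 6 laps,
# strong theta coupling.
fix_run <- function() fixture("run", function() {
  spec <- generator_spec(n_units = 40, theta_mod = 0.9)   # default 10 laps
  run <- generate_run_session(spec, maze_config(), seed = 31)
  run$maps <- compute_place_maps(run$spikes, run$trajectory)
  run$spec <- spec
  run
})

# A sleep session with two 8-unit templates embedded in frames.
fix_sleep <- function() fixture("sleep", function() {
  spec <- generator_spec(n_units = 20)
  ids <- sprintf("u%02d", 1:20)
  sl <- generate_sleep_session(spec, list(ids[1:8], ids[9:16]),
                               duration = 330, seed = 5)
  sl$spec <- spec
  sl
})

# Frame unit sequences extracted from the sleep fixture.
fix_sleep_seqs <- function() fixture("sleep_seqs", function() {
  sl <- fix_sleep()
  fr <- detect_frames(sl$spikes, c(0, sl$duration))
  seqs <- lapply(seq_len(nrow(fr)), function(k) {
    frame_sequence(frame_spikes(sl$spikes, fr$start[k], fr$stop[k]))
  })
  list(frames = fr, seqs = seqs[lengths(seqs) >= 2])
})

# Minimal trajectory running along track 1 at constant speed, for toy maps.
toy_trajectory <- function(speed = 30, duration = 5, maze = maze_config()) {
  t <- seq(0, duration, by = 1 / 30)
  x <- pmin(speed * t, maze$side - 1e-6)
  trajectory_session(t, x, rep(0, length(t)), maze,
                     lap = rep(1L, length(t)))
}

expect_close <- function(object, expected, tol = 1e-8) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("|%g - %g| <= %g", object, expected, tol))
}
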