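#' @title Session data model: spikes, trajectory, LFP, maze configuration
#'
#' @description Core S3 containers shared by every analysis stage. Time is in
#' seconds (double), session-relative and starting at 0. The linear maze
#' coordinate is 0-based, in cm, continuous within each track; tracks are
#' concatenated with explicit offsets stored in the maze configuration.
#' @name session_model
NULL

#' Construct a spike train for one sorted unit
#'
#' @param unit_id opaque unit identifier (coerced to character).
#' @param times spike times in seconds, strictly increasing, no NA.
#' @param label putative cell class, `"pyramidal"` or `"interneuron"`.
#' @return object of class `spike_train`.
#' @export
spike_train <- function(unit_id, times, label = "pyramidal") {
  times <- as.numeric(times)
  if (anyNA(times)) stop("spike_train: NA spike times for unit ", unit_id)
  if (is.unsorted(times, strictly = FALSE)) {
    stop("spike_train: non-monotone spike times for unit ", unit_id)
  }
  label <- match.arg(label, c("pyramidal", "interneuron"))
  structure(list(unit_id = as.character(unit_id), times = times, label = label),
            class = "spike_train")
}

#' Bundle spike trains into an ensemble
#'
#' @param trains list of `spike_train` objects with unique unit ids.
#' @return named list of class `spike_ensemble` (names are unit ids).
#' @export
spike_ensemble <- function(trains) {
  if (!length(trains)) {
    return(structure(stats::setNames(list(), character(0)), class = "spike_ensemble"))
  }
  ids <- vapply(trains, function(u) u$unit_id, character(1))
  if (anyDuplicated(ids)) stop("spike_ensemble: duplicated unit ids")
  structure(stats::setNames(trains, ids), class = "spike_ensemble")
}

#' Unit ids of an ensemble
#' @param spikes a `spike_ensemble`.
#' @param label optional cell-class filter.
#' @return character vector of unit ids.
#' @export
unit_ids <- function(spikes, label = NULL) {
  ids <- names(spikes)
  if (!is.null(label)) {
    keep <- vapply(spikes, function(u) u$label == label, logical(1))
    ids <- ids[keep]
  }
  ids
}

# ---- maze geometry -----------------------------------------------------------

track_polyline <- function(track, side, detoured, mobile_len, detour_len) {
  ## square maze corners, counter-clockwise; track-local coordinate runs along
  ## the polyline. The U-shape detour replaces the middle `mobile_len` piece by
  ## three `detour_len`/3 pieces folded toward the maze interior.
  corners <- rbind(c(0, 0), c(side, 0), c(side, side), c(0, side), c(0, 0))
  p0 <- corners[track, ]
  p1 <- corners[track + 1, ]
  u <- (p1 - p0) / side            # along-track unit vector
  v <- c(-u[2], u[1])              # inward normal (CCW square interior is left)
  if (!detoured) {
    return(rbind(p0, p1))
  }
  leg <- detour_len / 3
  a <- p0 + u * (side - mobile_len) / 2
  b <- p0 + u * (side + mobile_len) / 2
  rbind(p0, a, a + v * leg, b + v * leg, b, p1)
}

polyline_length <- function(pl) {
  sum(sqrt(rowSums((pl[-1, , drop = FALSE] - pl[-nrow(pl), , drop = FALSE])^2)))
}

#' Maze configuration for the square detour maze
#'
#' Four connected linear tracks of `side` cm form a square. On the detoured
#' track the removable middle `mobile_length` piece is replaced by a U-shaped
#' `detour_length` segment; the flanking `stationary_length` pieces are
#' unchanged. Linear offsets concatenate tracks T1..T4.
#'
#' @param detoured_track integer 1..4 or `NULL` for the plain square.
#' @param side track length in cm (150).
#' @param mobile_length removable middle segment length in cm (50).
#' @param detour_length U-shape detour segment length in cm (150).
#' @param stationary_length flanking stationary segment length in cm (50).
#' @param session_id optional label carried in metadata.
#' @return object of class `maze_config` with per-track polylines, lengths,
#'   segment tables, linear offsets and corner linear positions.
#' @export
maze_config <- function(detoured_track = NULL, side = 150, mobile_length = 50,
                        detour_length = 150, stationary_length = 50,
                        session_id = NULL) {
  stopifnot(side > 2 * stationary_length)
  if (!is.null(detoured_track)) stopifnot(detoured_track %in% 1:4)
  tracks <- lapply(1:4, function(k) {
    det <- !is.null(detoured_track) && k == detoured_track
    pl <- track_polyline(k, side, det, mobile_length, detour_length)
    len <- polyline_length(pl)
    mid_len <- if (det) detour_length else side - 2 * stationary_length
    seg <- data.frame(
      segment = c("first_stationary", if (det) "detour" else "mobile",
                  "last_stationary"),
      start = c(0, stationary_length, stationary_length + mid_len),
      stop  = c(stationary_length, stationary_length + mid_len, len),
      stringsAsFactors = FALSE)
    list(polyline = pl, length = len, detoured = det, segments = seg)
  })
  lens <- vapply(tracks, function(tr) tr$length, numeric(1))
  offsets <- cumsum(c(0, lens))[1:4]
  structure(list(tracks = tracks, side = side, mobile_length = mobile_length,
                 detour_length = detour_length,
                 stationary_length = stationary_length,
                 detoured_track = detoured_track,
                 offsets = offsets, total_length = sum(lens),
                 corners = offsets, session_id = session_id),
            class = "maze_config")
}

project_to_polyline <- function(x, y, pl) {
  ## squared distance + arclength of the closest point on a polyline
  n <- nrow(pl) - 1L
  best_d2 <- rep(Inf, length(x)); best_s <- rep(NA_real_, length(x))
  s0 <- 0
  for (k in seq_len(n)) {
    a <- pl[k, ]; b <- pl[k + 1L, ]
    ab <- b - a; len <- sqrt(sum(ab^2))
    t <- ((x - a[1]) * ab[1] + (y - a[2]) * ab[2]) / (len^2)
    t <- pmin(pmax(t, 0), 1)
    px <- a[1] + t * ab[1]; py <- a[2] + t * ab[2]
    d2 <- (x - px)^2 + (y - py)^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_s[upd] <- s0 + t[upd] * len
    s0 <- s0 + len
  }
  list(d = sqrt(best_d2), s = best_s)
}

#' Collapse 2D positions onto the linear maze coordinate
#'
#' Each sample is snapped perpendicularly onto the nearest track polyline.
#' Samples farther than `tol` from every track are flagged invalid (excluded
#' downstream rather than clamped). Ties at corners go to the lower-indexed
#' track.
#'
#' @param x,y position samples in cm.
#' @param maze a `maze_config`.
#' @param tol maximum snap distance in cm.
#' @return data.frame with `lin` (cm on the concatenated coordinate), `track`,
#'   `track_pos` (cm within the track), `segment`, `dist` and `valid`.
#' @export
linearize <- function(x, y, maze, tol = 10) {
  stopifnot(inherits(maze, "maze_config"), length(x) == length(y))
  proj <- lapply(maze$tracks, function(tr) project_to_polyline(x, y, tr$polyline))
  dmat <- vapply(proj, function(p) p$d, numeric(length(x)))
  dmat <- matrix(dmat, nrow = length(x))
  best <- max.col(-dmat, ties.method = "first")   # lower track index wins ties
  dist <- dmat[cbind(seq_along(x), best)]
  tpos <- vapply(seq_along(x), function(i) proj[[best[i]]]$s[i], numeric(1))
  lin <- maze$offsets[best] + tpos
  segment <- character(length(x))
  for (k in 1:4) {
    idx <- which(best == k)
    if (!length(idx)) next
    seg <- maze$tracks[[k]]$segments
    bin <- findInterval(tpos[idx], c(seg$start, Inf), rightmost.closed = FALSE)
    bin <- pmin(pmax(bin, 1L), nrow(seg))
    segment[idx] <- seg$segment[bin]
  }
  valid <- dist <= tol
  data.frame(lin = lin, track = best, track_pos = tpos, segment = segment,
             dist = dist, valid = valid, stringsAsFactors = FALSE)
}

#' Trajectory session from position samples
#'
#' Builds the 30 Hz linearized trajectory: velocity from the smoothed linear
#' coordinate (wrap-aware on the closed maze), direction labels (dir1 =
#' increasing linear coordinate, i.e. clockwise on the maze as mounted), and
#' lap counters if supplied by the generator.
#'
#' @param t sample times in seconds, strictly increasing.
#' @param x,y 2D position in cm.
#' @param maze `maze_config`.
#' @param lap optional integer lap index per sample.
#' @param tol snap tolerance forwarded to [linearize()].
#' @return data.frame of class `trajectory_session`; maze kept as attribute.
#' @export
trajectory_session <- function(t, x, y, maze, lap = NULL, tol = 10) {
  t <- as.numeric(t)
  if (is.unsorted(t, strictly = TRUE)) stop("trajectory_session: t not strictly increasing")
  linf <- linearize(x, y, maze, tol = tol)
  L <- maze$total_length
  dlin <- diff(linf$lin)
  dlin <- ((dlin + L / 2) %% L) - L / 2          # wrap-aware displacement
  v <- c(abs(dlin) / diff(t), 0)
  v[length(v)] <- v[length(v) - 1L]
  if (length(v) >= 7) v <- stats::filter(v, rep(1 / 7, 7), sides = 2)
  v <- as.numeric(v)
  v[is.na(v)] <- 0
  dirn <- ifelse(c(dlin, dlin[length(dlin)]) >= 0, "dir1", "dir2")
  out <- data.frame(t = t, x = x, y = y, lin = linf$lin, track = linf$track,
                    track_pos = linf$track_pos, segment = linf$segment,
                    velocity = v, direction = dirn, valid = linf$valid,
                    stringsAsFactors = FALSE)
  if (!is.null(lap)) out$lap <- as.integer(lap)
  attr(out, "maze") <- maze
  class(out) <- c("trajectory_session", "data.frame")
  out
}

#' LFP channel container
#'
#' @param samples microvolt samples at uniform rate.
#' @param rate sampling rate in Hz (>= 1000 so theta and ripples resolve).
#' @param t0 time of first sample (s).
#' @return object of class `lfp_channel` with a `t()`-style accessor field.
#' @export
lfp_channel <- function(samples, rate, t0 = 0) {
  if (rate < 1000) stop("lfp_channel: rate must be >= 1000 Hz")
  structure(list(samples = as.numeric(samples), rate = rate, t0 = t0),
            class = "lfp_channel")
}

#' Time axis of an LFP channel
#' @param lfp an `lfp_channel`.
#' @return numeric vector of sample times (s).
#' @export
lfp_times <- function(lfp) lfp$t0 + (seq_along(lfp$samples) - 1) / lfp$rate

#' Assemble an ordered session set
#'
#' Sessions alternate sleep and run (Sleep1, Run1, ... Sleep4, Run4). The unit
#' registry must be identical across sessions (stable-cluster assumption).
#'
#' @param sessions named list; each element is a list with fields `name`,
#'   `type` ("run" or "sleep"), `spikes` (`spike_ensemble`), `maze`
#'   (`maze_config`), and for runs `trajectory`; `lfp` optional.
#' @return object of class `session_set`.
#' @export
session_set <- function(sessions) {
  stopifnot(length(sessions) >= 1)
  nm <- vapply(sessions, function(s) s$name, character(1))
  names(sessions) <- nm
  reg <- NULL
  for (s in sessions) {
    if (!inherits(s$spikes, "spike_ensemble")) {
      stop("session ", s$name, ": spikes must be a spike_ensemble")
    }
    ids <- unit_ids(s$spikes)
    if (is.null(reg)) reg <- ids
    else if (!identical(sort(reg), sort(ids))) {
      stop("unit ID mismatch across sessions at ", s$name)
    }
    tmax <- session_duration(s)
    for (u in s$spikes) {
      if (length(u$times) && (min(u$times) < 0 || max(u$times) > tmax + 1e-9)) {
        stop("spike time outside session bounds: unit ", u$unit_id,
             " in session ", s$name)
      }
    }
  }
  structure(list(sessions = sessions, units = sort(reg)), class = "session_set")
}

session_duration <- function(s) {
  if (!is.null(s$duration)) return(s$duration)
  cand <- c(if (!is.null(s$trajectory)) max(s$trajectory$t),
            if (!is.null(s$lfp)) max(lfp_times(s$lfp)))
  if (!length(cand)) {
    cand <- max(0, unlist(lapply(s$spikes, function(u) u$times)))
  }
  max(cand)
}

num17 <- function(x) sprintf("%.17g", x)

#' Write a session set as plain-text files
#'
#' One sub-directory per session holding `spikes.csv` (unit, time, label),
#' `position.csv`, `lfp.csv`, and a top-level `sessions.yaml` with the session
#' order, maze parameters and durations. Floats are serialized with 17
#' significant digits so a read-back is bit-exact.
#'
#' @param set a `session_set`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_session_set <- function(set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(sessions = list())
  for (s in set$sessions) {
    sd <- file.path(dir, s$name)
    dir.create(sd, showWarnings = FALSE)
    sp <- do.call(rbind, lapply(s$spikes, function(u) {
      if (!length(u$times)) return(NULL)
      data.frame(unit = u$unit_id, time = num17(u$times), label = u$label,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(sp)) sp <- data.frame(unit = character(), time = character(),
                                      label = character())
    utils::write.csv(sp, file.path(sd, "spikes.csv"), row.names = FALSE, quote = FALSE)
    if (!is.null(s$trajectory)) {
      tr <- s$trajectory
      pos <- data.frame(t = num17(tr$t), x = num17(tr$x), y = num17(tr$y))
      if (!is.null(tr$lap)) pos$lap <- tr$lap
      utils::write.csv(pos, file.path(sd, "position.csv"), row.names = FALSE, quote = FALSE)
    }
    if (!is.null(s$lfp)) {
      utils::write.csv(data.frame(sample = num17(s$lfp$samples)),
                       file.path(sd, "lfp.csv"), row.names = FALSE)
    }
    mz <- if (!is.null(s$maze)) s$maze else NULL
    meta$sessions[[s$name]] <- list(
      name = s$name, type = s$type, duration = session_duration(s),
      lfp_rate = if (!is.null(s$lfp)) s$lfp$rate else NULL,
      lfp_t0 = if (!is.null(s$lfp)) s$lfp$t0 else NULL,
      detoured_track = if (!is.null(mz)) mz$detoured_track else NULL)
  }
  meta$units <- as.list(set$units)
  labs <- vapply(set$sessions[[1]]$spikes, function(u) u$label, character(1))
  meta$labels <- as.list(labs[set$units])
  yaml::write_yaml(meta, file.path(dir, "sessions.yaml"))
  invisible(dir)
}

#' Read a session set written by [write_session_set()]
#'
#' @param dir directory produced by [write_session_set()].
#' @return a `session_set`.
#' @export
read_session_set <- function(dir) {
  meta_path <- file.path(dir, "sessions.yaml")
  if (!file.exists(meta_path)) stop("no sessions.yaml in ", dir)
  meta <- yaml::read_yaml(meta_path)
  units <- unlist(meta$units)
  labels <- unlist(meta$labels)
  sessions <- lapply(meta$sessions, function(m) {
    sd <- file.path(dir, m$name)
    if (!dir.exists(sd)) stop("session ", m$name, " absent")
    sp <- utils::read.csv(file.path(sd, "spikes.csv"),
                          colClasses = c("character", "numeric", "character"))
    trains <- lapply(seq_along(units), function(i) {
      spike_train(units[i], sp$time[sp$unit == units[i]], labels[i])
    })
    maze <- maze_config(detoured_track = m$detoured_track)
    s <- list(name = m$name, type = m$type, spikes = spike_ensemble(trains),
              maze = maze, duration = m$duration)
    pos_path <- file.path(sd, "position.csv")
    if (file.exists(pos_path)) {
      pos <- utils::read.csv(pos_path)
      s$trajectory <- trajectory_session(pos$t, pos$x, pos$y, maze,
                                         lap = pos$lap)
    }
    lfp_path <- file.path(sd, "lfp.csv")
    if (file.exists(lfp_path) && !is.null(m$lfp_rate)) {
      lf <- utils::read.csv(lfp_path)
      s$lfp <- lfp_channel(lf$sample, m$lfp_rate,
                           if (is.null(m$lfp_t0)) 0 else m$lfp_t0)
    }
    s
  })
  session_set(sessions)
}

#' Load and validate a session set from disk
#'
#' Thin wrapper over [read_session_set()] that checks for the sessions named
#' in the experiment config.
#'
#' @param path directory containing the container.
#' @param required character vector of session names that must exist.
#' @return a validated `session_set`.
#' @export
load_session_set <- function(path, required = NULL) {
  set <- read_session_set(path)
  if (!is.null(required)) {
    missing <- setdiff(required, names(set$sessions))
    if (length(missing)) stop("session ", missing[1], " absent")
  }
  set
}
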