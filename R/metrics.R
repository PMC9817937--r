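# Per-rep behavioral measures: distance to targets, zone assignment,
# pre/post analysis windows, swim speed, darts, turning, and operant success
# scoring.

#' Analysis windows relative to stimulus onset
#'
#' Defaults follow the standard pre/post layout: PRE is the 1 s before sound
#' onset, POST2 and POST3 are the second and third seconds after onset.
#' Frame assignment uses half-open intervals `[start, end)` on frame
#' timestamps so no frame is counted twice.
#'
#' @param pre `(start, end)` seconds relative to onset, default `c(-1, 0)`.
#' @param post named list of `(start, end)` pairs, default
#'   `list(POST2 = c(1, 2), POST3 = c(2, 3))`.
#' @return a `window_spec` object (named list of intervals including `PRE`).
#' @export
window_spec <- function(pre = c(-1, 0),
                        post = list(POST2 = c(1, 2), POST3 = c(2, 3))) {
  wins <- c(list(PRE = as.numeric(pre)), lapply(post, as.numeric))
  for (nm in names(wins)) {
    w <- wins[[nm]]
    if (length(w) != 2 || !all(is.finite(w)) || w[2] <= w[1])
      stopf("window '%s' must be a finite (start, end) with end > start", nm)
  }
  ints <- do.call(rbind, wins)
  o <- order(ints[, 1])
  if (any(ints[o, 2][-nrow(ints)] > ints[o, 1][-1] + 1e-9))
    stopf("analysis windows must not overlap")
  structure(wins, class = "window_spec")
}

#' Per-frame distance to a target point or plane
#'
#' Euclidean distance to a point, or unsigned perpendicular distance to a
#' vertical plane (a chord, e.g. the divider plane or the boundary of the
#' target half).  Missing positions yield missing distances.
#'
#' @param traj a [trajectory_table()].
#' @param target either `(x, y)` in cm, or a plane
#'   `list(angle = <port angle deg>, offset = <cm from center>)` perpendicular
#'   to the port direction.
#' @return data.frame `frame`, `time`, `id`, `distance` (cm).
#' @export
distance_series <- function(traj, target) {
  stopifnot(inherits(traj, "trajectory_table"))
  if (is.list(target) && !is.null(target$angle)) {
    th <- target$angle * pi / 180
    off <- target$offset %||% 0
    d <- abs(traj$x * cos(th) + traj$y * sin(th) - off)
  } else {
    if (!is.numeric(target) || length(target) != 2)
      stopf("target must be (x, y) or list(angle=, offset=)")
    d <- sqrt((traj$x - target[1])^2 + (traj$y - target[2])^2)
  }
  data.frame(frame = traj$frame, time = traj$time, id = traj$id, distance = d)
}

#' Assign each frame to a distance zone
#'
#' Zone 1 is closest to the active feeder port: zone 1 iff
#' `distance < boundary1`, zone 2 iff `boundary1 <= distance < boundary2`,
#' else zone 3.
#'
#' @param traj a [trajectory_table()].
#' @param tank a [tank_geometry()].
#' @param port active port index.
#' @return data.frame `frame`, `time`, `id`, `distance`, `zone`.
#' @export
assign_zones <- function(traj, tank, port = 1) {
  d <- distance_series(traj, port_location(tank, port))
  b <- tank$zone_boundaries
  d$zone <- ifelse(d$distance < b[1], 1L, ifelse(d$distance < b[2], 2L, 3L))
  d
}

#' Per-window summaries of a distance (or any per-frame) series
#'
#' Frames are assigned to analysis windows by their time relative to
#' sound-playback onset (taken from the rep's event log); summaries ignore
#' missing frames, and a window containing no frames yields a missing
#' summary.
#'
#' @param series data.frame from [distance_series()] (columns `time`, `id`,
#'   and a value column).
#' @param events event log of the rep (must contain a `stimulus_on` with a
#'   sound stimulus, else an error).
#' @param windows a [window_spec()].
#' @param value name of the value column (default `"distance"`).
#' @return data.frame `id`, `window`, `n`, `mean`, `median`.
#' @export
window_stats <- function(series, events, windows = window_spec(),
                         value = "distance") {
  stopifnot(inherits(windows, "window_spec"))
  onset <- sound_onset_from_events(events)
  rel <- series$time - onset
  out <- list()
  for (ind in unique(series$id)) {
    sel_i <- series$id == ind
    for (nm in names(windows)) {
      w <- windows[[nm]]
      sel <- sel_i & rel >= w[1] & rel < w[2]
      v <- series[[value]][sel]
      v <- v[!is.na(v)]
      out[[length(out) + 1L]] <- data.frame(
        id = ind, window = nm, n = length(v),
        mean = if (length(v)) mean(v) else NA_real_,
        median = if (length(v)) median(v) else NA_real_)
    }
  }
  res <- do.call(rbind, out)
  res$window <- factor(res$window, levels = names(windows))
  res
}

sound_onset_from_events <- function(events) {
  on <- events[events$kind == "stimulus_on", , drop = FALSE]
  if (nrow(on) > 0) {
    mod <- payload_field(on$payload, "modality")
    on <- on[!is.na(mod) & mod == "sound", , drop = FALSE]
  }
  if (nrow(on) == 0) stopf("no sound stimulus_on event in this rep")
  min(on$t)
}

#' Per-frame swim speed and dart count
#'
#' Speed is the frame-to-frame displacement times the frame rate.  A *dart*
#' is a maximal run of consecutive frames with speed above `dart_threshold`,
#' counted once per run; darts are a standard arousal indicator.
#'
#' @param traj a [trajectory_table()] with at least 2 frames per individual.
#' @param dart_threshold cm/s; the default, 12 cm/s, is three times the
#'   default cruising speed.
#' @return list with `speed` (data.frame `frame`, `time`, `id`, `speed`; the
#'   first frame of each individual has no speed) and `darts` (data.frame
#'   `id`, `darts`).
#' @export
speed_and_darts <- function(traj, dart_threshold = 12) {
  stopifnot(inherits(traj, "trajectory_table"))
  fr <- attr(traj, "frame_rate")
  sp <- list(); dt <- list()
  for (ind in unique(traj$id)) {
    tr <- traj[traj$id == ind, ]
    tr <- tr[order(tr$frame), ]
    if (nrow(tr) < 2) stopf("individual %s has fewer than 2 frames", ind)
    v <- sqrt(diff(tr$x)^2 + diff(tr$y)^2) * fr
    sp[[length(sp) + 1L]] <- data.frame(frame = tr$frame[-1], time = tr$time[-1],
                                        id = ind, speed = v)
    above <- !is.na(v) & v > dart_threshold
    runs <- rle(above)
    dt[[length(dt) + 1L]] <- data.frame(id = ind,
                                        darts = sum(runs$values, na.rm = TRUE))
  }
  list(speed = do.call(rbind, sp), darts = do.call(rbind, dt))
}

#' Per-frame turning and turn frequency
#'
#' Headings are taken from successive displacement vectors; the per-frame
#' heading change is wrapped to `(-180, 180]` so a 179 to -179 degree
#' transition counts as a 2 degree turn, not 358.  A *turn* is a frame whose
#' absolute heading change exceeds `turn_threshold`.
#'
#' @param traj a [trajectory_table()] with at least 3 frames per individual.
#' @param turn_threshold degrees/frame (default 30).
#' @return list with `turning` (data.frame `frame`, `time`, `id`,
#'   `turn_deg`: absolute heading change) and `rate` (data.frame `id`,
#'   `turns_per_s`).
#' @export
turning_rate <- function(traj, turn_threshold = 30) {
  stopifnot(inherits(traj, "trajectory_table"))
  fr <- attr(traj, "frame_rate")
  tu <- list(); ra <- list()
  for (ind in unique(traj$id)) {
    tr <- traj[traj$id == ind, ]
    tr <- tr[order(tr$frame), ]
    if (nrow(tr) < 3) stopf("individual %s has fewer than 3 frames", ind)
    dx <- diff(tr$x); dy <- diff(tr$y)
    h <- atan2(dy, dx) * 180 / pi
    dh <- diff(h)
    dh <- ((dh + 180) %% 360) - 180
    dh[dh == -180] <- 180  # wrap to (-180, 180]
    tu[[length(tu) + 1L]] <- data.frame(frame = tr$frame[-(1:2)],
                                        time = tr$time[-(1:2)], id = ind,
                                        turn_deg = abs(dh))
    n_turn <- sum(!is.na(dh) & abs(dh) > turn_threshold)
    span <- (nrow(tr) - 1) / fr
    ra[[length(ra) + 1L]] <- data.frame(id = ind, turns_per_s = n_turn / span)
  }
  list(turning = do.call(rbind, tu), rate = do.call(rbind, ra))
}

#' Score an operant rep as success (1) or failure (0)
#'
#' Success means a correct-sensor trigger occurred inside the response
#' window.  Classical reps have no trigger contingency and are an error here
#' (use [window_stats()] proximity analysis instead).
#'
#' @param result a `rep_result` from [run_rep()].
#' @return integer 0 or 1.
#' @export
score_rep <- function(result) {
  stopifnot(inherits(result, "rep_result"))
  if (result$paradigm != "operant")
    stopf("score_rep is defined for operant reps only (got classical)")
  result$success
}
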