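# Discrete-event conditioning engine: executes rep templates against the
# virtual tank, enforcing classical (fixed-delay feed) vs operant
# (sensor-gated, time-limited window) reward logic, and emits canonical
# event logs plus frame-sampled trajectories.
#
# The engine runs on a virtual clock: multi-day schedules execute instantly
# and wall times are computed, never slept.  Recording onset (t = 0) is the
# reference point for all delay-based actions within a rep.

EVENT_KINDS <- c("rep_start", "record_start", "record_stop", "stimulus_on",
                 "stimulus_off", "sensor_high", "sensor_low",
                 "arm_move_start", "arm_move_end", "feed", "window_open",
                 "window_close", "rep_end")

# canonical tie-break at equal t: sensor < stimulus < feeder < recorder,
# with rep_start first and rep_end last so logs are byte-stable.
event_priority <- function(kind) {
  unname(c(rep_start = 0, sensor_high = 1, sensor_low = 1,
           stimulus_on = 2, stimulus_off = 2,
           arm_move_start = 3, arm_move_end = 3, feed = 3,
           window_open = 3, window_close = 3,
           record_start = 4, record_stop = 4, rep_end = 5)[kind])
}

#' Engine configuration
#'
#' @param tick simulation step, seconds; must not exceed one frame interval.
#'   The default equals the frame interval so one simulation step is one
#'   video frame.
#' @param frame_rate trajectory sampling rate, frames/second (default 30).
#' @param feed_latency seconds from a correct trigger to the food drop; the
#'   apparatus contract is at most 1 s (default 0.5).
#' @param rng_seed integer master seed; every stream the engine uses is
#'   derived from it.
#' @return an `engine_config` object.
#' @export
engine_config <- function(tick = 1 / 30, frame_rate = 30, feed_latency = 0.5,
                          rng_seed = 1) {
  if (!is.numeric(tick) || tick <= 0) stopf("'tick' must be > 0")
  if (!is.numeric(frame_rate) || frame_rate <= 0) stopf("'frame_rate' must be > 0")
  if (tick > 1 / frame_rate + 1e-12)
    stopf("'tick' must be <= 1 / frame_rate")
  if (!is.numeric(feed_latency) || feed_latency < 0 || feed_latency > 1)
    stopf("'feed_latency' must lie in [0, 1] seconds")
  structure(list(tick = as.numeric(tick), frame_rate = as.numeric(frame_rate),
                 feed_latency = as.numeric(feed_latency),
                 rng_seed = as.integer(rng_seed)),
            class = "engine_config")
}

#' Rotate the feeder arm along the shortest arc
#'
#' @param current_angle,target_angle degrees.
#' @param speed degrees/second (> 0).
#' @param t0 time (s) at which the move starts.
#' @return list with `duration` (seconds, shortest-arc distance / speed) and
#'   `events` (arm_move_start / arm_move_end rows; emitted back-to-back when
#'   no movement is needed).
#' @export
move_arm <- function(current_angle, target_angle, speed, t0 = 0) {
  if (speed <= 0) stopf("'speed' must be > 0")
  d <- abs(((target_angle - current_angle + 180) %% 360) - 180)
  duration <- d / speed
  events <- data.frame(
    t = c(t0, t0 + duration),
    kind = c("arm_move_start", "arm_move_end"),
    payload = sprintf("angle=%g", c(current_angle, target_angle)),
    stringsAsFactors = FALSE)
  list(duration = duration, events = events)
}

agent_V <- function(agent, stimulus_id) {
  v <- agent$state$V[stimulus_id]
  if (is.null(v) || is.na(v)) agent$params$V0 else unname(v)
}

# which port the template's reward location corresponds to (nearest port
# angle to the arm target).
target_port_index <- function(template, tank) {
  d <- abs(((tank$port_angles - template$arm_angle + 180) %% 360) - 180)
  which.min(d)
}

sound_onset_of <- function(template) {
  snd <- Filter(function(s) s$modality == "sound", template$stimuli)
  if (length(snd) == 0) return(NA_real_)
  min(vapply(snd, `[[`, numeric(1), "onset_delay"))
}

# ---- shared kinematics core ----------------------------------------------
# Simulates all agent paths for one rep and resolves the reward logic.
# Both run_rep() (full event log) and simulate_operant_series() (score-only
# fast path) call this with identical derived seeds, so their outcomes agree
# exactly.
rep_core <- function(template, tank, agents, config, seed,
                     arm_start_angle = template$arm_angle) {
  if (length(agents) == 0) stopf("agent list must not be empty")
  tick <- config$tick
  arm <- move_arm(arm_start_angle, template$arm_angle, template$arm_speed, 0)
  sound_onset <- sound_onset_of(template)
  operant <- template$paradigm == "operant"

  if (operant) {
    window_open <- sound_onset
    window_close_max <- sound_onset + template$response_window
    horizon <- max(window_close_max, arm$duration) + config$feed_latency +
      template$record_end_delay
  } else {
    feed_sched <- template$food_delay
    horizon <- max(feed_sched, arm$duration) + template$record_end_delay
  }
  stim_off_max <- if (length(template$stimuli) > 0)
    max(vapply(template$stimuli, function(s) s$onset_delay + s$duration,
               numeric(1))) else 0
  n_steps <- ceiling((horizon + 1e-9) / tick)
  t_steps <- seq(0, n_steps) * tick

  # per-tick stimulus activity (shared across agents)
  active <- matrix(FALSE, n_steps, length(template$stimuli))
  for (j in seq_along(template$stimuli)) {
    s <- template$stimuli[[j]]
    active[, j] <- t_steps[-length(t_steps)] >= s$onset_delay &
      t_steps[-length(t_steps)] < s$onset_delay + s$duration
  }
  stim_on <- as.integer(rowSums(active) > 0)
  port <- target_port_index(template, tank)

  paths <- vector("list", length(agents))
  sensor_high <- NULL  # per-step logical matrix (any agent) per sensor
  for (k in seq_along(agents)) {
    ag <- agents[[k]]
    w_stim <- vapply(seq_along(template$stimuli), function(j) {
      s <- template$stimuli[[j]]
      if (s$rewarded) bias_weight(agent_V(ag, s$stimulus_id), ag$state$satiation)
      else 0
    }, numeric(1))
    bias_w <- if (length(w_stim) == 0) numeric(n_steps)
              else apply(active, 1, function(a) if (any(a)) max(w_stim[a]) else 0)
    m <- with_seed(derive_seed(seed, "path", ag$id),
                   simulate_path(ag, n_steps, tick, stim_on, bias_w, tank, port))
    paths[[k]] <- m
    sh <- sense_frames(m[, 1:2, drop = FALSE], tank)
    sensor_high <- if (is.null(sensor_high)) sh else sensor_high | sh
  }

  # reward resolution
  trigger_t <- NA_real_; fed <- FALSE; feed_t <- NA_real_
  feed_delayed_by_arm <- FALSE
  if (operant) {
    tgt <- template$target_sensor
    if (!tgt %in% colnames(sensor_high))
      stopf("target_sensor '%s' is not a sensor in this tank", tgt)
    col <- sensor_high[, tgt]
    rising <- which(col & !c(FALSE, col[-length(col)]))
    tr <- t_steps[rising]
    tr <- tr[tr >= window_open & tr <= window_close_max]
    if (length(tr) > 0) {
      trigger_t <- tr[1]
      fed <- TRUE
      feed_t <- trigger_t + config$feed_latency
      if (feed_t < arm$duration) { feed_t <- arm$duration; feed_delayed_by_arm <- TRUE }
      # the window closes once the reward sequence completes, so the feed
      # always falls inside [window_open, window_close]
      window_close <- feed_t
    } else {
      window_close <- window_close_max
    }
    t_stop <- if (fed) feed_t + template$record_end_delay
              else window_close + template$record_end_delay
  } else {
    fed <- TRUE
    feed_t <- feed_sched
    if (feed_t < arm$duration) { feed_t <- arm$duration; feed_delayed_by_arm <- TRUE }
    window_open <- NA_real_; window_close <- NA_real_
    t_stop <- feed_t + template$record_end_delay
  }
  grains <- if (fed) {
    lambda <- if (template$feed_mode == "enhanced") 5 else 3
    with_seed(derive_seed(seed, "feed"), rpois(1, lambda))
  } else 0L

  list(paths = paths, sensor_high = sensor_high, t_steps = t_steps,
       n_steps = n_steps, stim_on = stim_on, arm = arm,
       sound_onset = sound_onset, operant = operant,
       window_open = window_open, window_close = window_close,
       trigger_t = trigger_t, fed = fed, feed_t = feed_t, grains = grains,
       feed_delayed_by_arm = feed_delayed_by_arm, t_stop = t_stop,
       target_port = port)
}

# association + satiation bookkeeping after a rep
apply_rep_outcome <- function(agents, template, fed, grains) {
  lapply(agents, function(ag) {
    p <- ag$params
    for (s in template$stimuli) {
      v0 <- agent_V(ag, s$stimulus_id)
      ag$state$V[s$stimulus_id] <-
        update_association(v0, s$rewarded && fed, p$alpha, p$lam)
    }
    if (fed) ag$state$satiation <- ag$state$satiation + grains * p$satiation_decay
    ag
  })
}

# satiation recovery over a wall-clock gap (hours), applied between reps
recover_satiation <- function(agents, gap_hours) {
  lapply(agents, function(ag) {
    hl <- ag$params$satiation_half_life
    if (hl > 0)
      ag$state$satiation <- ag$state$satiation * 0.5^(gap_hours / hl)
    ag
  })
}

#' Execute a single conditioning rep
#'
#' Realizes the rep timeline as an event log: recording starts at t = 0,
#' stimuli switch on/off at their configured delays and durations, and the
#' reward logic is enforced per paradigm.  Operant: the response window opens
#' at sound-playback onset and closes after `response_window` seconds; the
#' first correct in-window sensor trigger produces a feed within the feed
#' latency and closes the window; with no trigger the rep ends unrewarded.
#' Classical: food is dropped unconditionally at `food_delay`.  Recording
#' stops `record_end_delay` seconds after the feed (or after window close if
#' no feed occurred).  If a feed is requested while the arm is still moving,
#' the feed waits for the arm and the feed event carries a
#' `warning=arm_moving` payload.
#'
#' @param template a validated [rep_template()].
#' @param tank a [tank_geometry()].
#' @param agents nonempty cohort from [make_cohort()].
#' @param config an [engine_config()].
#' @param seed integer seed for this rep (all agent paths and the feed draw
#'   derive from it).
#' @param rep_index integer rep label.
#' @param wall_start POSIXct wall time of recording onset.
#' @param arm_start_angle arm position (degrees) when the rep begins.
#' @return a `rep_result`: success flag (operant), trigger latency, feed
#'   status, event log (data.frame `t`, `wall_time`, `kind`, `payload`),
#'   frame-sampled trajectory, and the updated agents.
#' @export
run_rep <- function(template, tank, agents, config, seed = config$rng_seed,
                    rep_index = 1L,
                    wall_start = as.POSIXct("2026-01-05 08:00:00", tz = "UTC"),
                    arm_start_angle = template$arm_angle) {
  stopifnot(inherits(template, "rep_template"), inherits(tank, "tank_geometry"),
            inherits(config, "engine_config"))
  core <- rep_core(template, tank, agents, config, seed, arm_start_angle)
  t_stop <- core$t_stop

  ev <- list()
  add <- function(t, kind, payload = "") {
    ev[[length(ev) + 1L]] <<- data.frame(t = t, kind = kind, payload = payload,
                                         stringsAsFactors = FALSE)
  }
  add(0, "rep_start", sprintf("rep_index=%d", rep_index))
  add(0, "record_start")
  for (i in seq_len(nrow(core$arm$events)))
    add(core$arm$events$t[i], core$arm$events$kind[i], core$arm$events$payload[i])

  for (s in template$stimuli) {
    if (s$onset_delay <= t_stop) {
      add(s$onset_delay, "stimulus_on",
          sprintf("stimulus_id=%s,modality=%s,channel=%s",
                  s$stimulus_id, s$modality, s$channel))
      add(min(s$onset_delay + s$duration, t_stop), "stimulus_off",
          sprintf("stimulus_id=%s", s$stimulus_id))
    }
  }

  # sensor transitions (always-on sensors; any agent breaks the beam)
  sh <- core$sensor_high
  keep <- core$t_steps <= t_stop
  for (sid in colnames(sh)) {
    col <- sh[, sid]
    prev <- c(FALSE, col[-length(col)])
    up <- which(col & !prev); down <- which(!col & prev)
    for (i in up) if (keep[i])
      add(core$t_steps[i], "sensor_high", sprintf("sensor_id=%s", sid))
    for (i in down) if (keep[i])
      add(core$t_steps[i], "sensor_low", sprintf("sensor_id=%s", sid))
  }

  if (core$fed) {
    payload <- sprintf("feed_mode=%s,grains=%d", template$feed_mode, core$grains)
    if (core$feed_delayed_by_arm) payload <- paste0(payload, ",warning=arm_moving")
    add(core$feed_t, "feed", payload)
  }
  if (core$operant) {
    add(core$window_open, "window_open",
        sprintf("sensor_id=%s", template$target_sensor))
    add(core$window_close, "window_close",
        if (core$fed) "reason=triggered" else "reason=timeout")
  }
  add(t_stop, "record_stop")
  add(t_stop, "rep_end", sprintf("rep_index=%d", rep_index))

  events <- do.call(rbind, ev)
  o <- order(events$t, event_priority(events$kind), seq_len(nrow(events)))
  events <- events[o, , drop = FALSE]
  events$wall_time <- fmt_wall(wall_start + events$t)
  events <- events[, c("t", "wall_time", "kind", "payload")]
  rownames(events) <- NULL

  # frame-sampled trajectory up to record_stop
  fr <- config$frame_rate
  n_frames <- floor(t_stop * fr + 1e-9) + 1L
  f_idx <- seq_len(n_frames) - 1L
  step_idx <- pmin(round(f_idx / fr / config$tick), core$n_steps) + 1L
  traj <- do.call(rbind, lapply(seq_along(agents), function(k) {
    m <- core$paths[[k]]
    data.frame(frame = f_idx, time = f_idx / fr, id = agents[[k]]$id,
               x = m[step_idx, 1], y = m[step_idx, 2])
  }))
  traj <- trajectory_table(traj, frame_rate = fr)

  agents_out <- apply_rep_outcome(agents, template, core$fed, core$grains)
  structure(list(
    rep_index = as.integer(rep_index), paradigm = template$paradigm,
    success = if (core$operant) as.integer(core$fed) else NA_integer_,
    trigger_latency = if (core$operant && core$fed)
      core$trigger_t - core$sound_onset else NA_real_,
    fed = core$fed, grains = core$grains,
    sound_onset = core$sound_onset,
    window = c(open = core$window_open, close = core$window_close),
    duration = t_stop, events = events, trajectory = traj,
    agents = agents_out, seed = as.integer(seed),
    arm_angle = template$arm_angle),
    class = "rep_result")
}

#' @export
print.rep_result <- function(x, ...) {
  cat(sprintf("<rep_result %d> %s, %.1f s, %d events, fed=%s%s\n",
              x$rep_index, x$paradigm, x$duration, nrow(x$events), x$fed,
              if (!is.na(x$success)) sprintf(", success=%d", x$success) else ""))
  invisible(x)
}

#' Execute a full trial schedule
#'
#' Expands the schedule over the horizon and runs every rep in timeline
#' order.  Agent state (association strengths, satiation) persists across
#' reps and runs, with satiation recovering over the wall-clock gaps between
#' reps; the feeder arm keeps its position between reps.  With `out_dir`, one
#' event-log and one trajectory file are written per rep plus a session
#' manifest.
#'
#' @param schedule a `trial_schedule`.
#' @param tank a [tank_geometry()].
#' @param agents cohort from [make_cohort()].
#' @param config an [engine_config()]; all rep seeds derive from
#'   `config$rng_seed`.
#' @param origin calendar start (see [expand_trial()]).
#' @param horizon days.
#' @param out_dir optional directory for persisted logs and manifest.
#' @return list of `rep_result`s in chronological order, with attributes
#'   `score_series` (per-rep data.frame: subject-independent rep scores and
#'   cumulative hours) and `manifest` (when persisted).
#' @export
run_trial <- function(schedule, tank, agents, config, origin = "2026-01-05",
                      horizon = 1, out_dir = NULL) {
  timeline <- expand_trial(schedule, origin, horizon)
  if (nrow(timeline) == 0) stopf("expanded schedule is empty")
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  results <- list()
  arm_angle <- 0
  prev_end_wall <- NULL
  trial_origin <- timeline$start[1]
  manifest <- NULL
  rep_counter <- 0L
  for (i in seq_len(nrow(timeline))) {
    run <- timeline$run[[i]]
    wall <- timeline$start[i]
    for (k in seq_len(run$rep_count)) {
      rep_counter <- rep_counter + 1L
      if (!is.null(prev_end_wall)) {
        gap_h <- as.numeric(difftime(wall, prev_end_wall, units = "hours"))
        agents <- recover_satiation(agents, max(gap_h, 0))
      }
      seed <- derive_seed(config$rng_seed, "rep", i, k)
      res <- run_rep(run$template, tank, agents, config, seed = seed,
                     rep_index = rep_counter, wall_start = wall,
                     arm_start_angle = arm_angle)
      res$run_index <- i
      res$rep_in_run <- k
      res$wall_start <- wall
      res$time_h <- as.numeric(difftime(wall, trial_origin, units = "hours"))
      agents <- res$agents
      arm_angle <- run$template$arm_angle
      prev_end_wall <- wall + res$duration
      wall <- prev_end_wall + run$inter_rep_delay
      results[[rep_counter]] <- res
      if (!is.null(out_dir)) {
        log_path <- file.path(out_dir, sprintf("rep_%04d.log", rep_counter))
        traj_path <- file.path(out_dir, sprintf("rep_%04d.csv", rep_counter))
        write_event_log(res$events, log_path)
        write_trajectory(res$trajectory, traj_path)
        manifest <- rbind(manifest, data.frame(
          rep_id = sprintf("rep_%04d", rep_counter),
          event_log = basename(log_path), trajectory = basename(traj_path),
          schedule_hash = text_md5(serialize_schedule(schedule)),
          seed = seed, stringsAsFactors = FALSE))
      }
    }
  }
  if (!is.null(out_dir)) {
    write_manifest(manifest, file.path(out_dir, "manifest.tsv"))
    attr(results, "manifest") <- manifest
  }
  attr(results, "score_series") <- data.frame(
    rep = seq_along(results),
    time_h = vapply(results, `[[`, numeric(1), "time_h"),
    score = vapply(results, `[[`, integer(1), "success"),
    paradigm = vapply(results, `[[`, character(1), "paradigm"))
  results
}
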