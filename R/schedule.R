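# Declarative schedule model: stimuli, rep templates, runs, trial schedules;
# YAML parsing/serialization, timeline expansion, and run randomization.
#
# A *rep* is one stimulus/reward opportunity, a *run* is a block of
# consecutive reps launched at a scheduled clock time, and a *trial* is the
# full multi-day set of runs.  All within-rep timing is expressed as delays
# in seconds from recording onset, which is the engine's reference point.

MODALITIES <- c("led", "sound")
PARADIGMS <- c("classical", "operant")
FEED_MODES <- c("simple", "enhanced")

#' Specify a single stimulus presentation
#'
#' @param stimulus_id label, unique within a rep template.
#' @param modality `"led"` or `"sound"`.
#' @param channel LED color/pin label or sound-file label.
#' @param onset_delay seconds from recording start (>= 0).
#' @param duration seconds (> 0).
#' @param rewarded is this stimulus paired with food?  Sham sounds are
#'   presented with `rewarded = FALSE` to keep sound-food association
#'   specific to the trained sounds.
#' @return a `stimulus_spec` object.
#' @export
stimulus_spec <- function(stimulus_id, modality, channel,
                          onset_delay, duration, rewarded = TRUE) {
  if (!is.character(stimulus_id) || !nzchar(stimulus_id))
    stopf("stimulus_id must be a non-empty label")
  modality <- match.arg(modality, MODALITIES)
  if (!is.numeric(onset_delay) || onset_delay < 0)
    stopf("stimulus '%s': onset_delay must be >= 0", stimulus_id)
  if (!is.numeric(duration) || duration <= 0)
    stopf("stimulus '%s': duration must be > 0", stimulus_id)
  structure(list(stimulus_id = stimulus_id, modality = modality,
                 channel = as.character(channel),
                 onset_delay = as.numeric(onset_delay),
                 duration = as.numeric(duration),
                 rewarded = isTRUE(rewarded)),
            class = "stimulus_spec")
}

#' Template for one conditioning rep
#'
#' Encodes everything the engine needs to execute a single stimulus/reward
#' repetition.  Exactly one of `response_window` (operant) or `food_delay`
#' (classical) is used, per paradigm.
#'
#' @param paradigm `"classical"` or `"operant"`.
#' @param stimuli list of [stimulus_spec()] objects.  Per rep at most 3
#'   distinct LED channels and 1 sound channel may be scheduled (the
#'   controller drives up to three LEDs and one sound channel).
#' @param baseline_delay seconds of pre-stimulus observation from recording
#'   onset (default 10).
#' @param response_window operant only: seconds after sound-playback onset
#'   during which a correct sensor trigger earns food.
#' @param food_delay classical only: seconds from recording start to the
#'   unconditional food drop.
#' @param target_sensor operant only: label of the sensor that must be
#'   triggered.
#' @param arm_angle feeder-arm target in degrees, in `[0, 360)`.
#' @param arm_speed arm rotation speed, degrees/second (default 90).
#' @param feed_mode `"simple"` or `"enhanced"` feeder motion.
#' @param record_end_delay seconds of recording kept after the feed (or
#'   window close), default 5.
#' @return a `rep_template` object.
#' @export
rep_template <- function(paradigm, stimuli,
                         baseline_delay = 10,
                         response_window = NULL, food_delay = NULL,
                         target_sensor = NULL,
                         arm_angle = 0, arm_speed = 90,
                         feed_mode = "simple", record_end_delay = 5) {
  paradigm <- match.arg(paradigm, PARADIGMS)
  feed_mode <- match.arg(feed_mode, FEED_MODES)
  if (!is.list(stimuli) || (length(stimuli) > 0 &&
      !all(vapply(stimuli, inherits, logical(1), "stimulus_spec"))))
    stopf("stimuli must be a list of stimulus_spec objects")
  led_ch <- unique(vapply(Filter(function(s) s$modality == "led", stimuli),
                          `[[`, character(1), "channel"))
  snd_ch <- unique(vapply(Filter(function(s) s$modality == "sound", stimuli),
                          `[[`, character(1), "channel"))
  if (length(led_ch) > 3)
    stopf("at most 3 LED channels may be active per rep (got %d)", length(led_ch))
  if (length(snd_ch) > 1)
    stopf("at most 1 sound channel may be active per rep (got %d)", length(snd_ch))
  if (paradigm == "operant") {
    if (is.null(response_window))
      stopf("operant rep requires 'response_window'")
    if (is.null(target_sensor))
      stopf("operant rep requires 'target_sensor'")
    if (!is.null(food_delay))
      stopf("operant rep must not set 'food_delay' (use response_window)")
    if (!any(vapply(stimuli, function(s) s$modality == "sound", logical(1))))
      stopf("operant rep requires a sound stimulus to anchor the response window")
    if (!is.numeric(response_window) || response_window <= 0)
      stopf("'response_window' must be > 0")
  } else {
    if (is.null(food_delay))
      stopf("classical rep requires 'food_delay'")
    if (!is.null(response_window))
      stopf("classical rep must not set 'response_window' (use food_delay)")
    if (!is.numeric(food_delay) || food_delay < 0)
      stopf("'food_delay' must be >= 0")
  }
  if (!is.numeric(arm_angle) || arm_angle < 0 || arm_angle >= 360)
    stopf("'arm_angle' must lie in [0, 360)")
  if (!is.numeric(arm_speed) || arm_speed <= 0)
    stopf("'arm_speed' must be > 0")
  for (nm in c("baseline_delay", "record_end_delay")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0) stopf("'%s' must be >= 0", nm)
  }
  structure(list(paradigm = paradigm, baseline_delay = as.numeric(baseline_delay),
                 stimuli = stimuli,
                 response_window = if (is.null(response_window)) NULL else as.numeric(response_window),
                 food_delay = if (is.null(food_delay)) NULL else as.numeric(food_delay),
                 target_sensor = if (is.null(target_sensor)) NULL else as.character(target_sensor),
                 arm_angle = as.numeric(arm_angle), arm_speed = as.numeric(arm_speed),
                 feed_mode = feed_mode, record_end_delay = as.numeric(record_end_delay)),
            class = "rep_template")
}

#' Schedule one run (a block of consecutive reps)
#'
#' @param start either a 24 h clock time (`"08:00"`) or a dated time
#'   (`"2026-03-02 08:00"`); clock times are required for the 24 h remix and
#'   random-mix features.
#' @param template a [rep_template()].
#' @param rep_count number of reps (>= 1; typically 4-6, a warning is issued
#'   above 12).
#' @param inter_rep_delay seconds between the end of one rep and the start of
#'   the next (default 30).
#' @return a `run_spec` object.
#' @export
run_spec <- function(start, template, rep_count = 4, inter_rep_delay = 30) {
  if (!is_clock_time(start) && is.na(parse_dated(start)))
    stopf("run start '%s' is neither a 24h clock time nor 'YYYY-MM-DD HH:MM'", start)
  if (!inherits(template, "rep_template"))
    stopf("template must be a rep_template")
  if (!is.numeric(rep_count) || rep_count < 1 || rep_count != round(rep_count))
    stopf("'rep_count' must be a positive integer")
  if (rep_count > 12)
    warning(sprintf("rep_count = %d is unusually high (typical runs use 4-6 reps)",
                    rep_count), call. = FALSE)
  if (!is.numeric(inter_rep_delay) || inter_rep_delay < 0)
    stopf("'inter_rep_delay' must be >= 0")
  structure(list(start = as.character(start), rep_count = as.integer(rep_count),
                 inter_rep_delay = as.numeric(inter_rep_delay),
                 template = template),
            class = "run_spec")
}

#' Assemble a multi-run trial schedule
#'
#' @param runs ordered list of [run_spec()] objects (may be empty).
#' @param remix_24h repeat the whole set of runs every 24 h; only valid when
#'   all runs use 24 h clock times.
#' @param random_mix_seed optional integer; when set, [randomize_runs()] with
#'   this seed is applied on expansion.
#' @return a `trial_schedule` object.
#' @export
trial_schedule <- function(runs = list(), remix_24h = FALSE,
                           random_mix_seed = NULL) {
  if (!is.list(runs) || (length(runs) > 0 &&
      !all(vapply(runs, inherits, logical(1), "run_spec"))))
    stopf("runs must be a list of run_spec objects")
  all_clock <- length(runs) == 0 ||
    all(vapply(runs, function(r) is_clock_time(r$start), logical(1)))
  if ((isTRUE(remix_24h) || !is.null(random_mix_seed)) && !all_clock)
    stopf("remix_24h and random_mix are only available when runs are scheduled using 24 h time")
  structure(list(runs = runs, remix_24h = isTRUE(remix_24h),
                 random_mix_seed = if (is.null(random_mix_seed)) NULL else as.integer(random_mix_seed)),
            class = "trial_schedule")
}

#' @export
print.trial_schedule <- function(x, ...) {
  cat(sprintf("<trial_schedule> %d run(s), remix_24h=%s\n",
              length(x$runs), x$remix_24h))
  for (i in seq_along(x$runs)) {
    r <- x$runs[[i]]
    cat(sprintf("  run %d @ %-16s %s x%d rep(s)\n", i, r$start,
                r$template$paradigm, r$rep_count))
  }
  invisible(x)
}

# ---- YAML config parsing -------------------------------------------------

check_fields <- function(x, allowed, required, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra) > 0)
    stopf("unknown field(s) in %s: %s", where, paste(extra, collapse = ", "))
  missing <- setdiff(required, names(x))
  if (length(missing) > 0)
    stopf("missing required field(s) in %s: %s", where, paste(missing, collapse = ", "))
  invisible(x)
}

parse_stimulus_yaml <- function(s, where) {
  check_fields(s, c("stimulus_id", "modality", "channel", "onset_delay",
                    "duration", "rewarded"),
               c("stimulus_id", "modality", "channel", "onset_delay", "duration"),
               where)
  stimulus_spec(s$stimulus_id, s$modality, s$channel, s$onset_delay,
                s$duration, rewarded = s$rewarded %||% TRUE)
}

parse_template_yaml <- function(tp, where) {
  check_fields(tp, c("paradigm", "baseline_delay", "stimuli", "response_window",
                     "food_delay", "target_sensor", "arm_angle", "arm_speed",
                     "feed_mode", "record_end_delay"),
               c("paradigm", "stimuli"), where)
  stimuli <- lapply(seq_along(tp$stimuli), function(j)
    parse_stimulus_yaml(tp$stimuli[[j]], sprintf("%s/stimuli[%d]", where, j)))
  rep_template(paradigm = tp$paradigm, stimuli = stimuli,
               baseline_delay = tp$baseline_delay %||% 10,
               response_window = tp$response_window,
               food_delay = tp$food_delay,
               target_sensor = tp$target_sensor,
               arm_angle = tp$arm_angle %||% 0,
               arm_speed = tp$arm_speed %||% 90,
               feed_mode = tp$feed_mode %||% "simple",
               record_end_delay = tp$record_end_delay %||% 5)
}

#' Parse a schedule configuration document
#'
#' Reads the YAML configuration dialect documented in the package vignette.
#' The document's `schedule:` section maps one-to-one onto
#' [trial_schedule()] / [run_spec()] / [rep_template()] / [stimulus_spec()]
#' fields; unknown fields are rejected rather than silently ignored, and
#' every omitted field takes a documented default.
#'
#' @param config a file path or a YAML character string.
#' @return a validated `trial_schedule`.
#' @export
parse_schedule <- function(config) {
  doc <- load_config_doc(config)
  sched <- doc$schedule
  if (is.null(sched)) stopf("config has no 'schedule' section")
  check_fields(sched, c("runs", "remix_24h", "random_mix_seed"), character(0),
               "schedule")
  runs <- lapply(seq_along(sched$runs), function(i) {
    r <- sched$runs[[i]]
    where <- sprintf("schedule/runs[%d]", i)
    check_fields(r, c("start", "rep_count", "inter_rep_delay", "template"),
                 c("start", "template"), where)
    run_spec(start = as.character(r$start),
             template = parse_template_yaml(r$template, paste0(where, "/template")),
             rep_count = r$rep_count %||% 4,
             inter_rep_delay = r$inter_rep_delay %||% 30)
  })
  trial_schedule(runs, remix_24h = sched$remix_24h %||% FALSE,
                 random_mix_seed = sched$random_mix_seed)
}

load_config_doc <- function(config) {
  if (length(config) == 1 && !grepl("\n", config) && file.exists(config))
    doc <- yaml::read_yaml(config)
  else
    doc <- yaml::yaml.load(paste(config, collapse = "\n"))
  if (!is.list(doc)) stopf("config document is not a mapping")
  check_fields(doc, c("schedule", "tank", "agents", "windows", "engine"),
               character(0), "config")
  doc
}

# ---- serialization -------------------------------------------------------

stimulus_to_list <- function(s)
  list(stimulus_id = s$stimulus_id, modality = s$modality, channel = s$channel,
       onset_delay = s$onset_delay, duration = s$duration, rewarded = s$rewarded)

template_to_list <- function(tp) {
  out <- list(paradigm = tp$paradigm, baseline_delay = tp$baseline_delay,
              stimuli = lapply(tp$stimuli, stimulus_to_list))
  if (!is.null(tp$response_window)) out$response_window <- tp$response_window
  if (!is.null(tp$food_delay)) out$food_delay <- tp$food_delay
  if (!is.null(tp$target_sensor)) out$target_sensor <- tp$target_sensor
  out$arm_angle <- tp$arm_angle
  out$arm_speed <- tp$arm_speed
  out$feed_mode <- tp$feed_mode
  out$record_end_delay <- tp$record_end_delay
  out
}

schedule_to_list <- function(schedule) {
  out <- list(runs = lapply(schedule$runs, function(r)
                list(start = r$start, rep_count = r$rep_count,
                     inter_rep_delay = r$inter_rep_delay,
                     template = template_to_list(r$template))),
              remix_24h = schedule$remix_24h)
  if (!is.null(schedule$random_mix_seed))
    out$random_mix_seed <- schedule$random_mix_seed
  out
}

#' Serialize a trial schedule back to YAML
#'
#' `parse_schedule(serialize_schedule(x))` reproduces `x` exactly.
#'
#' @param schedule a `trial_schedule`.
#' @return a YAML character string.
#' @export
serialize_schedule <- function(schedule) {
  stopifnot(inherits(schedule, "trial_schedule"))
  yaml::as.yaml(list(schedule = schedule_to_list(schedule)))
}

#' @rdname serialize_schedule
#' @param path file to write.
#' @export
write_schedule <- function(schedule, path) {
  writeLines(serialize_schedule(schedule), path)
  invisible(path)
}

# ---- expansion and randomization -----------------------------------------

#' Expand a schedule into an absolute run timeline
#'
#' Resolves every run to an absolute start time within `horizon` days of
#' `origin`.  With `remix_24h`, the base day's set of clock-time runs repeats
#' every 24 h for the whole horizon; without it, clock-time runs occur only on
#' the first day and dated runs appear only at their own date.
#'
#' @param schedule a `trial_schedule`.
#' @param origin calendar start, `"YYYY-MM-DD"` or a POSIXct midnight.
#' @param horizon days to expand (>= 1).
#' @return a data.frame with columns `start` (POSIXct), `day`, `run_index`
#'   (index into `schedule$runs`), and list-column `run`, sorted by start
#'   time.  Two runs at the same start time are an error.
#' @export
expand_trial <- function(schedule, origin, horizon = 1) {
  stopifnot(inherits(schedule, "trial_schedule"))
  if (!is.numeric(horizon) || horizon < 1)
    stopf("'horizon' must be >= 1 day")
  horizon <- as.integer(horizon)
  if (is.character(origin))
    origin <- as.POSIXct(paste(origin, "00:00:00"), tz = "UTC")
  if (!inherits(origin, "POSIXct")) stopf("'origin' must be a date or POSIXct")

  sched <- schedule
  if (!is.null(sched$random_mix_seed))
    sched <- randomize_runs(sched, sched$random_mix_seed)

  starts <- list(); days <- integer(0); idx <- integer(0)
  for (i in seq_along(sched$runs)) {
    r <- sched$runs[[i]]
    clock <- parse_clock(r$start)
    if (!is.na(clock)) {
      rep_days <- if (sched$remix_24h) seq_len(horizon) else 1L
      for (d in rep_days) {
        starts[[length(starts) + 1L]] <- origin + (d - 1L) * 86400 + clock
        days <- c(days, d); idx <- c(idx, i)
      }
    } else {
      abs_t <- parse_dated(r$start)
      if (abs_t >= origin && abs_t < origin + horizon * 86400) {
        starts[[length(starts) + 1L]] <- abs_t
        days <- c(days, as.integer(floor(as.numeric(abs_t - origin, units = "days"))) + 1L)
        idx <- c(idx, i)
      }
    }
  }
  if (length(starts) == 0)
    return(data.frame(start = as.POSIXct(character(0), tz = "UTC"),
                      day = integer(0), run_index = integer(0)))
  start_v <- do.call(c, starts)
  if (anyDuplicated(start_v))
    stopf("two runs share the same start time: %s",
          fmt_wall(start_v[duplicated(start_v)][1]))
  o <- order(start_v)
  out <- data.frame(start = start_v[o], day = days[o], run_index = idx[o])
  out$run <- lapply(out$run_index, function(i) sched$runs[[i]])
  out
}

#' Randomize the assignment of run contents to start times
#'
#' Permutes run contents (template, rep count, inter-rep delay) across the
#' fixed grid of 24 h start times; the start times themselves never move, so
#' the daily feeding rhythm is preserved while which sound plays at which
#' session is shuffled.  The permutation is a deterministic function of
#' `seed` and the caller's RNG state is left untouched.
#'
#' @param schedule a `trial_schedule` whose runs all use 24 h clock times.
#' @param seed integer.
#' @return a `trial_schedule` with permuted run contents.
#' @export
randomize_runs <- function(schedule, seed) {
  stopifnot(inherits(schedule, "trial_schedule"))
  if (length(schedule$runs) > 0 &&
      !all(vapply(schedule$runs, function(r) is_clock_time(r$start), logical(1))))
    stopf("randomize_runs requires all runs to use 24 h clock times")
  n <- length(schedule$runs)
  if (n <= 1) return(schedule)
  perm <- with_seed(as.integer(seed), sample.int(n))
  runs <- lapply(seq_len(n), function(i) {
    r <- schedule$runs[[perm[i]]]
    r$start <- schedule$runs[[i]]$start
    r
  })
  trial_schedule(runs, remix_24h = schedule$remix_24h, random_mix_seed = NULL)
}
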