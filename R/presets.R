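# Bundled presets and full-config loading.  Presets are data files under
# inst/extdata/presets/ so the protocols they encode are inspectable and
# editable, not hard-coded constants.

#' List or resolve bundled presets
#'
#' Two presets ship with the package: `"audiovisual-4day"` (a 4-day operant
#' audiovisual discrimination paradigm: six daily runs at 08:00, 10:00,
#' 12:00, 16:00, 18:00, 20:00 with alternating sound-port pairings and an
#' LED cue 2 s after sound onset, 8 s response window) and
#' `"classical-measures"` (group classical conditioning with the standard
#' measurement timing: 10 s baseline, 4 s sound, feed at sound offset,
#' recording stop 5 s after the feed, PRE/POST2/POST3 analysis windows).
#'
#' @param name preset name.
#' @return `preset_names()` returns available names; `condukt_preset()`
#'   returns the path to the preset's config file.
#' @export
preset_names <- function() {
  sub("\\.yaml$", "",
      list.files(system.file("extdata", "presets", package = "condukt"),
                 pattern = "\\.yaml$"))
}

#' @rdname preset_names
#' @export
condukt_preset <- function(name) {
  path <- system.file("extdata", "presets", paste0(name, ".yaml"),
                      package = "condukt")
  if (!nzchar(path))
    stopf("unknown preset '%s' (available: %s)", name,
          paste(preset_names(), collapse = ", "))
  path
}

# template of a preset's first run (convenience for simulations)
preset_template <- function(name) {
  parse_schedule(condukt_preset(name))$runs[[1]]$template
}

#' Load a full configuration file
#'
#' Parses every section of the config dialect: `schedule` (required; see
#' [parse_schedule()]), and optional `tank`, `agents`, `windows`, `engine`
#' sections, each mapped onto the corresponding constructor with documented
#' defaults for omitted fields.
#'
#' @param config a file path, preset name, or YAML string.
#' @return list with elements `schedule`, `tank`, `agents` (an
#'   `agent_params`), `n_agents`, `jitter`, `windows`, `engine` (partial
#'   [engine_config()] arguments).
#' @export
load_config <- function(config) {
  if (length(config) == 1 && !grepl("\n", config) && !file.exists(config) &&
      config %in% preset_names())
    config <- condukt_preset(config)
  doc <- load_config_doc(config)
  schedule <- parse_schedule(config)

  tank <- if (is.null(doc$tank)) tank_geometry() else {
    check_fields(doc$tank, c("radius", "port_angles", "zone_boundaries",
                             "divider"), character(0), "tank")
    tank_geometry(radius = doc$tank$radius %||% 15,
                  port_angles = unlist(doc$tank$port_angles) %||% c(0, 180),
                  zone_boundaries = unlist(doc$tank$zone_boundaries) %||% c(10, 20),
                  divider = doc$tank$divider)
  }
  n_agents <- 1L; jitter <- 0.1
  agents <- if (is.null(doc$agents)) agent_params() else {
    a <- doc$agents
    check_fields(a, c("count", "jitter", "base_speed", "speed_sd",
                      "turn_concentration", "arousal_gain", "bias_gain",
                      "alpha", "lam", "V0", "satiation_decay",
                      "satiation_half_life"),
                 character(0), "agents")
    n_agents <- as.integer(a$count %||% 1L)
    jitter <- a$jitter %||% 0.1
    a$count <- NULL; a$jitter <- NULL
    do.call(agent_params, a)
  }
  windows <- if (is.null(doc$windows)) window_spec() else {
    check_fields(doc$windows, c("pre", "post"), character(0), "windows")
    window_spec(pre = unlist(doc$windows$pre) %||% c(-1, 0),
                post = lapply(doc$windows$post %||%
                                list(POST2 = c(1, 2), POST3 = c(2, 3)), unlist))
  }
  engine <- if (is.null(doc$engine)) list() else {
    check_fields(doc$engine, c("tick", "frame_rate", "feed_latency"),
                 character(0), "engine")
    doc$engine
  }
  list(schedule = schedule, tank = tank, agents = agents,
       n_agents = n_agents, jitter = jitter, windows = windows,
       engine = engine)
}
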