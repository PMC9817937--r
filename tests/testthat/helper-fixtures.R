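# Shared fixtures: short rep templates keep simulated reps a few seconds
# long so property suites over many reps stay fast.

quick_sound <- function(onset = 1, duration = 2, id = "snd", rewarded = TRUE)
  stimulus_spec(id, "sound", "tone", onset_delay = onset, duration = duration,
                rewarded = rewarded)

quick_operant <- function(response_window = 3, target_sensor = "s1",
                          arm_angle = 0, record_end_delay = 1, ...)
  rep_template("operant", list(quick_sound(...)), baseline_delay = 1,
               response_window = response_window, target_sensor = target_sensor,
               arm_angle = arm_angle, record_end_delay = record_end_delay)

quick_classical <- function(food_delay = 3, record_end_delay = 1, ...)
  rep_template("classical", list(quick_sound(...)), baseline_delay = 1,
               food_delay = food_delay, record_end_delay = record_end_delay)

# a deterministic straight-line swimmer: fixed speed, negligible turning
scripted_agent <- function(position, heading, speed = 4) {
  p <- agent_params(base_speed = speed, speed_sd = 0,
                    turn_concentration = 1e8, arousal_gain = 1,
                    alpha = 0, V0 = 0)
  list(id = 1L, params = p,
       state = list(position = position, heading = heading, speed = 0,
                    V = numeric(0), satiation = 0))
}

# an agent that cannot move (never reaches any sensor)
still_agent <- function(position = c(0, 0)) scripted_agent(position, 0, speed = 0)

# a fish with a fully learned association for the given stimulus
trained_agent <- function(stimulus_id = "snd", V = 1, seed = 1,
                          tank = tank_geometry()) {
  a <- make_cohort(1, agent_params(), seed = seed, tank = tank)[[1]]
  a$state$V[stimulus_id] <- V
  a
}

random_trajectory <- function(n_frames = 20, n_ind = 2, frame_rate = 30,
                              missing_frac = 0.1) {
  df <- do.call(rbind, lapply(seq_len(n_ind), function(i) {
    x <- cumsum(rnorm(n_frames)); y <- cumsum(rnorm(n_frames))
    miss <- runif(n_frames) < missing_frac
    x[miss] <- NA; y[miss] <- NA
    data.frame(frame = seq_len(n_frames) - 1L,
               time = (seq_len(n_frames) - 1L) / frame_rate,
               id = i, x = x, y = y)
  }))
  trajectory_table(df, frame_rate)
}
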