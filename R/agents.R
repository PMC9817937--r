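# Virtual fish: kinematic parameters, reward-association state, cohort
# construction, and the correlated-random-walk step (compiled core).
#
# The swim model is a correlated random walk with wall reflection: baseline
# wandering, stimulus-driven arousal (faster swimming, more turning), and,
# once an association has been learned, heading bias toward the reward port
# weighted by association strength discounted by satiation.  Association
# strength follows the Rescorla-Wagner rule V <- V + alpha * (lam - V) on
# rewarded presentations, with mild extinction V <- V * (1 - alpha/4) on
# unrewarded ones.

#' Kinematic and learning parameters of a virtual fish
#'
#' Defaults describe an adult zebrafish cruising in a 30 cm tank: mean swim
#' speed 4 cm/s with 1.5 cm/s spread, moderate heading persistence, and a 1.5x
#' arousal multiplier on speed and turning while a stimulus is playing.
#'
#' @param base_speed mean swim speed, cm/s.
#' @param speed_sd per-tick speed spread, cm/s (draws are truncated at 0).
#' @param turn_concentration heading persistence (unitless, > 0); the
#'   per-second heading diffusion is `1/sqrt(turn_concentration)` radians, so
#'   larger values give straighter paths.
#' @param arousal_gain multiplier on speed and turning while any stimulus is
#'   active (> 1 reproduces post-onset arousal: more turns, higher speed).
#' @param bias_gain port-attraction rate, radians/second at full association:
#'   while a learned stimulus plays, heading drifts toward the reward-port
#'   bearing at `bias_gain * V / (1 + satiation) * sin(bearing - heading)`.
#' @param alpha learning rate per rewarded rep, in `[0, 1]`.
#' @param lam association asymptote (fixed at 1).
#' @param V0 initial association strength per stimulus, in `[0, lam]`.
#' @param satiation_decay appetite reduction per grain of food eaten; the
#'   port-seeking bias is `V / (1 + satiation)`.
#' @param satiation_half_life hours for satiation to halve between reps
#'   (digestion), so appetite recovers across the daily feeding rhythm.
#' @return an `agent_params` object.
#' @export
agent_params <- function(base_speed = 4, speed_sd = 1.5, turn_concentration = 2,
                         arousal_gain = 1.5, bias_gain = 4, alpha = 0.1,
                         lam = 1, V0 = 0.02,
                         satiation_decay = 0.05, satiation_half_life = 3) {
  vals <- list(base_speed = base_speed, speed_sd = speed_sd,
               turn_concentration = turn_concentration,
               arousal_gain = arousal_gain, bias_gain = bias_gain,
               alpha = alpha, lam = lam, V0 = V0,
               satiation_decay = satiation_decay,
               satiation_half_life = satiation_half_life)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0)
      stopf("'%s' must be a nonnegative number", nm)
  }
  if (alpha > 1) stopf("'alpha' must be <= 1")
  if (V0 > lam) stopf("'V0' must be <= lam")
  if (turn_concentration <= 0) stopf("'turn_concentration' must be > 0")
  structure(lapply(vals, as.numeric), class = "agent_params")
}

new_agent_state <- function(position, heading, V = numeric(0), satiation = 0) {
  list(position = as.numeric(position), heading = as.numeric(heading),
       speed = 0, V = V, satiation = as.numeric(satiation))
}

#' Create a cohort of virtual fish
#'
#' Each agent gets independently jittered kinematic parameters (multiplicative
#' log-normal jitter on speed, spread, persistence, and arousal gain;
#' `jitter = 0` yields identical agents) and a uniform random start position
#' and heading inside the tank.  The construction is deterministic in `seed`,
#' and each agent later draws from its own RNG stream split from the rep
#' seed, so cohort size never changes any single agent's path.
#'
#' @param n number of fish (>= 1).
#' @param params shared [agent_params()].
#' @param seed integer.
#' @param tank a [tank_geometry()] for start positions.
#' @param jitter log-scale sd of the per-agent parameter jitter (default 0.1).
#' @return list of agents; each is a list with `id`, `params`, `state`.
#' @export
make_cohort <- function(n, params = agent_params(), seed = 1,
                        tank = tank_geometry(), jitter = 0.1) {
  if (!is.numeric(n) || n < 1 || n != round(n)) stopf("'n' must be >= 1")
  stopifnot(inherits(params, "agent_params"))
  with_seed(derive_seed(seed, "cohort"), {
    lapply(seq_len(n), function(i) {
      p <- params
      for (nm in c("base_speed", "speed_sd", "turn_concentration", "arousal_gain"))
        p[[nm]] <- p[[nm]] * exp(rnorm(1, 0, jitter))
      r <- tank$radius * 0.9 * sqrt(runif(1))
      th <- runif(1, 0, 2 * pi)
      list(id = i, params = p,
           state = new_agent_state(position = r * c(cos(th), sin(th)),
                                   heading = runif(1, 0, 2 * pi)))
    })
  })
}

#' Rescorla-Wagner association update
#'
#' `V + alpha * (lam - V)` after a rewarded presentation;
#' `V * (1 - alpha / 4)` (mild extinction) after an unrewarded one.  The
#' result always stays in `[0, lam]` and is monotone in both `V` and reward.
#'
#' @param V current association strength in `[0, lam]` (vectorized).
#' @param rewarded logical.
#' @param alpha learning rate in `[0, 1]`.
#' @param lam asymptote (default 1).
#' @return updated strength(s).
#' @export
update_association <- function(V, rewarded, alpha, lam = 1) {
  if (any(V < 0 | V > lam)) stopf("V must lie in [0, lam]")
  if (alpha < 0 || alpha > 1) stopf("alpha must lie in [0, 1]")
  if (isTRUE(rewarded)) V + alpha * (lam - V) else V * (1 - alpha / 4)
}

# internal: per-tick heading-bias weight toward the port for a given
# association strength and satiation level.
bias_weight <- function(V, satiation) V / (1 + satiation)

# internal: simulate an agent's path for n_steps ticks.
# stim_on: integer 0/1 per tick (any stimulus active -> arousal);
# bias_w: numeric per tick (port-seeking weight; 0 when no learned stimulus
# is active).  Consumes the current RNG stream.
simulate_path <- function(agent, n_steps, dt, stim_on, bias_w, tank,
                          target_port = 1) {
  p <- agent$params
  st <- agent$state
  port <- port_location(tank, target_port)
  div <- tank$divider
  th <- tank$port_angles[target_port] * pi / 180
  sim_path_cpp(as.integer(n_steps), dt,
               st$position[1], st$position[2], st$heading,
               p$base_speed, p$speed_sd, 1 / sqrt(p$turn_concentration),
               p$arousal_gain, p$bias_gain,
               as.numeric(bias_w), port[1], port[2],
               as.integer(stim_on), tank$radius,
               as.integer(!is.null(div)),
               if (is.null(div)) 0 else div$offset,
               if (is.null(div)) 0 else div$gap_center,
               if (is.null(div)) 0 else div$gap_width / 2,
               cos(th), sin(th))
}

#' Advance one agent by one time step
#'
#' Thin wrapper over the compiled path core (a single step), exposed for
#' inspection and property testing; the engine uses the same core to step
#' whole reps at once.
#'
#' @param state agent state (list with `position`, `heading`, `V`,
#'   `satiation`).
#' @param active_stimuli list of [stimulus_spec()] currently playing (may be
#'   empty).
#' @param tank a [tank_geometry()].
#' @param dt step size, seconds (> 0).
#' @param params [agent_params()].
#' @param target_port port index the rewarded stimuli are associated with.
#' @return the updated state.
#' @export
step_agent <- function(state, active_stimuli, tank, dt,
                       params = agent_params(), target_port = 1) {
  if (dt <= 0) stopf("'dt' must be > 0")
  stim_on <- as.integer(length(active_stimuli) > 0)
  w <- 0
  for (s in active_stimuli) {
    if (isTRUE(s$rewarded)) {
      V <- state$V[s$stimulus_id]
      if (is.null(V) || is.na(V)) V <- params$V0
      w <- max(w, bias_weight(V, state$satiation))
    }
  }
  m <- simulate_path(list(params = params, state = state), 1L, dt,
                     stim_on = stim_on, bias_w = w, tank = tank,
                     target_port = target_port)
  state$position <- c(m[2, 1], m[2, 2])
  state$heading <- m[2, 3]
  state$speed <- m[2, 4]
  state
}
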