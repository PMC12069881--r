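#' Intelligent driver model parameters
#'
#' @param v0 desired speed (m/s).
#' @param x0 desired minimum gap (m).
#' @param headway desired time headway T (s).
#' @param a_max maximum acceleration (m/s^2).
#' @param b_max comfortable braking magnitude (m/s^2).
#' @return An object of class `idm_params` (the free-flow exponent is the
#'   conventional constant 4).
#' @export
idm_params <- function(v0 = 50 / 3.6, x0 = 2, headway = 1.5, a_max = 2,
                       b_max = 4) {
  vals <- c(v0, x0, headway, a_max, b_max)
  if (any(vals <= 0)) stop("all IDM parameters must be positive")
  structure(list(v0 = v0, x0 = x0, headway = headway, a_max = a_max,
                 b_max = b_max, delta = 4),
            class = "idm_params")
}

#' Intelligent driver model acceleration
#'
#' Car-following law
#' `dv/dt = a_max * (1 - (v/v0)^4 - (x*/gap)^2)` with desired gap
#' `x* = x0 + max(0, v*T + v*dv / (2*sqrt(a_max*b_max)))`, where `dv` is the
#' closing speed (ego minus front). The output is clamped to
#' `[-b_max, a_max]`. Serves as the safe fallback action when risk is
#' flagged.
#'
#' @param v ego speed (m/s).
#' @param gap bumper-to-bumper gap to the front agent (m, > 0); `Inf`
#'   gives free-road behaviour.
#' @param dv closing speed `v - v_front` (m/s).
#' @param p an [idm_params()].
#' @return Acceleration in m/s^2.
#' @export
idm_accel <- function(v, gap, dv, p = idm_params()) {
  if (any(gap <= 0)) stop("gap must be positive")
  x_star <- p$x0 + pmax(0, v * p$headway +
                          v * dv / (2 * sqrt(p$a_max * p$b_max)))
  a <- p$a_max * (1 - (v / p$v0)^p$delta - (x_star / gap)^2)
  pmin(pmax(a, -p$b_max), p$a_max)
}

#' Scenario configuration for the longitudinal simulator
#'
#' Three scenarios, each with 10 s of stable driving followed by a
#' randomised risk event:
#' \describe{
#'   \item{1 (emergency braking)}{ego and front vehicle both at 50 km/h,
#'     50 m apart; after 10 s the front vehicle decelerates mildly, then
#'     brakes hard when the relative distance reaches a uniform draw from
#'     20--40 m.}
#'   \item{2 (cut-in)}{ego 50 km/h, front 40 km/h in the neighbouring lane
#'     80 m ahead longitudinally; it merges instantaneously at a random
#'     time after 10 s.}
#'   \item{3 (pedestrian crossing)}{ego 40 km/h, pedestrian 300 m ahead
#'     crossing at 1.5 m/s at a random time after 10 s; passing within
#'     1.5 m is a near-miss.}
#' }
#'
#' @param scenario 1, 2 or 3.
#' @param dt integration step (s).
#' @param episode_cap_s wall-clock cap per episode (s).
#' @param accel_bounds physical acceleration range (m/s^2) that the
#'   normalised action [-1, 1] maps onto.
#' @param vehicle_length bumper-to-bumper collision distance (m).
#' @param ped_threshold pedestrian near-miss clearance (m).
#' @param reward_weights named vector `w_v` (speed tracking), `w_c`
#'   (collision/near-miss), `w_j` (jerk), `w_r` (risk field).
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(scenario = 1, dt = 0.05, episode_cap_s = 40,
                            accel_bounds = c(-8, 3), vehicle_length = 5,
                            ped_threshold = 1.5,
                            reward_weights = c(w_v = 0.1, w_c = 10,
                                               w_j = 0.01, w_r = 1)) {
  if (!scenario %in% 1:3) stop("unknown scenario id: ", scenario)
  base <- list(scenario = scenario, dt = dt, episode_cap_s = episode_cap_s,
               accel_bounds = accel_bounds, vehicle_length = vehicle_length,
               ped_threshold = ped_threshold, reward_weights = reward_weights,
               lane_offset = 3.5)
  sc <- switch(scenario,
    `1` = list(ego_speed = 50 / 3.6, front_speed = 50 / 3.6, gap0 = 50,
               trigger_dist_range = c(20, 40), mild_decel = -1,
               hard_decel = -6),
    `2` = list(ego_speed = 50 / 3.6, front_speed = 40 / 3.6, gap0 = 80,
               cutin_time_range = c(10, 20)),
    `3` = list(ego_speed = 40 / 3.6, ped_ahead = 300, ped_speed = 1.5,
               cross_time_range = c(10, 18), road_halfwidth = 2,
               ped_start_y = -5))
  structure(c(base, sc), class = "scenario_config")
}

#' Reset the simulator
#'
#' Places the ego and front agent at the scenario's initial condition and
#' samples the risk trigger from its stated distribution.
#'
#' @param config a [scenario_config()].
#' @param seed integer seed for the trigger draw.
#' @return An environment-state object of class `sim_env`; query the 8-dim
#'   agent state with [sim_state()].
#' @export
sim_reset <- function(config, seed = 1) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(as.integer(seed))
  sc <- config$scenario
  env <- list(config = config, t = 0, phase = "stable", done = FALSE,
              flags = list(collision = FALSE, near_miss = FALSE,
                           timeout = FALSE, resolved = FALSE),
              prev_accel = 0, step_count = 0L)
  if (sc == 1) {
    env$ego <- c(x = 0, y = 0, vx = config$ego_speed, vy = 0)
    env$front <- c(x = config$gap0, y = 0, vx = config$front_speed, vy = 0)
    env$trigger_dist <- runif(1, config$trigger_dist_range[1],
                              config$trigger_dist_range[2])
  } else if (sc == 2) {
    env$ego <- c(x = 0, y = 0, vx = config$ego_speed, vy = 0)
    env$front <- c(x = config$gap0, y = config$lane_offset,
                   vx = config$front_speed, vy = 0)
    env$trigger_time <- runif(1, config$cutin_time_range[1],
                              config$cutin_time_range[2])
  } else {
    env$ego <- c(x = 0, y = 0, vx = config$ego_speed, vy = 0)
    env$front <- c(x = config$ped_ahead, y = config$ped_start_y,
                   vx = 0, vy = 0)
    env$trigger_time <- runif(1, config$cross_time_range[1],
                              config$cross_time_range[2])
  }
  structure(env, class = "sim_env")
}

#' Eight-dimensional agent state
#'
#' Ego velocity (x, y), ego position (x, y), front-agent velocity (x, y),
#' front-agent position (x, y).
#'
#' @param env a `sim_env`.
#' @return Named numeric vector of length 8.
#' @export
sim_state <- function(env) {
  c(ego_vx = unname(env$ego["vx"]), ego_vy = unname(env$ego["vy"]),
    ego_x = unname(env$ego["x"]), ego_y = unname(env$ego["y"]),
    front_vx = unname(env$front["vx"]), front_vy = unname(env$front["vy"]),
    front_x = unname(env$front["x"]), front_y = unname(env$front["y"]))
}

## bumper gap used for IDM/TTC; Inf while the front agent is not in the
## ego lane (pre-merge cut-in, pedestrian not yet crossing)
sim_gap <- function(env) {
  cfg <- env$config
  if (cfg$scenario == 2 && abs(env$front["y"]) > 1e-9) return(Inf)
  if (cfg$scenario == 3) {
    if (env$phase == "stable" || env$flags$resolved) return(Inf)
    return(unname(env$front["x"] - env$ego["x"]))
  }
  unname(env$front["x"] - env$ego["x"] - cfg$vehicle_length)
}

#' IDM fallback action for the current simulator state
#'
#' @param env a `sim_env`.
#' @param p an [idm_params()]; defaults to the scenario's initial ego speed
#'   as the desired speed.
#' @return Normalised action in [-1, 1] (inverse of the acceleration map).
#' @export
sim_idm_action <- function(env, p = NULL) {
  cfg <- env$config
  if (is.null(p)) p <- idm_params(v0 = cfg$ego_speed)
  gap <- sim_gap(env)
  dv <- unname(env$ego["vx"] - env$front["vx"])
  if (cfg$scenario == 3) dv <- unname(env$ego["vx"])  # crossing point is static
  a <- if (is.infinite(gap)) {
    p$a_max * (1 - (unname(env$ego["vx"]) / p$v0)^p$delta)
  } else {
    idm_accel(unname(env$ego["vx"]), max(gap, 0.1), dv, p)
  }
  accel_to_action(a, cfg$accel_bounds)
}

#' Map between normalised actions and physical acceleration
#'
#' The agent's action in [-1, 1] maps linearly onto
#' `accel_bounds = c(min, max)` m/s^2.
#'
#' @param action normalised action.
#' @param bounds `c(min, max)` acceleration bounds.
#' @return `action_to_accel()`: acceleration in m/s^2;
#'   `accel_to_action()`: normalised action (clipped to [-1, 1]).
#' @export
action_to_accel <- function(action, bounds = c(-8, 3)) {
  action <- pmin(pmax(action, -1), 1)
  bounds[1] + (action + 1) / 2 * (bounds[2] - bounds[1])
}

#' @rdname action_to_accel
#' @param accel acceleration in m/s^2.
#' @export
accel_to_action <- function(accel, bounds = c(-8, 3)) {
  a <- (accel - bounds[1]) / (bounds[2] - bounds[1]) * 2 - 1
  pmin(pmax(a, -1), 1)
}

#' Advance the simulator one step
#'
#' Maps the normalised command to physical acceleration, integrates the
#' kinematics with forward Euler, advances the scenario's front-agent
#' script, and evaluates termination: collision, pedestrian clearance
#' below threshold, standstill after the risk has resolved, or the time
#' cap.
#'
#' @param env a `sim_env`.
#' @param action normalised acceleration command in [-1, 1].
#' @param dt integration step; defaults to the configured `dt`.
#' @return List with `env` (advanced state), `state` (next 8-dim state),
#'   `reward`, `done`, and `info` (gap, gap rate, jerk, risk-field value,
#'   phase, flags).
#' @export
sim_step <- function(env, action, dt = NULL) {
  stopifnot(inherits(env, "sim_env"))
  cfg <- env$config
  if (is.null(dt)) dt <- cfg$dt
  if (dt <= 0) stop("dt must be positive")
  if (env$done) stop("episode is done; call sim_reset()")
  accel <- action_to_accel(action, cfg$accel_bounds)
  if (env$ego["vx"] <= 0 && accel < 0) accel <- 0  # no reversing

  ## --- front-agent script
  sc <- cfg$scenario
  if (sc == 1) {
    gap_now <- unname(env$front["x"] - env$ego["x"])
    if (env$phase == "stable" && env$t >= 10) env$phase <- "decel"
    if (env$phase == "decel" && gap_now <= env$trigger_dist) env$phase <- "risk"
    fa <- switch(env$phase, stable = 0, decel = cfg$mild_decel,
                 risk = cfg$hard_decel)
    if (env$front["vx"] <= 0) { fa <- 0; env$front["vx"] <- 0 }
    if (env$phase != "stable" && env$front["vx"] <= 0)
      env$flags$resolved <- TRUE  # front has come to a stop: event over
    env$front["vx"] <- max(0, env$front["vx"] + fa * dt)
    env$front["x"] <- env$front["x"] + env$front["vx"] * dt
  } else if (sc == 2) {
    if (env$phase == "stable" && env$t >= env$trigger_time) {
      env$phase <- "risk"
      env$front["y"] <- 0  # instantaneous merge into the ego lane
    }
    if (env$phase == "risk" &&
        (env$front["x"] - env$ego["x"]) > 2 * cfg$vehicle_length &&
        env$t > env$trigger_time + 5)
      env$flags$resolved <- TRUE
    env$front["x"] <- env$front["x"] + env$front["vx"] * dt
  } else {
    if (env$phase == "stable" && env$t >= env$trigger_time) {
      env$phase <- "risk"
      env$front["vy"] <- cfg$ped_speed
    }
    env$front["y"] <- env$front["y"] + env$front["vy"] * dt
    if (env$phase == "risk" && env$front["y"] > cfg$road_halfwidth + 3) {
      env$front["vy"] <- 0
      env$flags$resolved <- TRUE
      env$phase <- "post"
    }
  }

  ## --- ego kinematics (forward Euler)
  env$ego["vx"] <- max(0, env$ego["vx"] + accel * dt)
  env$ego["x"] <- env$ego["x"] + env$ego["vx"] * dt
  env$t <- env$t + dt
  env$step_count <- env$step_count + 1L

  ## --- termination & safety flags
  gap <- unname(env$front["x"] - env$ego["x"])
  if (sc %in% c(1, 2)) {
    in_lane <- abs(env$front["y"]) < 1e-9
    if (in_lane && gap <= cfg$vehicle_length) {
      env$flags$collision <- TRUE; env$done <- TRUE
    }
  } else {
    ped_on_road <- abs(env$front["y"]) <= cfg$road_halfwidth &&
      env$phase == "risk"
    if (ped_on_road && abs(gap) < cfg$ped_threshold) {
      env$flags$near_miss <- TRUE
      env$flags$collision <- abs(gap) < 0.5
      env$done <- TRUE
    }
    if (!env$flags$resolved && env$ego["x"] > env$front["x"] + 2 &&
        env$phase == "risk") {
      env$done <- TRUE  # passed through the active crossing safely
    }
  }
  ## standstill: episode over once the ego has stopped after the stable
  ## phase (post-risk stop, or a full deliberate stop mid-event)
  if (env$t > 10 && env$ego["vx"] < 0.1 &&
      (env$flags$resolved || env$phase != "stable")) env$done <- TRUE
  if (sc == 3 && env$flags$resolved &&
      env$ego["x"] > env$front["x"] + 20) env$done <- TRUE
  if (env$t >= cfg$episode_cap_s) { env$flags$timeout <- TRUE; env$done <- TRUE }

  jerk <- (accel - env$prev_accel) / dt
  ## risk field of the front agent acting on the ego vehicle: the relative
  ## position vector r points front -> ego
  r_vec <- c(env$ego["x"] - env$front["x"], env$ego["y"] - env$front["y"])
  v2 <- c(env$front["vx"], env$front["vy"])
  rf <- if (sqrt(sum(r_vec^2)) > 0) {
    theta <- angle_between(r_vec, v2)
    risk_field(sqrt(sum(r_vec^2)), sqrt(sum(v2^2)), theta)
  } else Inf

  w <- cfg$reward_weights
  v_ref <- cfg$ego_speed
  speed_term <- w["w_v"] * (1 - abs(env$ego["vx"] - v_ref) / v_ref)
  crash_term <- if (env$flags$collision || env$flags$near_miss) w["w_c"] else 0
  jerk_term <- w["w_j"] * min(jerk^2, 400)  # bounded per step
  rf_term <- w["w_r"] * min(rf, 1)
  reward <- unname(speed_term - crash_term - jerk_term - rf_term)

  env$prev_accel <- accel
  gap_rate <- unname(env$front["vx"] - env$ego["vx"])
  ttc_val <- if (env$flags$collision || env$flags$near_miss) {
    0
  } else if (sc %in% c(1, 2)) {
    if (abs(env$front["y"]) > 1e-9 || gap < cfg$vehicle_length) Inf
    else ttc(gap, cfg$vehicle_length, gap_rate)
  } else {
    if (env$phase == "risk" && !env$flags$resolved && gap > 0)
      ttc(gap, 0, gap_rate) else Inf
  }
  info <- list(gap = gap, gap_rate = gap_rate, jerk = unname(jerk),
               accel = accel, risk_field = unname(rf), ttc = unname(ttc_val),
               phase = env$phase, flags = env$flags, t = env$t)
  list(env = env, state = sim_state(env), reward = reward,
       done = env$done, info = info)
}

angle_between <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(pi / 2)  # undefined direction: neutral
  acos(pmin(pmax(sum(a * b) / (na * nb), -1), 1))
}

#' True risk phase of the simulator
#'
#' Ground-truth risk gate (1 while the scripted risk event is active and
#' unresolved); the oracle guidance source for protocol runs.
#'
#' @param env a `sim_env`.
#' @return 0 or 1.
#' @export
sim_risk_active <- function(env) {
  as.integer(env$phase %in% c("risk") && !env$flags$resolved)
}
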