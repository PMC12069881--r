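## ---- minimal dense networks with Adam -------------------------------------
## The actor and critics are small fully connected networks (ReLU hidden
## layers; tanh head for the actor, linear head for the critics), trained
## with explicit backpropagation. Network sizes are configurable; the
## defaults follow common TD3 practice.

mlp_init <- function(sizes, out_act = c("linear", "tanh")) {
  out_act <- match.arg(out_act)
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1], 0,
                           sqrt(2 / sizes[l])), sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  list(W = W, b = b, out_act = out_act, sizes = sizes)
}

mlp_forward <- function(net, X) {
  L <- length(net$W)
  acts <- vector("list", L + 1L)
  acts[[1]] <- X
  for (l in seq_len(L)) {
    Z <- acts[[l]] %*% net$W[[l]] + rep(net$b[[l]], each = nrow(X))
    acts[[l + 1]] <- if (l < L) pmax(Z, 0)
    else if (net$out_act == "tanh") tanh(Z) else Z
  }
  list(out = acts[[L + 1]], acts = acts)
}

## dOut: gradient of the loss wrt the network output (n x out_dim)
mlp_backward <- function(net, fw, dOut) {
  L <- length(net$W)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- if (net$out_act == "tanh") dOut * (1 - fw$out^2) else dOut
  for (l in seq(L, 1)) {
    gW[[l]] <- crossprod(fw$acts[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(net$W[[l]])) * (fw$acts[[l]] > 0)
    } else {
      dIn <- delta %*% t(net$W[[l]])
    }
  }
  list(gW = gW, gb = gb, dIn = dIn)
}

adam_init <- function(net) {
  zero <- function(p) lapply(p, function(x) x * 0)
  list(mW = zero(net$W), vW = zero(net$W), mb = zero(net$b),
       vb = zero(net$b), t = 0L)
}

adam_step <- function(net, opt, gW, gb, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t; c2 <- 1 - beta2^opt$t
  for (l in seq_along(net$W)) {
    opt$mW[[l]] <- beta1 * opt$mW[[l]] + (1 - beta1) * gW[[l]]
    opt$vW[[l]] <- beta2 * opt$vW[[l]] + (1 - beta2) * gW[[l]]^2
    net$W[[l]] <- net$W[[l]] - lr * (opt$mW[[l]] / c1) /
      (sqrt(opt$vW[[l]] / c2) + eps)
    opt$mb[[l]] <- beta1 * opt$mb[[l]] + (1 - beta1) * gb[[l]]
    opt$vb[[l]] <- beta2 * opt$vb[[l]] + (1 - beta2) * gb[[l]]^2
    net$b[[l]] <- net$b[[l]] - lr * (opt$mb[[l]] / c1) /
      (sqrt(opt$vb[[l]] / c2) + eps)
  }
  list(net = net, opt = opt)
}

## ---- TD3 agent -------------------------------------------------------------

#' TD3 hyperparameter configuration
#'
#' Standard twin-delayed deep deterministic policy gradient settings, plus
#' the guidance-specific knobs: `bc_weight`, the coefficient of the
#' behaviour-cloning term in the guided actor update, and
#' `store_executed`, whether guided transitions store the executed
#' (switched-to-IDM) action (so the critic learns on executed behaviour)
#' or the raw policy proposal.
#'
#' @param hidden hidden layer sizes of actor and critics.
#' @param gamma discount factor.
#' @param rho Polyak averaging constant for target networks.
#' @param lr_actor,lr_critic learning rates (beta and alpha).
#' @param batch_size replay batch size.
#' @param policy_delay actor/target update period in critic updates.
#' @param expl_noise exploration noise sd (action units).
#' @param target_noise,noise_clip target-policy smoothing noise sd and
#'   clip; set `target_noise = 0` to disable smoothing.
#' @param warmup steps of random actions before learning starts.
#' @param warmup_accel physical acceleration range (m/s^2) that warm-up
#'   exploration samples uniformly; kept to comfortable magnitudes so
#'   exploratory driving stays plausible (full braking remains available
#'   to the policy itself).
#' @param buffer_cap replay capacity.
#' @param bc_weight behaviour-cloning coefficient.
#' @param store_executed store the executed action in guided steps?
#' @param state_scale divisors normalising the 8-dim state before the
#'   networks (positions in metres, speeds in m/s).
#' @return An object of class `td3_config`.
#' @export
td3_config <- function(hidden = c(256, 256), gamma = 0.99, rho = 0.995,
                       lr_actor = 3e-4, lr_critic = 3e-4, batch_size = 256,
                       policy_delay = 2, expl_noise = 0.1,
                       target_noise = 0.2, noise_clip = 0.5, warmup = 1000,
                       warmup_accel = c(-2, 2),
                       buffer_cap = 100000, bc_weight = 1,
                       store_executed = TRUE,
                       state_scale = c(20, 20, 500, 10, 20, 20, 500, 10)) {
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]")
  structure(as.list(environment()), class = "td3_config")
}

#' Initialise a TD3 agent bundle
#'
#' Actor, two independent critics, their target copies, and Adam optimiser
#' state.
#'
#' @param config a [td3_config()].
#' @param state_dim state dimension (8).
#' @param seed integer seed for weight initialisation.
#' @return An object of class `td3_agent`.
#' @export
td3_init <- function(config = td3_config(), state_dim = 8, seed = 1) {
  set.seed(as.integer(seed))
  h <- config$hidden
  actor <- mlp_init(c(state_dim, h, 1), "tanh")
  c1 <- mlp_init(c(state_dim + 1, h, 1), "linear")
  c2 <- mlp_init(c(state_dim + 1, h, 1), "linear")
  structure(list(actor = actor, actor_targ = actor,
                 critic1 = c1, critic2 = c2,
                 critic1_targ = c1, critic2_targ = c2,
                 opt_actor = adam_init(actor),
                 opt_c1 = adam_init(c1), opt_c2 = adam_init(c2),
                 config = config, state_dim = state_dim,
                 n_updates = 0L),
            class = "td3_agent")
}

norm_state <- function(agent, s) {
  sc <- agent$config$state_scale
  if (is.matrix(s)) sweep(s, 2, sc, "/") else s / sc
}

#' Deterministic policy action with optional exploration noise
#'
#' @param agent a `td3_agent`.
#' @param state 8-dim state vector (or matrix of rows).
#' @param explore add Gaussian exploration noise?
#' @return Action(s) in [-1, 1].
#' @export
select_action <- function(agent, state, explore = FALSE) {
  if ((is.matrix(state) && ncol(state) != agent$state_dim) ||
      (!is.matrix(state) && length(state) != agent$state_dim))
    stop("state dimension must be ", agent$state_dim)
  X <- if (is.matrix(state)) state else matrix(state, nrow = 1)
  a <- mlp_forward(agent$actor, norm_state(agent, X))$out
  if (explore && agent$config$expl_noise > 0)
    a <- a + rnorm(length(a), 0, agent$config$expl_noise)
  pmin(pmax(as.numeric(a), -1), 1)
}

#' Risk-gated action switching
#'
#' `a = (1 - k) * a_rl + k * a_idm`: exactly the IDM fallback when the risk
#' gate `k` is 1, exactly the policy action when 0.
#'
#' @param a_rl policy action.
#' @param a_idm IDM fallback action.
#' @param k_fnirs risk gate, 0 or 1 (vectorised).
#' @return The executed action.
#' @export
switch_action <- function(a_rl, a_idm, k_fnirs) {
  if (!all(k_fnirs %in% c(0, 1))) stop("k_fnirs must be boolean (0/1)")
  (1 - k_fnirs) * a_rl + k_fnirs * a_idm
}

## ---- replay buffer ---------------------------------------------------------

#' Uniform replay buffer
#'
#' Ring store of transitions `(s, a, r, s', done, k_fnirs, a_idm)`.
#'
#' @param capacity maximum number of stored transitions.
#' @param state_dim state dimension.
#' @return An object of class `replay_buffer`.
#' @export
replay_init <- function(capacity = 100000, state_dim = 8) {
  structure(list(s = matrix(0, capacity, state_dim),
                 a = numeric(capacity), r = numeric(capacity),
                 s2 = matrix(0, capacity, state_dim),
                 done = numeric(capacity), k = numeric(capacity),
                 a_idm = numeric(capacity),
                 capacity = capacity, size = 0L, pos = 0L),
            class = "replay_buffer")
}

#' @rdname replay_init
#' @param buf a `replay_buffer`.
#' @param s,a,r,s2,done,k,a_idm one transition.
#' @export
replay_add <- function(buf, s, a, r, s2, done, k, a_idm) {
  i <- (buf$pos %% buf$capacity) + 1L
  buf$s[i, ] <- s; buf$a[i] <- a; buf$r[i] <- r; buf$s2[i, ] <- s2
  buf$done[i] <- done; buf$k[i] <- k; buf$a_idm[i] <- a_idm
  buf$pos <- buf$pos + 1L
  buf$size <- min(buf$size + 1L, buf$capacity)
  buf
}

#' @rdname replay_init
#' @param n batch size; sampling is uniform over the fill level and never
#'   reaches beyond it.
#' @export
replay_sample <- function(buf, n) {
  if (buf$size == 0L) stop("empty replay buffer")
  idx <- sample.int(buf$size, n, replace = buf$size < n)
  list(s = buf$s[idx, , drop = FALSE], a = buf$a[idx], r = buf$r[idx],
       s2 = buf$s2[idx, , drop = FALSE], done = buf$done[idx],
       k = buf$k[idx], a_idm = buf$a_idm[idx])
}

## ---- updates ---------------------------------------------------------------

critic_q <- function(net, s_norm, a) {
  mlp_forward(net, cbind(s_norm, a))
}

#' Twin-critic update
#'
#' Regresses both critics toward the clipped double-Q target
#' `y = r + gamma * (1 - done) * min_i Q_targ_i(s', a')` where `a'` is the
#' target policy's action with clipped Gaussian smoothing noise. One Adam
#' step per critic at the critic learning rate.
#'
#' @param agent a `td3_agent`.
#' @param batch a [replay_sample()] batch.
#' @return List with updated `agent` and the two critic mean-squared
#'   losses; also exposes the targets `y` for inspection.
#' @export
critic_update <- function(agent, batch) {
  cfg <- agent$config
  if (length(batch$r) == 0L) stop("empty batch")
  s_n <- norm_state(agent, batch$s)
  s2_n <- norm_state(agent, batch$s2)
  a2 <- mlp_forward(agent$actor_targ, s2_n)$out
  if (cfg$target_noise > 0) {
    eps <- pmin(pmax(rnorm(length(a2), 0, cfg$target_noise),
                     -cfg$noise_clip), cfg$noise_clip)
    a2 <- pmin(pmax(a2 + eps, -1), 1)
  }
  q1t <- critic_q(agent$critic1_targ, s2_n, a2)$out
  q2t <- critic_q(agent$critic2_targ, s2_n, a2)$out
  y <- batch$r + cfg$gamma * (1 - batch$done) * pmin(q1t, q2t)
  n <- length(y)
  losses <- numeric(2)
  for (ci in 1:2) {
    net <- agent[[paste0("critic", ci)]]
    fw <- critic_q(net, s_n, batch$a)
    err <- fw$out - y
    losses[ci] <- mean(err^2)
    g <- mlp_backward(net, fw, matrix(2 * err / n, ncol = 1))
    upd <- adam_step(net, agent[[paste0("opt_c", ci)]], g$gW, g$gb,
                     cfg$lr_critic)
    agent[[paste0("critic", ci)]] <- upd$net
    agent[[paste0("opt_c", ci)]] <- upd$opt
  }
  list(agent = agent, losses = losses, y = as.numeric(y))
}

#' Guided actor update
#'
#' Ascends `Q_1(s, pi(s))` while descending the behaviour-cloning penalty
#' `bc_weight * k * (a_idm - pi(s))^2` over the batch: transitions whose
#' risk gate is 0 contribute no cloning gradient, so with `k = 0`
#' everywhere the update is the standard TD3 actor step.
#'
#' @param agent a `td3_agent`.
#' @param batch a [replay_sample()] batch.
#' @return List with updated `agent` and the scalar actor loss
#'   (`-mean Q + bc penalty`).
#' @export
actor_update_guided <- function(agent, batch) {
  cfg <- agent$config
  s_n <- norm_state(agent, batch$s)
  fw_a <- mlp_forward(agent$actor, s_n)
  a_pi <- fw_a$out
  n <- nrow(s_n)
  fw_q <- critic_q(agent$critic1, s_n, a_pi)
  ## dQ/da: backprop a unit gradient through the critic to its action input
  gq <- mlp_backward(agent$critic1, fw_q, matrix(1 / n, n, 1))
  dq_da <- gq$dIn[, ncol(gq$dIn), drop = FALSE]
  bc_grad <- 2 * cfg$bc_weight * batch$k * (a_pi - batch$a_idm) / n
  dL_da <- -dq_da + bc_grad
  g <- mlp_backward(agent$actor, fw_a, dL_da)
  upd <- adam_step(agent$actor, agent$opt_actor, g$gW, g$gb, cfg$lr_actor)
  agent$actor <- upd$net
  agent$opt_actor <- upd$opt
  loss <- -mean(fw_q$out) +
    cfg$bc_weight * mean(batch$k * (batch$a_idm - a_pi)^2)
  list(agent = agent, loss = loss)
}

#' Polyak (exponential) target network update
#'
#' `targ <- rho * targ + (1 - rho) * source` for both target critics and
#' the target actor. `rho = 1` freezes the targets; `rho = 0` copies the
#' sources.
#'
#' @param agent a `td3_agent`.
#' @param rho averaging constant in [0, 1]; defaults to the configured
#'   value.
#' @return The agent with updated targets.
#' @export
polyak_update <- function(agent, rho = NULL) {
  if (is.null(rho)) rho <- agent$config$rho
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]")
  mix <- function(targ, src) {
    for (l in seq_along(targ$W)) {
      targ$W[[l]] <- rho * targ$W[[l]] + (1 - rho) * src$W[[l]]
      targ$b[[l]] <- rho * targ$b[[l]] + (1 - rho) * src$b[[l]]
    }
    targ
  }
  agent$actor_targ <- mix(agent$actor_targ, agent$actor)
  agent$critic1_targ <- mix(agent$critic1_targ, agent$critic1)
  agent$critic2_targ <- mix(agent$critic2_targ, agent$critic2)
  agent
}

## ---- training protocol -----------------------------------------------------

#' Alternating human-in-loop / agent-only training protocol
#'
#' Runs `2 * n_pairs` episodes. Odd episodes are guided training episodes:
#' the risk gate switches control to IDM ([switch_action()]), transitions
#' are stored and the networks updated (critics every step after warm-up,
#' actor and targets at the policy delay). Even episodes are agent-only
#' test episodes: the gate is forced to 0, actions are deterministic, and
#' no learning happens. With `guidance = "none"` the gate is 0 everywhere
#' (the plain-TD3 control arm, which still trains on odd episodes).
#'
#' @param config a [scenario_config()].
#' @param agent a `td3_agent` (modified copy returned).
#' @param guidance `"oracle"` (ground-truth risk phase), `"fnirs"`
#'   (online detector on a synchronised synthetic episode) or `"none"`.
#' @param n_pairs number of guided/test episode pairs.
#' @param seed master seed (episode trigger draws, exploration noise).
#' @param detector,selector fitted [train_detector()] /[fit_selector()]
#'   artifacts; required when `guidance = "fnirs"`.
#' @param episode_profile [scenario_profile()] used to synthesise the
#'   fNIRS stream in `"fnirs"` mode (its scenario must match `config`).
#' @param updates_per_step gradient updates per environment step.
#' @return List with `log` (one row per episode: cumulative reward, max
#'   risk-field value, min TTC, mean absolute/positive/negative jerk,
#'   collision flag, guided flag, steps) and the trained `agent`.
#' @export
run_protocol <- function(config, agent, guidance = c("oracle", "none", "fnirs"),
                         n_pairs = 30, seed = 1, detector = NULL,
                         selector = NULL, episode_profile = NULL,
                         updates_per_step = 1) {
  guidance <- match.arg(guidance)
  if (guidance == "fnirs") {
    if (is.null(detector) || is.null(selector))
      stop("fnirs guidance requires a detector and selector")
    if (is.null(episode_profile)) episode_profile <- scenario_profile(config$scenario)
    if (episode_profile$scenario != config$scenario)
      stop("episode profile scenario does not match the simulator scenario")
  }
  cfg <- agent$config
  buf <- replay_init(cfg$buffer_cap, agent$state_dim)
  total_steps <- 0L
  rows <- list()
  set.seed(as.integer(seed))
  ep_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_pairs)

  for (ep in seq_len(2L * n_pairs)) {
    guided_ep <- (ep %% 2L == 1L)
    env <- sim_reset(config, seed = ep_seeds[ep])
    ## synchronise an fNIRS stream to this episode's scripted risk window
    k_lookup <- NULL
    if (guidance == "fnirs" && guided_ep) {
      k_lookup <- fnirs_gate_for_episode(env, detector, selector,
                                         episode_profile, ep_seeds[ep])
    }
    s <- sim_state(env)
    cum_r <- 0; max_rf <- 0; min_ttc <- Inf
    jerks <- numeric(0)
    done <- FALSE
    ## scripted stable phase: the ego holds its cruise speed for the first
    ## 10 s (the participant's "stable driving" span); the agent takes
    ## over at handover
    hold <- accel_to_action(0, config$accel_bounds)
    while (!done && env$t < 10) {
      st <- sim_step(env, hold)
      env <- st$env
      s <- st$state
      done <- st$done
    }
    while (!done) {
      a_rl <- if (guided_ep) {
        if (total_steps < cfg$warmup)
          accel_to_action(runif(1, cfg$warmup_accel[1], cfg$warmup_accel[2]),
                          config$accel_bounds)
        else select_action(agent, s, explore = TRUE)
      } else {
        select_action(agent, s, explore = FALSE)
      }
      a_idm <- sim_idm_action(env)
      k <- 0L
      if (guided_ep) {
        k <- switch(guidance,
                    oracle = sim_risk_active(env),
                    none = 0L,
                    fnirs = k_lookup(env$t))
      }
      a_exec <- switch_action(a_rl, a_idm, k)
      st <- sim_step(env, a_exec)
      env <- st$env
      if (guided_ep) {
        a_store <- if (cfg$store_executed) a_exec else a_rl
        buf <- replay_add(buf, s, a_store, st$reward, st$state,
                          as.numeric(st$done), k, a_idm)
        total_steps <- total_steps + 1L
        if (total_steps >= cfg$warmup && buf$size >= cfg$batch_size) {
          for (u in seq_len(updates_per_step)) {
            batch <- replay_sample(buf, cfg$batch_size)
            cu <- critic_update(agent, batch)
            agent <- cu$agent
            agent$n_updates <- agent$n_updates + 1L
            if (agent$n_updates %% cfg$policy_delay == 0L) {
              au <- actor_update_guided(agent, batch)
              agent <- au$agent
              agent <- polyak_update(agent)
            }
          }
        }
      }
      cum_r <- cum_r + st$reward
      if (is.finite(st$info$risk_field))
        max_rf <- max(max_rf, st$info$risk_field)
      min_ttc <- min(min_ttc, st$info$ttc)
      jerks <- c(jerks, st$info$jerk)
      s <- st$state
      done <- st$done
    }
    if (env$flags$collision) min_ttc <- 0
    rows[[ep]] <- data.frame(
      episode = ep, guided = guided_ep, reward = cum_r,
      max_risk_field = max_rf, min_ttc = min_ttc,
      mean_abs_jerk = mean(abs(jerks)),
      mean_pos_jerk = if (any(jerks > 0)) mean(jerks[jerks > 0]) else 0,
      mean_neg_jerk = if (any(jerks < 0)) mean(jerks[jerks < 0]) else 0,
      collision = env$flags$collision,
      near_miss = env$flags$near_miss,
      steps = env$step_count)
  }
  list(log = do.call(rbind, rows), agent = agent)
}

## Build a k(t) lookup from an online detection run on a synthetic episode
## whose risk interval matches the simulator's scripted risk window.
fnirs_gate_for_episode <- function(env, detector, selector, profile, seed) {
  cfg <- env$config
  ## scripted risk onset (s1's depends on the trigger distance; solve the
  ## pre-risk kinematics cheaply by simulation with a zero-accel probe)
  probe <- env
  onset <- NA; offset <- NA
  while (!probe$done) {
    st <- sim_step(probe, accel_to_action(0, cfg$accel_bounds))
    probe <- st$env
    if (is.na(onset) && sim_risk_active(probe) == 1) onset <- probe$t
    if (!is.na(onset) && sim_risk_active(probe) == 0) { offset <- probe$t; break }
  }
  if (is.na(onset)) onset <- 10
  if (is.na(offset)) offset <- min(onset + 5, cfg$episode_cap_s)
  base <- profile$baseline_s
  epi <- generate_episode(
    duration_s = base + cfg$episode_cap_s + 1,
    risk_intervals = list(c(base + onset, base + offset)),
    noise = profile$noise, hrf_amplitude = profile$hrf_amplitude,
    baseline_s = base, seed = seed)
  det <- online_detect(epi, detector, selector)
  function(t) {
    tt <- base + t
    i <- findInterval(tt, det$time)
    if (i < 1) 0L else as.integer(det$k_fnirs[i])
  }
}
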