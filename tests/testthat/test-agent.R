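test_that("action selection is deterministic, clipped, and noise-limited", {
  ag <- td3_init(tiny_td3(), seed = 1)
  s <- rnorm(8)
  expect_identical(select_action(ag, s), select_action(ag, s))
  set.seed(2)
  S <- matrix(rnorm(10000 * 8, 0, 50), ncol = 8)
  a <- select_action(ag, S)
  expect_true(all(a >= -1 & a <= 1))
  ## zero exploration noise is the deterministic policy
  ag0 <- td3_init(tiny_td3(expl_noise = 0), seed = 1)
  expect_identical(select_action(ag0, s, explore = TRUE),
                   select_action(ag0, s, explore = FALSE))
  expect_error(select_action(ag, rnorm(5)), "dimension")
})

test_that("risk-gated switching is exact at both gate values", {
  expect_equal(switch_action(0.7, -0.9, 1), -0.9)
  expect_equal(switch_action(0.7, -0.9, 0), 0.7)
  ## elementwise over a logged trace
  set.seed(3)
  a_rl <- runif(200, -1, 1); a_idm <- runif(200, -1, 1)
  k <- rbinom(200, 1, 0.3)
  expect_equal(switch_action(a_rl, a_idm, k),
               ifelse(k == 1, a_idm, a_rl))
  expect_error(switch_action(0.1, 0.2, 0.5), "boolean")
})

test_that("the critic target matches hand arithmetic on frozen tiny networks", {
  cfg <- td3_config(hidden = 1, gamma = 0.5, target_noise = 0,
                    batch_size = 1, state_scale = rep(1, 2))
  ag <- td3_init(cfg, state_dim = 2, seed = 1)
  ## freeze hand-chosen weights: actor_targ outputs tanh(0) = 0;
  ## critic targets are constant: Q1t = 2*relu(1) + 0.5 = 2.5, Q2t = 1.0
  zero_net <- function(net, b1, w2, b2) {
    net$W[[1]][] <- 0; net$b[[1]] <- b1
    net$W[[2]][] <- w2; net$b[[2]] <- b2
    net
  }
  ag$actor_targ <- zero_net(ag$actor_targ, 0, 0, 0)
  ag$critic1_targ <- zero_net(ag$critic1_targ, 1, 2, 0.5)
  ag$critic2_targ <- zero_net(ag$critic2_targ, 1, 1, 0)
  batch <- list(s = matrix(c(0.3, -0.2), 1), a = 0.4, r = 2,
                s2 = matrix(c(0.1, 0.1), 1), done = 0, k = 0, a_idm = 0)
  res <- critic_update(ag, batch)
  ## y = r + gamma * min(2.5, 1.0) = 2 + 0.5 * 1 = 2.5
  expect_equal(res$y, 2.5, tolerance = 1e-12)
  ## gamma = 0 reduces the target to the reward alone
  ag$config$gamma <- 0
  expect_equal(critic_update(ag, batch)$y, 2, tolerance = 1e-12)
  ## identical twin critics give identical losses
  ag$critic2 <- ag$critic1
  ag$opt_c2 <- ag$opt_c1
  res2 <- critic_update(ag, batch)
  expect_equal(res2$losses[1], res2$losses[2], tolerance = 1e-12)
  expect_error(critic_update(ag, list(r = numeric(0))), "empty")
})

test_that("the twin-critic target tracks the smaller critic", {
  cfg <- td3_config(hidden = 1, gamma = 1, target_noise = 0,
                    state_scale = rep(1, 2))
  ag <- td3_init(cfg, state_dim = 2, seed = 2)
  set_const <- function(net, q) {
    net$W[[1]][] <- 0; net$b[[1]] <- 1
    net$W[[2]][] <- 0; net$b[[2]] <- q
    net
  }
  ag$critic1_targ <- set_const(ag$critic1_targ, 5)
  ag$critic2_targ <- set_const(ag$critic2_targ, 5 - 2)  # smaller by c = 2
  batch <- list(s = matrix(0, 1, 2), a = 0, r = 0,
                s2 = matrix(0, 1, 2), done = 0, k = 0, a_idm = 0)
  expect_equal(critic_update(ag, batch)$y, 3, tolerance = 1e-12)
})

test_that("the guided actor update reduces to the plain TD3 step when the gate is 0", {
  set.seed(4)
  cfg <- tiny_td3(bc_weight = 1)
  ag_a <- td3_init(cfg, seed = 5)
  ag_b <- td3_init(tiny_td3(bc_weight = 7), seed = 5)  # different bc weight
  batch <- list(s = matrix(rnorm(16 * 8), 16), a = runif(16, -1, 1),
                r = rnorm(16), s2 = matrix(rnorm(16 * 8), 16),
                done = rep(0, 16), k = rep(0, 16),
                a_idm = runif(16, -1, 1))
  ra <- actor_update_guided(ag_a, batch)
  rb <- actor_update_guided(ag_b, batch)
  ## k = 0 everywhere: the cloning term is inert, any bc weight gives the
  ## same (standard) actor step
  expect_equal(ra$agent$actor, rb$agent$actor, tolerance = 1e-14)
})

test_that("a policy already matching IDM gets no cloning gradient", {
  cfg <- tiny_td3()
  ag <- td3_init(cfg, seed = 6)
  s <- matrix(rnorm(16 * 8), 16)
  a_pi <- select_action(ag, s)
  batch1 <- list(s = s, a = a_pi, r = rnorm(16), s2 = s,
                 done = rep(0, 16), k = rep(1, 16), a_idm = a_pi)
  batch0 <- batch1; batch0$k <- rep(0, 16)
  r1 <- actor_update_guided(ag, batch1)
  r0 <- actor_update_guided(ag, batch0)
  expect_equal(r1$agent$actor, r0$agent$actor, tolerance = 1e-14)
})

test_that("with a frozen flat critic, cloning drives the policy to IDM", {
  cfg <- tiny_td3(lr_actor = 1e-2, bc_weight = 1)
  ag <- td3_init(cfg, seed = 7)
  ## flat critic: dQ/da = 0, so only the cloning term acts
  for (l in seq_along(ag$critic1$W)) ag$critic1$W[[l]][] <- 0
  set.seed(8)
  s <- matrix(rnorm(16 * 8), 16)
  a_idm <- runif(16, -0.8, 0.8)
  batch <- list(s = s, a = a_idm, r = rep(0, 16), s2 = s,
                done = rep(0, 16), k = rep(1, 16), a_idm = a_idm)
  d0 <- mean((select_action(ag, s) - a_idm)^2)
  for (i in 1:300) ag <- actor_update_guided(ag, batch)$agent
  d1 <- mean((select_action(ag, s) - a_idm)^2)
  expect_lt(d1, d0 / 10)
})

test_that("Polyak updates interpolate and hit both limits", {
  ag <- td3_init(tiny_td3(), seed = 9)
  frozen <- ag$actor_targ
  ag2 <- polyak_update(ag, rho = 1)
  expect_identical(ag2$actor_targ, frozen)
  ag3 <- polyak_update(ag, rho = 0)
  expect_identical(ag3$actor_targ$W, ag$actor$W)
  ## scalar check: targ 1, source 3, rho 0.9 -> 1.2
  ag$actor_targ$W[[1]][] <- 1
  ag$actor$W[[1]][] <- 3
  ag4 <- polyak_update(ag, rho = 0.9)
  expect_equal(ag4$actor_targ$W[[1]][1, 1], 1.2, tolerance = 1e-12)
  expect_error(polyak_update(ag, rho = 1.5), "rho")
})

test_that("replay sampling is uniform and bounded by the fill level", {
  buf <- replay_init(50, 2)
  for (i in 1:20)
    buf <- replay_add(buf, c(i, i), 0, 0, c(i, i), 0, 0, 0)
  expect_equal(buf$size, 20L)
  set.seed(10)
  draws <- unlist(lapply(1:2000, function(i) replay_sample(buf, 5)$s[, 1]))
  expect_true(all(draws %in% 1:20))
  expect_gt(stats::chisq.test(table(factor(draws, levels = 1:20)))$p.value,
            0.01)
  expect_error(replay_sample(replay_init(10, 2), 1), "empty")
})

test_that("the protocol is deterministic and its control arm ignores guidance plumbing", {
  cfg <- scenario_config(1, dt = 0.1)
  acfg <- tiny_td3(warmup = 100)
  r1 <- run_protocol(cfg, td3_init(acfg, seed = 1), guidance = "none",
                     n_pairs = 2, seed = 11)
  r2 <- run_protocol(cfg, td3_init(acfg, seed = 1), guidance = "none",
                     n_pairs = 2, seed = 11)
  expect_identical(r1$log, r2$log)
  expect_equal(nrow(r1$log), 4)
  expect_identical(r1$log$guided, c(TRUE, FALSE, TRUE, FALSE))
  ## guided episodes under oracle guidance execute IDM while risk is active
  env <- sim_reset(cfg, seed = 2)
  hold <- accel_to_action(0, cfg$accel_bounds)
  while (!sim_risk_active(env)) env <- sim_step(env, hold)$env
  a_idm <- sim_idm_action(env)
  expect_equal(switch_action(0.42, a_idm, sim_risk_active(env)), a_idm)
})
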