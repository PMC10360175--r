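# network whose outputs are a constant vector of Q-values (one per action)
rig_net <- function(out_bias) {
  net <- init_qnetwork(qnetwork_spec(hidden = c(4L), seed = 1L))
  L <- length(net$W)
  net$W[[L]][] <- 0
  net$b[[L]] <- out_bias
  net
}

rand_states <- function(n, seed = 1) {
  set.seed(seed)
  matrix(stats::runif(n * 12), n, 12)
}

test_that("epsilon-greedy selection spans pure exploration to exploitation", {
  s <- rand_states(10000, 2)
  q1 <- init_qnetwork(qnetwork_spec(seed = 3L))
  set.seed(5)
  a <- select_actions(q1, s, epsilon = 1)
  counts <- table(factor(a, levels = 0:7))
  sigma <- sqrt(10000 * (1 / 8) * (7 / 8))
  expect_true(all(abs(counts - 1250) < 3 * sigma))

  rig <- rig_net(c(0, 0, 0, 0, 1, 0, 0, 0))   # action 4 maximal everywhere
  expect_true(all(select_actions(rig, s[1:50, ], epsilon = 0) == 4L))

  tie <- rig_net(c(0, 0, 1, 0, 0, 1, 0, 0))   # exact tie between 2 and 5
  expect_true(all(select_actions(tie, s[1:50, ], epsilon = 0) == 2L))
})

test_that("the squared TD loss matches hand evaluation and has a fixed point", {
  s <- rand_states(1, 7)
  batch <- collect_transitions(s, 2L, 0.2, s)
  tl <- td_loss(rig_net(rep(0.3, 8)), rig_net(rep(0.5, 8)), batch, gamma = 1)
  expect_equal(tl$loss, (0.2 + 0.5 - 0.3)^2)

  fixed <- td_loss(rig_net(rep(0.5, 8)), rig_net(rep(0.5, 8)),
                   collect_transitions(s, 1L, 0, s), gamma = 1)
  expect_equal(fixed$loss, 0)

  # discounting scales the bootstrap term
  tl0 <- td_loss(rig_net(rep(0.3, 8)), rig_net(rep(0.5, 8)), batch, gamma = 0)
  expect_equal(tl0$loss, (0.2 - 0.3)^2)
})

test_that("TD gradients agree with finite differences and ignore q2", {
  set.seed(9)
  q1 <- init_qnetwork(qnetwork_spec(hidden = c(5L), seed = 21L))
  q2 <- init_qnetwork(qnetwork_spec(hidden = c(5L), seed = 22L))
  s <- rand_states(6, 10)
  s2 <- rand_states(6, 11)
  batch <- collect_transitions(s, sample(0:7, 6, TRUE), stats::rnorm(6), s2)
  tl <- td_loss(q1, q2, batch, gamma = 0.9)
  expect_identical(length(tl$grads$W), length(q1$W))
  h <- 1e-6
  for (probe in list(c(1, 3, 2), c(2, 4, 7))) {
    k <- probe[1]
    qp <- q1; qp$W[[k]][probe[2], probe[3]] <- qp$W[[k]][probe[2], probe[3]] + h
    qm <- q1; qm$W[[k]][probe[2], probe[3]] <- qm$W[[k]][probe[2], probe[3]] - h
    num <- (td_loss(qp, q2, batch, gamma = 0.9)$loss -
            td_loss(qm, q2, batch, gamma = 0.9)$loss) / (2 * h)
    expect_equal(tl$grads$W[[k]][probe[2], probe[3]], num, tolerance = 1e-4)
  }
})

test_that("the target network syncs every C updates and copies exactly", {
  q1 <- init_qnetwork(qnetwork_spec(seed = 1L))
  q2 <- init_qnetwork(qnetwork_spec(seed = 2L))
  for (step in 1:9) {
    q2 <- sync_target(q1, q2, step, C = 10L)
    expect_false(identical(q2$W, q1$W))
  }
  q2 <- sync_target(q1, q2, 10L, C = 10L)
  expect_identical(q2$W, q1$W)
  s <- rand_states(20, 3)
  expect_equal(apply(q_values(q2, s), 1, max), apply(q_values(q1, s), 1, max))
  q3 <- sync_target(q1, init_qnetwork(qnetwork_spec(seed = 5L)), 1L, C = 1L)
  expect_identical(q3$W, q1$W)
})

test_that("the replay buffer is FIFO-bounded and samples uniformly", {
  buf <- replay_buffer(10L)
  for (i in 1:13) {
    push_transitions(buf, collect_transitions(rand_states(1, i), 0L, i,
                                              rand_states(1, i)))
  }
  expect_length(buf, 10L)
  expect_equal(buffer_contents(buf)$r, 4:13, ignore_attr = TRUE)

  buf2 <- replay_buffer(200L)
  push_transitions(buf2, collect_transitions(rand_states(200, 1),
                                             rep(0L, 200), 1:200,
                                             rand_states(200, 2)))
  set.seed(13)
  counts <- integer(200)
  for (b in 1:400) {
    idx <- sample_transitions(buf2, 20L)$r
    counts[idx] <- counts[idx] + 1L
  }
  expect_gt(stats::chisq.test(counts)$p.value, 1e-6)
  expect_error(sample_transitions(buf, 11L), "size")
})

test_that("training runs the full episode x step accounting deterministically", {
  states <- rand_states(5, 42)
  colnames(states) <- state_feature_names()
  rule <- function(s) if (s[[1]] < 0.5) 1L else 2L
  cfg <- agent_config(episodes = 2L, batch_size = 4L, seed = 8L,
                      gamma = 0, updates_per_step = 1L)
  fit1 <- train_dqn(bandit_env(states, rule, steps_per_episode = 3L), cfg)
  fit2 <- train_dqn(bandit_env(states, rule, steps_per_episode = 3L), cfg)
  expect_identical(nrow(fit1$history), 6L)
  expect_length(fit1$buffer, 30L)
  expect_identical(fit1$history$reward, fit2$history$reward)
  expect_true(all(is.finite(fit1$history$reward)))
  expect_identical(fit1$history$episode, rep(1:2, each = 3L))
})

test_that("epsilon decays linearly between its endpoints", {
  cfg <- agent_config(epsilon_start = 1, epsilon_end = 0.1,
                      epsilon_decay_steps = 10L)
  eps <- vapply(1:21, function(g) adaptaug:::epsilon_at(cfg, g, 20L),
                numeric(1))
  expect_equal(eps[1], 1)
  expect_equal(eps[11], 0.1)
  expect_equal(eps[21], 0.1)
  expect_equal(diff(eps[1:11]), rep(-0.09, 10), tolerance = 1e-12)
})
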