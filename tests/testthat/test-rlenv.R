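make_env <- function(finetune_epochs = 3, seed = 2L) {
  sp <- fixture_split()
  pre <- fixture_pretrain()
  env_init(sp$pretrain, sp$test, snapshot(pre$model),
           env_config(finetune_cfg = train_config(epochs = finetune_epochs,
                                                  learning_rate = 0.3,
                                                  seed = 7L),
                      seed = seed))
}

test_that("a perfect pre-trained model gives the maximal baseline Dice", {
  sp <- fixture_split()
  oracle <- pretrain("oracle", sp$pretrain, sp$test, train_config())$model
  env <- env_init(sp$pretrain, sp$test, snapshot(oracle), env_config())
  expect_equal(env$d0, 2)
  expect_identical(length(env$father), length(sp$pretrain))
})

test_that("reset restores the initial state vector and counts episodes", {
  env <- make_env()
  s0 <- env_reset(env)
  expect_identical(env$episode_index, 1L)
  out <- env_step(env, rep(1L, length(env$father)))
  expect_false(identical(out$state, s0))
  s1 <- env_reset(env)
  expect_identical(s1, s0)
  expect_identical(env$episode_index, 2L)
  expect_identical(env_reset(env), s0)
  expect_identical(env$episode_index, 3L)
  expect_equal(env$d_prev, env$d0)
})

test_that("a no-op step with zero-epoch fine-tuning earns exactly zero reward", {
  env <- make_env(finetune_epochs = 0)
  env_reset(env)
  out <- env_step(env, rep(0L, length(env$father)))
  expect_identical(out$reward, 0)
  expect_false(out$done)
})

test_that("the retraining set holds I0 plus exactly one descendant per image", {
  sp <- fixture_split()
  child <- apply_action_vector(sp$pretrain, rep(2L, length(sp$pretrain)))
  retrain <- concat_image_vectors(sp$pretrain, child)
  expect_length(retrain, 2L * length(sp$pretrain))
  ids <- vapply(retrain$items, `[[`, character(1), "id")
  expect_true(all(table(ids) == 2L))
})

test_that("steps are deterministic and rewards telescope over an episode", {
  env1 <- make_env(seed = 5L)
  env2 <- make_env(seed = 5L)
  set.seed(77)
  acts <- lapply(1:3, function(i) sample(0:7, length(env1$father), TRUE))
  env_reset(env1); env_reset(env2)
  total <- 0
  for (i in 1:3) {
    o1 <- env_step(env1, acts[[i]])
    o2 <- env_step(env2, acts[[i]])
    expect_identical(o1$reward, o2$reward)
    expect_identical(o1$state, o2$state)
    total <- total + o1$reward
  }
  expect_true(o1$done)
  expect_equal(total, 100 * (env1$d_prev - env1$d0), tolerance = 1e-9)
  expect_error(env_step(env1, acts[[1]]), "episode is over")
})

test_that("episode rewards do not leak across episodes", {
  env <- make_env(seed = 9L)
  acts <- lapply(1:3, function(i) rep(c(1L, 4L)[1 + i %% 2], length(env$father)))
  env_reset(env)
  r1 <- vapply(acts, function(a) env_step(env, a)$reward, numeric(1))
  env_reset(env)
  r2 <- vapply(acts, function(a) env_step(env, a)$reward, numeric(1))
  expect_identical(r1, r2)
})

test_that("per-image transitions share the step reward and keep order", {
  s <- matrix(stats::runif(60), 5, 12,
              dimnames = list(NULL, state_feature_names()))
  s2 <- matrix(stats::runif(60), 5, 12)
  tb <- collect_transitions(s, c(0L, 3L, 7L, 1L, 1L), 2.5, s2)
  expect_length(tb, 5L)
  expect_equal(tb$r, rep(2.5, 5))
  expect_equal(tb$a, c(0L, 3L, 7L, 1L, 1L))
  expect_equal(tb$s[4, ], s[4, ], ignore_attr = TRUE)
  expect_error(collect_transitions(s, c(1L, 2L), 1, s2), "misaligned")
  expect_error(collect_transitions(s, c(0L, 3L, 7L, 1L, 1L), c(1, 2), s2),
               "scalar or one per image")
})

test_that("step info records the evaluation metrics", {
  env <- make_env()
  env_reset(env)
  out <- env_step(env, rep(0L, length(env$father)))
  expect_true(all(c("episode", "step", "dice", "reward", "PA", "MPA", "CPA",
                    "IoU", "MIoU") %in% names(out$info)))
  expect_error(env_step(env, rep(0L, 3L)), "one action per")
})
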