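#' Environment configuration
#'
#' @param steps_per_episode Steps `T` per episode (3 by default: one episode
#'   augments the set three times before the father vector is reset).
#' @param mask_mode `"oracle"` (use the items' own labels for state
#'   extraction) or `"identifier"`.
#' @param finetune_cfg [train_config()] used for the per-step fine-tuning.
#' @param dice_factor Constant of the Dice-style score (default 2).
#' @param noise_sd Gaussian-noise standard deviation for action 7.
#' @param seed Environment seed (drives the per-step noise streams).
#' @param leaf_identifier,rust_identifier Models for identifier mode.
#' @return A list of class `env_config`.
#' @export
env_config <- function(steps_per_episode = 3L,
                       mask_mode = c("oracle", "identifier"),
                       finetune_cfg = train_config(epochs = 3, learning_rate = 0.3),
                       dice_factor = 2, noise_sd = 10, seed = 1L,
                       leaf_identifier = NULL, rust_identifier = NULL) {
  mask_mode <- match.arg(mask_mode)
  stopifnot(steps_per_episode >= 1)
  structure(list(steps_per_episode = as.integer(steps_per_episode),
                 mask_mode = mask_mode, finetune_cfg = finetune_cfg,
                 dice_factor = dice_factor, noise_sd = noise_sd,
                 seed = as.integer(seed),
                 leaf_identifier = leaf_identifier,
                 rust_identifier = rust_identifier),
            class = "env_config")
}

#' Initialize the augmentation environment
#'
#' The environment owns the pre-training image vector `I0`, the fixed test
#' set, and a snapshot of the pre-trained segmentation model. Each step
#' augments the current father vector per image, fine-tunes a restored copy
#' of the pre-trained model on `I0` plus the child vector, evaluates it on
#' the test set, and returns 100 times the change in the Dice-style score as
#' the reward.
#'
#' @param pretrain_set,test_set [image_vector()]s.
#' @param model_snapshot A `seg_snapshot` of the pre-trained model (from
#'   [snapshot()]).
#' @param cfg An [env_config()].
#' @return An object of class `aug_env` (an R environment; stepping mutates
#'   it in place).
#' @export
env_init <- function(pretrain_set, test_set, model_snapshot, cfg = env_config()) {
  stopifnot(inherits(pretrain_set, "image_vector"), length(pretrain_set) >= 1,
            inherits(test_set, "image_vector"), length(test_set) >= 1)
  model <- restore(model_snapshot)   # errors on incompatible blobs
  e <- new.env(parent = emptyenv())
  e$pretrain <- pretrain_set
  e$test <- test_set
  e$snapshot <- model_snapshot
  e$cfg <- cfg
  e$source <- if (cfg$mask_mode == "oracle") mask_source("oracle") else {
    mask_source("identifier", cfg$leaf_identifier, cfg$rust_identifier)
  }
  base_ev <- evaluate_model(model, test_set, dice_factor = cfg$dice_factor)
  e$d0 <- base_ev$dice$d
  e$father <- pretrain_set
  e$t <- 0L
  e$d_prev <- e$d0
  e$episode_index <- 0L
  class(e) <- c("aug_env", "environment")
  e
}

#' Reset an environment to the start of a new episode
#'
#' Restores `I0` as the father vector, discards the image vectors of the
#' previous episode, resets the step counter and the previous Dice value to
#' the pre-trained baseline, and increments the episode index.
#'
#' @param env An environment created by [env_init()] (or a mock environment).
#' @return The state of the restored father vector (a tibble, one row per
#'   image).
#' @export
env_reset <- function(env) UseMethod("env_reset")

#' @export
env_reset.aug_env <- function(env) {
  env$father <- env$pretrain
  env$t <- 0L
  env$d_prev <- env$d0
  env$episode_index <- env$episode_index + 1L
  extract_state_vector(env$father, env$source)
}

#' Execute one environment step
#'
#' Applies `actions` per image to the father vector, builds the retraining
#' set `I0` plus the child (size `2m`), restores the pre-trained snapshot,
#' fine-tunes it on the retraining set, evaluates on the test set, and emits
#' `100 * (d_t - d_prev)` as the reward. The child becomes the next father.
#'
#' @param env An `aug_env`.
#' @param actions Integer vector of action ids, one per father image.
#' @return List with `state` (tibble of the child's states), `reward`
#'   (number), `done` (`TRUE` when the episode's step budget is exhausted),
#'   and `info` (one-row tibble: episode, step, dice, reward and the five
#'   pooled test metrics).
#' @export
env_step <- function(env, actions) UseMethod("env_step")

#' @export
env_step.aug_env <- function(env, actions) {
  cfg <- env$cfg
  if (env$t >= cfg$steps_per_episode) {
    stop("episode is over (t = T); call env_reset()", call. = FALSE)
  }
  if (length(actions) != length(env$father)) {
    stop("need exactly one action per father image", call. = FALSE)
  }
  step_seed <- derive_seed(cfg$seed, env$episode_index * 10000L + env$t + 1L)
  child <- apply_action_vector(env$father, actions,
                               noise_sd = cfg$noise_sd, noise_seed = step_seed)
  retrain_set <- concat_image_vectors(env$pretrain, child)
  model <- finetune(restore(env$snapshot), retrain_set, cfg$finetune_cfg)
  ev <- evaluate_model(model, env$test, dice_factor = cfg$dice_factor)
  r <- reward(ev$dice$d, env$d_prev)
  if (!is.finite(r)) stop("non-finite reward", call. = FALSE)
  state <- extract_state_vector(child, env$source)
  env$father <- child
  env$d_prev <- ev$dice$d
  env$t <- env$t + 1L
  info <- dplyr::bind_cols(
    tibble::tibble(episode = env$episode_index, step = env$t,
                   dice = ev$dice$d, reward = r),
    ev$metrics
  )
  list(state = state, reward = r, done = env$t >= cfg$steps_per_episode,
       info = info)
}

#' Pair states, actions and rewards into replay transitions
#'
#' Decomposes one vector-level step into per-image transitions: the i-th
#' transition pairs state row i with action i and next-state row i. The
#' step-level scalar reward is shared by every transition of the step (a
#' per-image reward vector is also accepted, for mock environments).
#'
#' @param s,s_next State tibbles (or matrices) with one row per image.
#' @param a Integer action vector.
#' @param r Reward: scalar (recycled) or one value per image.
#' @return A list of class `transition_batch` with aligned components `s`
#'   (matrix), `a`, `r`, `s_next` (matrix); its length is the image count.
#' @export
collect_transitions <- function(s, a, r, s_next) {
  sm <- if (is.matrix(s)) s else state_matrix(s)
  snm <- if (is.matrix(s_next)) s_next else state_matrix(s_next)
  m <- nrow(sm)
  if (length(a) != m || nrow(snm) != m) {
    stop("misaligned transition components", call. = FALSE)
  }
  if (length(r) == 1L) r <- rep(r, m)
  if (length(r) != m) stop("reward must be scalar or one per image", call. = FALSE)
  structure(list(s = sm, a = as.integer(a), r = as.numeric(r), s_next = snm),
            class = "transition_batch")
}

#' @export
length.transition_batch <- function(x) nrow(x$s)

#' Mock contextual-bandit environment with a planted best action
#'
#' A lightweight environment for studying the agent in isolation from the
#' segmentation loop: states are feature rows of real (generated) images, and
#' the reward for each image is +1 when the chosen action matches a planted
#' state-dependent rule and -1 otherwise. Episodes last
#' `steps_per_episode` steps; every step presents the same state rows.
#'
#' @param states A state tibble (from [extract_state_vector()]) or matrix.
#' @param rule Function mapping a 12-feature state row to the planted best
#'   action id.
#' @param steps_per_episode Steps per episode.
#' @return An object of class `bandit_env`.
#' @export
bandit_env <- function(states, rule, steps_per_episode = 10L) {
  sm <- if (is.matrix(states)) states else state_matrix(states)
  e <- new.env(parent = emptyenv())
  e$states <- sm
  e$rule <- rule
  e$best <- as.integer(apply(sm, 1, rule))
  e$cfg <- list(steps_per_episode = as.integer(steps_per_episode))
  e$t <- 0L
  e$episode_index <- 0L
  class(e) <- c("bandit_env", "environment")
  e
}

#' @export
env_reset.bandit_env <- function(env) {
  env$t <- 0L
  env$episode_index <- env$episode_index + 1L
  env$states
}

#' @export
env_step.bandit_env <- function(env, actions) {
  if (length(actions) != nrow(env$states)) {
    stop("need one action per state row", call. = FALSE)
  }
  r <- ifelse(as.integer(actions) == env$best, 1, -1)
  env$t <- env$t + 1L
  list(state = env$states, reward = r,
       done = env$t >= env$cfg$steps_per_episode,
       info = tibble::tibble(episode = env$episode_index, step = env$t,
                             reward = mean(r)))
}
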