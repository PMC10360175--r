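#' Q-network specification
#'
#' A fully connected network mapping the 12 state features to one Q-value
#' per augmentation action (8 outputs), with rectified-linear hidden layers.
#'
#' @param hidden Integer vector of hidden-layer widths.
#' @param seed Seed for the (He-scaled) weight initialization.
#' @return A list of class `qnetwork_spec` with `input_dim = 12` and
#'   `output_dim = 8`.
#' @export
qnetwork_spec <- function(hidden = c(64L, 64L), seed = 1L) {
  structure(list(input_dim = 12L, output_dim = 8L,
                 hidden = as.integer(hidden), seed = as.integer(seed)),
            class = "qnetwork_spec")
}

#' Initialize a Q-network from a specification
#'
#' @param spec A [qnetwork_spec()].
#' @return A list of class `qnetwork` holding weight matrices and biases.
#' @export
init_qnetwork <- function(spec) {
  dims <- c(spec$input_dim, spec$hidden, spec$output_dim)
  with_seed(spec$seed, {
    W <- list(); b <- list()
    for (k in seq_len(length(dims) - 1L)) {
      W[[k]] <- matrix(stats::rnorm(dims[k] * dims[k + 1], 0,
                                    sqrt(2 / dims[k])),
                       dims[k], dims[k + 1])
      b[[k]] <- rep(0, dims[k + 1])
    }
    structure(list(W = W, b = b, spec = spec), class = "qnetwork")
  })
}

qnet_forward <- function(net, X) {
  L <- length(net$W)
  A <- list(X)
  Z <- list()
  for (k in seq_len(L)) {
    Z[[k]] <- sweep(A[[k]] %*% net$W[[k]], 2, net$b[[k]], `+`)
    A[[k + 1]] <- if (k < L) pmax(Z[[k]], 0) else Z[[k]]
  }
  list(Q = A[[L + 1]], A = A, Z = Z)
}

#' Q-values of a batch of states
#'
#' @param net A `qnetwork`.
#' @param states State tibble or `n x 12` matrix.
#' @return An `n x 8` matrix, one column per action id 0..7.
#' @export
q_values <- function(net, states) {
  X <- if (is.matrix(states)) states else state_matrix(states)
  qnet_forward(net, X)$Q
}

# Backpropagate an output-gradient matrix through the network.
qnet_backprop <- function(net, fwd, dQ) {
  L <- length(net$W)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- dQ
  for (k in L:1) {
    gW[[k]] <- crossprod(fwd$A[[k]], delta)
    gb[[k]] <- colSums(delta)
    if (k > 1) delta <- (delta %*% t(net$W[[k]])) * (fwd$Z[[k - 1]] > 0)
  }
  list(W = gW, b = gb)
}

#' Squared temporal-difference loss and its gradients
#'
#' `mean over the batch of [r + gamma * max_a Q2(s', a) - Q1(s, a)]^2`.
#' The target network `q2` is treated as a constant: gradients flow only to
#' `q1`. The default `gamma = 1` matches the undiscounted printed loss.
#'
#' @param q1 Decision network (gradients computed for it).
#' @param q2 Target network (no gradients).
#' @param batch A `transition_batch` (see [collect_transitions()]).
#' @param gamma Discount factor in `[0, 1]`.
#' @return List with `loss` (scalar) and `grads` (same shape as the
#'   network's parameters).
#' @export
td_loss <- function(q1, q2, batch, gamma = 1) {
  stopifnot(length(batch) >= 1, gamma >= 0, gamma <= 1)
  n <- length(batch)
  fwd <- qnet_forward(q1, batch$s)
  pred <- fwd$Q[cbind(seq_len(n), batch$a + 1L)]
  max_next <- apply(q_values(q2, batch$s_next), 1, max)
  target <- batch$r + gamma * max_next
  err <- pred - target
  dQ <- matrix(0, n, ncol(fwd$Q))
  dQ[cbind(seq_len(n), batch$a + 1L)] <- 2 * err / n
  list(loss = mean(err^2), grads = qnet_backprop(q1, fwd, dQ))
}

#' Epsilon-greedy action selection
#'
#' For each state row independently: with probability `epsilon` a uniform
#' random action, otherwise the argmax of that row's Q-values, ties broken
#' by the lowest action id.
#'
#' @param q1 A `qnetwork`.
#' @param states State tibble or matrix.
#' @param epsilon Exploration probability in `[0, 1]`.
#' @return Integer vector of action ids (0..7), one per state row.
#' @export
select_actions <- function(q1, states, epsilon = 0) {
  stopifnot(epsilon >= 0, epsilon <= 1)
  X <- if (is.matrix(states)) states else state_matrix(states)
  Q <- qnet_forward(q1, X)$Q
  greedy <- max.col(Q, ties.method = "first") - 1L
  explore <- stats::runif(nrow(X)) < epsilon
  if (any(explore)) {
    greedy[explore] <- sample.int(ncol(Q), sum(explore), replace = TRUE) - 1L
  }
  greedy
}

#' Bounded FIFO experience replay buffer
#'
#' Stores per-image transitions; once full, the oldest transitions are
#' evicted first.
#'
#' @param capacity Maximum number of stored transitions.
#' @return An object of class `replay_buffer`.
#' @export
replay_buffer <- function(capacity = 10000L) {
  stopifnot(capacity >= 1)
  e <- new.env(parent = emptyenv())
  e$capacity <- as.integer(capacity)
  e$s <- matrix(0, capacity, 12L)
  e$s_next <- matrix(0, capacity, 12L)
  e$a <- integer(capacity)
  e$r <- numeric(capacity)
  e$n <- 0L
  e$pos <- 0L   # next write slot (0-based)
  class(e) <- c("replay_buffer", "environment")
  e
}

#' @export
length.replay_buffer <- function(x) x$n

#' Push a batch of transitions into a buffer
#'
#' @param buf A [replay_buffer()].
#' @param batch A `transition_batch`.
#' @return The buffer, invisibly.
#' @export
push_transitions <- function(buf, batch) {
  stopifnot(inherits(buf, "replay_buffer"), inherits(batch, "transition_batch"))
  for (i in seq_len(length(batch))) {
    slot <- buf$pos + 1L
    buf$s[slot, ] <- batch$s[i, ]
    buf$s_next[slot, ] <- batch$s_next[i, ]
    buf$a[slot] <- batch$a[i]
    buf$r[slot] <- batch$r[i]
    buf$pos <- (buf$pos + 1L) %% buf$capacity
    buf$n <- min(buf$n + 1L, buf$capacity)
  }
  invisible(buf)
}

# Stored transitions in age order (oldest first).
buffer_contents <- function(buf) {
  idx <- if (buf$n < buf$capacity) seq_len(buf$n) else {
    (((buf$pos + seq_len(buf$capacity) - 1L) %% buf$capacity) + 1L)
  }
  collect_transitions(buf$s[idx, , drop = FALSE], buf$a[idx], buf$r[idx],
                      buf$s_next[idx, , drop = FALSE])
}

#' Sample a uniform batch from a replay buffer
#'
#' @param buf A [replay_buffer()].
#' @param size Batch size (at most the stored count).
#' @return A `transition_batch`.
#' @export
sample_transitions <- function(buf, size) {
  stopifnot(size >= 1, size <= buf$n)
  idx <- sample.int(buf$n, size)
  collect_transitions(buf$s[idx, , drop = FALSE], buf$a[idx], buf$r[idx],
                      buf$s_next[idx, , drop = FALSE])
}

#' Periodic target-network synchronization
#'
#' Copies the decision network's parameters into the target network whenever
#' `step_counter` is a multiple of `C`; otherwise returns the target
#' unchanged, so the target evolves `C` times slower.
#'
#' @param q1 Decision network.
#' @param q2 Target network.
#' @param step_counter Gradient-update counter.
#' @param C Synchronization period (in gradient updates).
#' @return The (possibly updated) target network.
#' @export
sync_target <- function(q1, q2, step_counter, C) {
  stopifnot(C >= 1)
  if (step_counter %% C == 0) {
    q2$W <- q1$W
    q2$b <- q1$b
  }
  q2
}

#' Agent configuration
#'
#' @param batch_size Transitions sampled per gradient update (`S`).
#' @param target_sync Gradient updates between target syncs (`C`).
#' @param episodes Number of episodes (`L`).
#' @param epsilon_start,epsilon_end Linear exploration schedule endpoints.
#' @param epsilon_decay_steps Steps over which epsilon decays; defaults to
#'   half the total number of environment steps.
#' @param gamma Discount in `[0, 1]` (1 matches the undiscounted loss; 0
#'   turns the update into a contextual-bandit regression).
#' @param learning_rate Adam step size.
#' @param buffer_capacity Replay capacity.
#' @param updates_per_step Gradient updates per environment step.
#' @param seed Seed for exploration, sampling and network initialization.
#' @return A list of class `agent_config`.
#' @export
agent_config <- function(batch_size = 64L, target_sync = 10L, episodes = 10L,
                         epsilon_start = 1, epsilon_end = 0.05,
                         epsilon_decay_steps = NULL, gamma = 1,
                         learning_rate = 1e-3, buffer_capacity = 10000L,
                         updates_per_step = 1L, seed = 1L) {
  stopifnot(batch_size >= 1, target_sync >= 1, episodes >= 1,
            epsilon_start >= 0, epsilon_start <= 1,
            epsilon_end >= 0, epsilon_end <= 1,
            gamma >= 0, gamma <= 1, learning_rate > 0, updates_per_step >= 1)
  structure(list(batch_size = as.integer(batch_size),
                 target_sync = as.integer(target_sync),
                 episodes = as.integer(episodes),
                 epsilon_start = epsilon_start, epsilon_end = epsilon_end,
                 epsilon_decay_steps = epsilon_decay_steps, gamma = gamma,
                 learning_rate = learning_rate,
                 buffer_capacity = as.integer(buffer_capacity),
                 updates_per_step = as.integer(updates_per_step),
                 seed = as.integer(seed)),
            class = "agent_config")
}

adam_init <- function(net) {
  list(m = list(W = lapply(net$W, function(w) w * 0),
                b = lapply(net$b, function(b) b * 0)),
       v = list(W = lapply(net$W, function(w) w * 0),
                b = lapply(net$b, function(b) b * 0)),
       t = 0L)
}

adam_update <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in seq_along(net$W)) {
    state$m$W[[k]] <- beta1 * state$m$W[[k]] + (1 - beta1) * grads$W[[k]]
    state$v$W[[k]] <- beta2 * state$v$W[[k]] + (1 - beta2) * grads$W[[k]]^2
    net$W[[k]] <- net$W[[k]] -
      lr * (state$m$W[[k]] / bc1) / (sqrt(state$v$W[[k]] / bc2) + eps)
    state$m$b[[k]] <- beta1 * state$m$b[[k]] + (1 - beta1) * grads$b[[k]]
    state$v$b[[k]] <- beta2 * state$v$b[[k]] + (1 - beta2) * grads$b[[k]]^2
    net$b[[k]] <- net$b[[k]] -
      lr * (state$m$b[[k]] / bc1) / (sqrt(state$v$b[[k]] / bc2) + eps)
  }
  list(net = net, state = state)
}

epsilon_at <- function(cfg, global_step, total_steps) {
  decay <- cfg$epsilon_decay_steps
  if (is.null(decay)) decay <- max(1, ceiling(total_steps / 2))
  frac <- min(1, max(0, (global_step - 1) / decay))
  cfg$epsilon_start + frac * (cfg$epsilon_end - cfg$epsilon_start)
}

#' Train the DQN agent on an environment
#'
#' Runs `episodes` episodes of `steps_per_episode` steps each. Every step:
#' select one epsilon-greedy action per state row, execute the step, store
#' per-image transitions in the replay buffer, and (once the buffer holds at
#' least `batch_size` transitions) run `updates_per_step` gradient updates of
#' the decision network from uniformly sampled batches, syncing the target
#' network every `target_sync` updates. Network parameters persist across
#' episodes; only the environment is reset.
#'
#' @param env An environment ([env_init()] or [bandit_env()]).
#' @param agent_cfg An [agent_config()].
#' @param qspec A [qnetwork_spec()].
#' @return An object of class `dqn_fit`: list with the trained `q1`, the
#'   target `q2`, a per-step `history` tibble (`episode`, `step`,
#'   `global_step`, `epsilon`, `loss`, `reward`, `buffer_size`), the configs
#'   and the replay buffer.
#' @export
train_dqn <- function(env, agent_cfg = agent_config(), qspec = qnetwork_spec()) {
  Tsteps <- env$cfg$steps_per_episode
  total <- agent_cfg$episodes * Tsteps
  qspec$seed <- derive_seed(agent_cfg$seed, 1L)
  q1 <- init_qnetwork(qspec)
  q2 <- q1
  opt <- adam_init(q1)
  buf <- replay_buffer(agent_cfg$buffer_capacity)
  history <- vector("list", total)
  infos <- vector("list", total)
  gstep <- 0L
  updates <- 0L
  with_seed(derive_seed(agent_cfg$seed, 2L), {
    for (ep in seq_len(agent_cfg$episodes)) {
      s <- env_reset(env)
      for (tt in seq_len(Tsteps)) {
        gstep <- gstep + 1L
        eps <- epsilon_at(agent_cfg, gstep, total)
        a <- select_actions(q1, s, epsilon = eps)
        out <- env_step(env, a)
        if (any(!is.finite(out$reward))) stop("non-finite reward", call. = FALSE)
        push_transitions(buf, collect_transitions(s, a, out$reward, out$state))
        loss <- NA_real_
        if (length(buf) >= agent_cfg$batch_size) {
          for (u in seq_len(agent_cfg$updates_per_step)) {
            batch <- sample_transitions(buf, agent_cfg$batch_size)
            tl <- td_loss(q1, q2, batch, gamma = agent_cfg$gamma)
            upd <- adam_update(q1, tl$grads, opt, agent_cfg$learning_rate)
            q1 <- upd$net; opt <- upd$state
            updates <- updates + 1L
            q2 <- sync_target(q1, q2, updates, agent_cfg$target_sync)
            loss <- tl$loss
          }
        }
        history[[gstep]] <- tibble::tibble(
          episode = ep, step = tt, global_step = gstep, epsilon = eps,
          loss = loss, reward = mean(out$reward), buffer_size = length(buf))
        infos[[gstep]] <- out$info
        s <- out$state
      }
    }
  })
  structure(list(q1 = q1, q2 = q2, history = dplyr::bind_rows(history),
                 info = dplyr::bind_rows(infos), agent_cfg = agent_cfg,
                 qspec = qspec, buffer = buf),
            class = "dqn_fit")
}

#' Mean step reward over the first and last quartile of episodes
#'
#' Quartiles are taken over whole episodes (the first and last
#' `ceiling(L/4)` of them) rather than raw steps: every episode restarts
#' from the restored pre-trained snapshot, so rewards are strongly
#' step-phase dependent (the first step of an episode doubles the training
#' set and earns most of the Dice gain), and only whole episodes give the
#' two quartiles the same phase composition.
#'
#' @param history A `dqn_fit` history tibble (columns `episode`, `reward`).
#' @return List with `first` and `last` mean rewards.
#' @export
quartile_rewards <- function(history) {
  L <- max(history$episode)
  qe <- ceiling(L / 4)
  list(first = mean(history$reward[history$episode <= qe]),
       last = mean(history$reward[history$episode > L - qe]))
}

#' @export
print.dqn_fit <- function(x, ...) {
  h <- x$history
  qr <- quartile_rewards(h)
  cat(sprintf(paste0("<dqn_fit> %d episodes x %d steps, %d transitions stored\n",
                     "  mean episode-quartile reward: first %.4f, last %.4f\n"),
              max(h$episode), max(h$step), length(x$buffer),
              qr$first, qr$last))
  invisible(x)
}

#' Greedy policy of a trained agent
#'
#' @param fit A `dqn_fit` (or a bare `qnetwork`).
#' @param states State tibble or matrix.
#' @return Integer action ids, one per state row.
#' @export
greedy_actions <- function(fit, states) {
  net <- if (inherits(fit, "dqn_fit")) fit$q1 else fit
  X <- if (is.matrix(states)) states else state_matrix(states)
  max.col(qnet_forward(net, X)$Q, ties.method = "first") - 1L
}

#' Planted best action: flip up when the rust centroid is in the top half
#'
#' The reference rule of the planted-policy experiment: action 1 (vertical
#' flip) when the rust centroid lies in the top half of the image
#' (`y_r < 0.5`, which includes spot-free images whose rust features are
#' zero), action 2 (horizontal flip) otherwise.
#'
#' @param state Numeric 12-feature state row.
#' @return Action id 1 or 2.
#' @export
rule_rust_top_half <- function(state) if (state[[8]] < 0.5) 1L else 2L

#' Planted-policy recovery experiment
#'
#' Trains the agent on a mock contextual-bandit environment whose states are
#' feature rows of generated images and whose per-image reward is +1 when
#' the chosen action matches a planted rule, -1 otherwise; then measures how
#' often the greedy policy matches the rule on freshly generated held-out
#' states. With the defaults the agent sees 5,000 transitions.
#'
#' @param seed Root seed (generates train/holdout images and the agent seed).
#' @param n_states Number of training-state images.
#' @param n_holdout Number of held-out images.
#' @param episodes,steps_per_episode Bandit episode layout.
#' @param rule Planted rule (default [rule_rust_top_half()]).
#' @param image_size Generated image side length.
#' @param agent_cfg Optional [agent_config()] override. The default uses
#'   `gamma = 0` (the bandit's next state carries no information, so the
#'   bootstrap term would only add noise) and several gradient updates per
#'   step.
#' @return List with `accuracy` (held-out match rate), `n_transitions`, and
#'   the `dqn_fit`.
#' @export
planted_policy_experiment <- function(seed = 1L, n_states = 50L,
                                      n_holdout = 40L, episodes = 10L,
                                      steps_per_episode = 10L,
                                      rule = rule_rust_top_half,
                                      image_size = 64L,
                                      agent_cfg = NULL) {
  gen <- generator_config(image_size = image_size, n_images = n_states,
                          rust_spot_count_range = c(1L, 3L),
                          seed = derive_seed(seed, 11L))
  states <- extract_state_vector(generate_dataset(gen))
  env <- bandit_env(states, rule, steps_per_episode = steps_per_episode)
  if (is.null(agent_cfg)) {
    agent_cfg <- agent_config(episodes = episodes, gamma = 0,
                              learning_rate = 3e-3, updates_per_step = 5L,
                              seed = derive_seed(seed, 12L))
  }
  fit <- train_dqn(env, agent_cfg, qnetwork_spec())
  hold_gen <- generator_config(image_size = image_size, n_images = n_holdout,
                               rust_spot_count_range = c(1L, 3L),
                               seed = derive_seed(seed, 13L))
  hold <- extract_state_vector(generate_dataset(hold_gen))
  hs <- state_matrix(hold)
  acc <- mean(greedy_actions(fit, hs) == apply(hs, 1, rule))
  list(accuracy = acc,
       n_transitions = n_states * episodes * steps_per_episode,
       fit = fit)
}
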