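# MOSS-DDPG: single-step deterministic policy gradient over the 2N+1
# observation matrix. One prediction per episode, immediate reward, no
# target networks (there is no future return to bootstrap).

#' Training schedule for MOSS-DDPG
#'
#' @param episodes Number of training episodes (default 40,000).
#' @param warmup_episodes Episodes with frozen networks at the start,
#'   exploring through action noise only (default 10% of `episodes`).
#' @param noise_profiles Exploration-noise profiles evaluated per episode
#'   (`k`, default 15); each stored as its own transition.
#' @param exploration_sd0 Initial SD of the zero-mean Gaussian exploration
#'   noise, um; annealed linearly to exactly 0 at the final episode.
#' @param batch_size Replay minibatch size.
#' @param replay_capacity Maximum stored transitions.
#' @param lr_actor,lr_critic Adam learning rates.
#' @param updates_per_episode Critic gradient updates per post-warm-up
#'   episode.
#' @param actor_updates_per_episode Actor policy-gradient updates per
#'   post-warm-up episode (defaults to `updates_per_episode`; the critic
#'   regression typically needs more steps than the policy).
#' @param hidden LSTM hidden width (shared by actor and critic encoders).
#' @param critic_hidden Width of the critic's post-concatenation layer.
#' @param action_limit Saturation bound of the actor's tanh output head, um.
#' @return Object of class `training_schedule`.
#' @examples
#' s <- training_schedule()
#' s$warmup_episodes * s$noise_profiles  # transitions banked during warm-up
#' @export
training_schedule <- function(episodes = 40000,
                              warmup_episodes = round(0.1 * episodes),
                              noise_profiles = 15,
                              exploration_sd0 = 0.05,
                              batch_size = 256, replay_capacity = 1e6,
                              lr_actor = 1e-4, lr_critic = 1e-3,
                              updates_per_episode = 1,
                              actor_updates_per_episode = updates_per_episode,
                              hidden = 128, critic_hidden = 64,
                              action_limit = 0.2) {
  stopifnot(episodes >= 1, warmup_episodes >= 0, warmup_episodes < episodes,
            noise_profiles >= 1, exploration_sd0 >= 0, action_limit > 0)
  structure(list(episodes = as.integer(episodes),
                 warmup_episodes = as.integer(warmup_episodes),
                 noise_profiles = as.integer(noise_profiles),
                 exploration_sd0 = exploration_sd0,
                 batch_size = as.integer(batch_size),
                 replay_capacity = replay_capacity,
                 lr_actor = lr_actor, lr_critic = lr_critic,
                 updates_per_episode = as.integer(updates_per_episode),
                 actor_updates_per_episode =
                   as.integer(actor_updates_per_episode),
                 hidden = as.integer(hidden),
                 critic_hidden = as.integer(critic_hidden),
                 action_limit = action_limit),
            class = "training_schedule")
}

#' @export
print.training_schedule <- function(x, ...) {
  cat(sprintf(paste0(
    "MOSS-DDPG training schedule: %d episodes (%d warm-up), k = %d noise\n",
    "  profiles/episode, exploration SD %.3g um -> 0, batch %d, LSTM hidden %d\n"),
    x$episodes, x$warmup_episodes, x$noise_profiles, x$exploration_sd0,
    x$batch_size, x$hidden))
  invisible(x)
}

# Exploration SD at episode ep: linear anneal from sd0 (episode 1) to
# exactly 0 at the final episode.
.exploration_sd <- function(schedule, ep) {
  if (schedule$episodes == 1) return(0)
  schedule$exploration_sd0 * (schedule$episodes - ep) / (schedule$episodes - 1)
}

.obs_dims <- function(env) c(T = 2L * env$N + 1L, d = env$N + 1L)

# Core training loop shared by moss_ddpg() and transfer_learn().
.train_loop <- function(env, schedule, actor, critic, verbose) {
  N <- env$N
  dm <- .obs_dims(env)
  TT <- dm[["T"]]; d <- dm[["d"]]
  k <- schedule$noise_profiles
  lim <- schedule$action_limit
  nstore <- min(schedule$replay_capacity, schedule$episodes * k)
  obs_buf <- array(0, c(nstore, TT, d))
  act_buf <- matrix(0, nstore, N)
  rew_buf <- numeric(nstore)
  ptr <- 0L; count <- 0L
  st_actor <- adam_init(actor)
  st_critic <- adam_init(critic)
  trace <- numeric(schedule$episodes)
  X1 <- array(0, c(1, TT, d))

  for (ep in seq_len(schedule$episodes)) {
    obs <- env_reset(env)
    X1[1, , ] <- obs
    a0 <- drop(actor_forward(actor, X1, lim)$A)
    sd_ep <- .exploration_sd(schedule, ep)
    noise <- matrix(stats::rnorm(k * N, 0, sd_ep), k, N)
    rewards <- evaluate_action_batch(env, a0, noise)
    if (any(!is.finite(rewards))) stop("non-finite reward at episode ", ep)

    idx <- (ptr + seq_len(k) - 1L) %% nstore + 1L
    obs_buf[idx, , ] <- rep(obs, each = k)
    act_buf[idx, ] <- sweep(noise, 2, a0, `+`)
    rew_buf[idx] <- rewards
    ptr <- (ptr + k) %% nstore
    count <- min(count + k, nstore)
    trace[ep] <- mean(rewards)

    if (ep > schedule$warmup_episodes && count >= schedule$batch_size) {
      B <- schedule$batch_size
      for (u in seq_len(schedule$updates_per_episode)) {
        # critic regression toward the observed immediate rewards
        b <- sample.int(count, B)
        Xb <- obs_buf[b, , , drop = FALSE]
        cf <- critic_forward(critic, Xb, act_buf[b, , drop = FALSE] / lim)
        if (any(!is.finite(cf$q))) stop("critic diverged at episode ", ep)
        dq <- 2 * (cf$q - rew_buf[b]) / B
        gc_ <- critic_backward(critic, cf, dq)
        upd <- adam_step(critic, gc_, st_critic, schedule$lr_critic)
        critic <- upd$params; st_critic <- upd$state
      }
      for (u in seq_len(schedule$actor_updates_per_episode)) {
        # deterministic policy gradient through the (fixed) critic;
        # only the head gradient w.r.t. the action is needed
        b <- sample.int(count, B)
        Xb <- obs_buf[b, , , drop = FALSE]
        af <- actor_forward(actor, Xb, lim)
        cf2 <- critic_forward(critic, Xb, af$A / lim)
        dA <- critic_dA(critic, cf2, rep(-1 / B, B)) / lim
        ga <- actor_backward(actor, af, dA, lim)
        upd <- adam_step(actor, ga, st_actor, schedule$lr_actor)
        actor <- upd$params; st_actor <- upd$state
      }
    }
    if (verbose && ep %% max(1, schedule$episodes %/% 20) == 0)
      cat(sprintf("episode %d/%d  mean reward %.3f  expl sd %.4f\n",
                  ep, schedule$episodes, mean(trace[max(1, ep - 99):ep]), sd_ep))
  }
  list(actor = actor, critic = critic, trace = trace,
       n_transitions = schedule$episodes * k, replay_occupancy = count)
}

#' Train a MOSS-DDPG sensorless-AO agent
#'
#' Fits the LSTM actor-critic by single-step deterministic policy gradient.
#' Each episode: reset the environment (fresh hidden aberration, `2N+1`
#' observations), predict a correction, add `k` Gaussian exploration-noise
#' profiles, score each against the same hidden aberration, and bank the
#' `k` transitions.  After the warm-up phase every episode performs
#' minibatch updates: the critic regresses toward the observed immediate
#' rewards and the actor follows the policy gradient through the critic.
#' There are no target networks: with single-step episodes there is no
#' future return to stabilize.
#'
#' @param env A [sao_env()].
#' @param schedule A [training_schedule()].
#' @param seed Optional integer seed covering the whole run (aberration
#'   draws, exploration noise, replay sampling, weight init).
#' @param verbose Print progress.
#' @return Object of class `moss_ddpg`: the trained policy with its reward
#'   trace.  Methods: [predict.moss_ddpg()], `print`, `summary`, `plot`.
#' @seealso [transfer_learn()], [run_benchmark()]
#' @export
moss_ddpg <- function(env, schedule = training_schedule(), seed = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(env, "sao_env"), inherits(schedule, "training_schedule"))
  if (!is.null(seed)) set.seed(seed)
  dm <- .obs_dims(env)
  actor <- actor_init(dm[["d"]], schedule$hidden, env$N)
  critic <- critic_init(dm[["d"]], schedule$hidden, env$N,
                        schedule$critic_hidden)
  fit <- .train_loop(env, schedule, actor, critic, verbose)
  structure(list(actor = fit$actor, critic = fit$critic,
                 schedule = schedule, N = env$N,
                 mode_order = env$target_indices, bias = env$bias,
                 action_limit = schedule$action_limit,
                 reward_trace = fit$trace, seed = seed,
                 n_transitions = fit$n_transitions,
                 replay_occupancy = fit$replay_occupancy,
                 transfer_trace = NULL),
            class = "moss_ddpg")
}

#' Predict correction coefficients from an observation matrix
#'
#' @param object A trained [moss_ddpg()] agent.
#' @param observation The `(2N+1) x (N+1)` observation matrix from
#'   [env_reset()].
#' @param ... Unused.
#' @return Named numeric vector of N correction coefficients, um, bounded
#'   by the agent's `action_limit`.
#' @export
predict.moss_ddpg <- function(object, observation, ...) {
  dm <- dim(observation)
  if (is.null(dm) || dm[1] != 2 * object$N + 1 || dm[2] != object$N + 1)
    stop("observation must be a (2N+1) x (N+1) matrix with N = ", object$N)
  X <- array(0, c(1, dm[1], dm[2]))
  X[1, , ] <- observation
  a <- drop(actor_forward(object$actor, X, object$action_limit)$A)
  names(a) <- as.character(object$mode_order)
  a
}

#' Critic value of an observation/action pair
#'
#' @param object A [moss_ddpg()] agent.
#' @param observation Observation matrix from [env_reset()].
#' @param action Numeric vector of N coefficients, um.
#' @return Scalar predicted reward.
#' @export
critic_value <- function(object, observation, action) {
  stopifnot(inherits(object, "moss_ddpg"))
  X <- array(0, c(1, nrow(observation), ncol(observation)))
  X[1, , ] <- observation
  A <- matrix(action / object$action_limit, 1)
  critic_forward(object$critic, X, A)$q
}

#' @export
print.moss_ddpg <- function(x, ...) {
  cat(sprintf(paste0(
    "MOSS-DDPG agent: N = %d modes (Noll %s), observation bias %.2g um\n",
    "  trained %d episodes; mean reward (last 200 episodes): %.3f\n"),
    x$N, paste(range(x$mode_order), collapse = ".."), x$bias,
    length(x$reward_trace),
    mean(utils::tail(x$reward_trace, 200))))
  invisible(x)
}

#' @export
summary.moss_ddpg <- function(object, ...) {
  tr <- object$reward_trace
  s <- object$schedule
  wu <- seq_len(s$warmup_episodes)
  out <- list(
    N = object$N, episodes = length(tr),
    warmup_mean_reward = if (length(wu)) mean(tr[wu]) else NA_real_,
    final200_mean_reward = mean(utils::tail(tr, 200)),
    schedule = s)
  class(out) <- "summary.moss_ddpg"
  out
}

#' @export
print.summary.moss_ddpg <- function(x, ...) {
  cat(sprintf(paste0(
    "MOSS-DDPG training summary (N = %d)\n",
    "  episodes            : %d\n",
    "  warm-up mean reward : %.3f\n",
    "  final-200 mean reward: %.3f\n"),
    x$N, x$episodes, x$warmup_mean_reward, x$final200_mean_reward))
  invisible(x)
}

#' Plot the per-episode mean reward trace
#'
#' @param x A [moss_ddpg()] agent.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.moss_ddpg <- function(x, ...) {
  graphics::plot(seq_along(x$reward_trace), x$reward_trace,
                 pch = 16, cex = 0.3, col = "darkgreen",
                 xlab = "episode", ylab = "mean episode reward", ...)
  graphics::abline(v = x$schedule$warmup_episodes, lty = 2)
  invisible(x)
}

#' Fine-tune a trained agent on a different (target) environment
#'
#' Brief transfer learning: continues training the actor and critic on a
#' target environment that may differ from the source (e.g. perturbed
#' fiber diameter, a fixed static instrument aberration, metric noise),
#' using the same single-step update rule with a fresh, smaller
#' exploration schedule and a fresh replay buffer.
#'
#' @param object A trained [moss_ddpg()] agent.
#' @param target_env A [sao_env()] with the same number of target modes.
#' @param episodes Fine-tuning episodes (default 1,000).
#' @param noise_profiles Noise profiles per episode (default 7).
#' @param exploration_sd0 Initial exploration SD, um (default 0.02).
#' @param warmup_episodes Frozen-network episodes (default 10%).
#' @param seed Optional integer seed.
#' @param verbose Print progress.
#' @return A new `moss_ddpg` object with updated weights and a
#'   `transfer_trace` reward trace.
#' @export
transfer_learn <- function(object, target_env, episodes = 1000,
                           noise_profiles = 7, exploration_sd0 = 0.02,
                           warmup_episodes = round(0.1 * episodes),
                           seed = NULL, verbose = FALSE) {
  stopifnot(inherits(object, "moss_ddpg"), inherits(target_env, "sao_env"))
  if (target_env$N != object$N)
    stop("mode count mismatch: agent has N = ", object$N,
         ", environment N = ", target_env$N)
  if (!is.null(seed)) set.seed(seed)
  s <- object$schedule
  schedule <- training_schedule(
    episodes = episodes, warmup_episodes = warmup_episodes,
    noise_profiles = noise_profiles, exploration_sd0 = exploration_sd0,
    batch_size = min(s$batch_size, max(64L, episodes)),
    replay_capacity = episodes * noise_profiles,
    lr_actor = s$lr_actor, lr_critic = s$lr_critic,
    updates_per_episode = s$updates_per_episode,
    actor_updates_per_episode = s$actor_updates_per_episode,
    hidden = s$hidden, critic_hidden = s$critic_hidden,
    action_limit = s$action_limit)
  fit <- .train_loop(target_env, schedule, object$actor, object$critic,
                     verbose)
  out <- object
  out$actor <- fit$actor
  out$critic <- fit$critic
  out$transfer_trace <- fit$trace
  out
}

# ---- checkpoints --------------------------------------------------------

#' Save an agent checkpoint as JSON
#'
#' Writes a single JSON file holding every named weight array (flattened,
#' with dimensions) plus the schedule/configuration sidecar, loadable
#' without the training code.
#'
#' @param object A [moss_ddpg()] agent.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(object, path) {
  stopifnot(inherits(object, "moss_ddpg"))
  pack <- function(p) lapply(p, function(w)
    list(dim = if (is.matrix(w)) dim(w) else length(w), data = as.numeric(w)))
  payload <- list(
    format = "mossddpg-checkpoint-1",
    config = list(N = object$N, mode_order = object$mode_order,
                  bias = object$bias, action_limit = object$action_limit,
                  schedule = unclass(object$schedule), seed = object$seed),
    actor = pack(object$actor), critic = pack(object$critic),
    reward_trace = object$reward_trace,
    transfer_trace = object$transfer_trace)
  writeLines(jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                              null = "null"), path)
  invisible(path)
}

#' Load an agent checkpoint saved by [save_checkpoint()]
#'
#' @param path Checkpoint file path.
#' @return A `moss_ddpg` object.
#' @export
load_checkpoint <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(payload$format, "mossddpg-checkpoint-1"))
    stop("not a mossddpg checkpoint: ", path)
  unpack <- function(p) lapply(p, function(w) {
    if (length(w$dim) == 2) matrix(w$data, w$dim[1], w$dim[2]) else w$data
  })
  cfg <- payload$config
  sched <- do.call(training_schedule, cfg$schedule)
  structure(list(actor = unpack(payload$actor),
                 critic = unpack(payload$critic),
                 schedule = sched, N = cfg$N,
                 mode_order = as.integer(cfg$mode_order), bias = cfg$bias,
                 action_limit = cfg$action_limit,
                 reward_trace = as.numeric(payload$reward_trace),
                 seed = cfg$seed,
                 transfer_trace = payload$transfer_trace),
            class = "moss_ddpg")
}
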