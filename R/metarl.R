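#' Meta reinforcement-learning two-stage environment
#'
#' Each trial has three within-trial periods (discrete time steps):
#' Delay 1 (choice state S0, fixation cue, previous trial's unit reward in
#' the observation), Go (choice state, go cue; the agent picks A1 or A2 and
#' transitions to a second-stage state with the common probability 0.8), and
#' Delay 2 (second-stage state, fixation cue; the unit reward is drawn with
#' the state's current probability, 0.8 or 0.2, switching with per-trial
#' probability 0.025). Any non-Fixate action during a delay, or Fixate at
#' Go, yields the violation penalty -0.1; a violated Go draws the
#' second-stage state uniformly. Observations are 8-vectors: state one-hot
#' (S0/S1/S2), fixation(1)/go(0) cue, previous-step reward, previous-step
#' action one-hot (A1/A2/Fixate).
#'
#' `metarl_env_reset` creates the environment; `metarl_env_obs` returns the
#' current observation; `metarl_env_step` consumes an action code
#' (0 = A1, 1 = A2, 2 = Fixate) and advances one period. Randomness is drawn
#' from the caller's RNG stream.
#'
#' @param config a `metarl` [task_config()].
#' @return `metarl_env_reset`: an environment state list.
#' @export
metarl_env_reset <- function(config = task_config("metarl")) {
  list(config = config, period = "delay1", probs = config$reward_probs,
       state2 = NA_integer_, prev_reward = 0, prev_action = 3L,
       trial_reward = 0, trial = 1L)
}

#' @param env the environment state.
#' @rdname metarl_env_reset
#' @export
metarl_env_obs <- function(env) {
  st <- switch(env$period, delay1 = 0L, go = 0L, delay2 = env$state2 + 1L)
  onehot_s <- numeric(3); onehot_s[st + 1L] <- 1
  fix <- if (env$period == "go") 0 else 1
  onehot_a <- numeric(3)
  if (env$prev_action <= 2L) onehot_a[env$prev_action + 1L] <- 1
  c(onehot_s, fix, env$prev_reward, onehot_a)
}

#' @param action integer action code (0 = A1, 1 = A2, 2 = Fixate).
#' @rdname metarl_env_reset
#' @export
metarl_env_step <- function(env, action) {
  if (!action %in% 0:2)
    stop("metarl_env_step: action must be 0 (A1), 1 (A2) or 2 (Fixate)")
  cfg <- env$config
  pen <- cfg$violation_penalty
  reward <- 0
  trial_done <- FALSE
  if (env$period == "delay1") {
    if (action != 2L) reward <- pen
    env$period <- "go"
  } else if (env$period == "go") {
    if (action == 2L) {
      reward <- pen
      env$state2 <- sample.int(2L, 1L) - 1L
    } else {
      env$state2 <- sample.int(2L, 1L,
                               prob = cfg$transitions[action + 1L, ]) - 1L
    }
    env$period <- "delay2"
  } else {                                   # delay2
    if (action != 2L) reward <- pen
    unit <- rbinom(1, 1, env$probs[env$state2 + 1L])
    reward <- reward + unit
    env$trial_reward <- unit
    if (runif(1) < cfg$block$p_switch) env$probs <- rev(env$probs)
    env$period <- "delay1"
    env$trial <- env$trial + 1L
    trial_done <- TRUE
  }
  env$prev_action <- action
  env$prev_reward <- reward
  list(obs = metarl_env_obs(env), reward = reward, env = env,
       trial_done = trial_done)
}

#' Meta-RL agent specification
#'
#' @param d recurrent core size (default 48).
#' @param lr Adam learning rate.
#' @param discount per-step discount factor.
#' @param w_policy,w_value,w_entropy loss weights for the policy-gradient,
#'   value and entropy terms.
#' @param episode_trials trials per training episode.
#' @return an `a2c_spec` list.
#' @export
a2c_spec <- function(d = 48L, lr = 3e-3, discount = 0.9, w_policy = 1,
                     w_value = 0.5, w_entropy = 0.01, episode_trials = 100L) {
  stopifnot(w_policy >= 0, w_value >= 0, w_entropy >= 0,
            discount >= 0, discount <= 1)
  structure(list(d = as.integer(d), lr = lr, discount = discount,
                 w_policy = w_policy, w_value = w_value,
                 w_entropy = w_entropy,
                 episode_trials = as.integer(episode_trials)),
            class = "a2c_spec")
}

## parameter container for the agent: GRU core + actor/critic heads
a2c_init <- function(spec, seed) {
  d <- spec$d; k <- 8L
  sc <- 1 / sqrt(d)
  with_local_seed(seed, {
    U <- function(...) array(runif(prod(c(...)), -sc, sc), dim = c(...))
    list(Wir = U(d, k), Wiz = U(d, k), Win = U(d, k),
         Whr = U(d, d), Whz = U(d, d), Whn = U(d, d),
         bir = U(d, 1)[, 1], biz = U(d, 1)[, 1], bin = U(d, 1)[, 1],
         bhr = U(d, 1)[, 1], bhz = U(d, 1)[, 1], bhn = U(d, 1)[, 1],
         Wa = U(3, d), ba = U(3, 1)[, 1], Wv = U(1, d), bv = 0)
  })
}

gru_names <- c("Wir", "Wiz", "Win", "Whr", "Whz", "Whn",
               "bir", "biz", "bin", "bhr", "bhz", "bhn")

## run one episode; returns the step records needed for the A2C update
a2c_episode <- function(w, spec, env, sample_actions = TRUE) {
  steps <- 3L * spec$episode_trials
  X <- matrix(0, steps, 8L)
  acts <- integer(steps)
  rewards <- numeric(steps)
  pol <- matrix(0, steps, 3L)
  h <- numeric(spec$d)
  unit_rewards <- numeric(0)
  for (s in seq_len(steps)) {
    x <- metarl_env_obs(env)
    X[s, ] <- x
    h <- gru_step(h, x, w)
    p <- softmax_policy(as.numeric(w$Wa %*% h + w$ba), 1)
    a <- if (sample_actions) sample.int(3L, 1L, prob = p) - 1L
         else which.max(p) - 1L
    res <- metarl_env_step(env, a)
    if (res$trial_done)
      unit_rewards <- c(unit_rewards, res$env$trial_reward)
    env <- res$env
    acts[s] <- a; rewards[s] <- res$reward; pol[s, ] <- p
  }
  list(X = X, actions = acts, rewards = rewards, policies = pol, env = env,
       unit_rewards = unit_rewards)
}

#' Train a meta-RL agent with advantage actor-critic
#'
#' A GRU-core agent (actor head over A1/A2/Fixate, scalar critic head) is
#' trained with the policy-gradient, value-error and entropy-regularization
#' losses on episodes of the two-stage environment. Returns the weights and
#' the learning curve of unit rewards per trial.
#'
#' @param spec an [a2c_spec()].
#' @param config a `metarl` [task_config()].
#' @param n_trials total training budget in trials.
#' @param seed integer seed (training is reproducible given the seed).
#' @return list with `weights`, `spec`, `curve` (mean unit reward per trial,
#'   one entry per episode).
#' @export
train_a2c <- function(spec = a2c_spec(), config = task_config("metarl"),
                      n_trials = 200000L, seed = 1L) {
  with_local_seed(seed, {
    w <- a2c_init(spec, seed = sample.int(1e6, 1L))
    flat <- flatten_weights(w)
    theta <- flat$theta
    opt <- adam_new(length(theta))
    n_episodes <- max(1L, floor(n_trials / spec$episode_trials))
    curve <- numeric(n_episodes)
    env <- metarl_env_reset(config)
    for (ep in seq_len(n_episodes)) {
      w <- restore_weights(theta, flat)
      epi <- a2c_episode(w, spec, env)
      env <- epi$env
      curve[ep] <- mean(epi$unit_rewards)
      g <- a2c_gradient(w, spec, epi)
      if (!all(is.finite(g)))
        stop("train_a2c: non-finite gradient at episode ", ep)
      gn <- sqrt(sum(g^2))
      if (gn > 5) g <- g * (5 / gn)
      opt <- adam_step(opt, g, spec$lr)
      theta <- theta + opt$delta
    }
    list(weights = restore_weights(theta, flat), spec = spec, curve = curve)
  })
}

## gradient of the A2C losses for one recorded episode
a2c_gradient <- function(w, spec, epi) {
  steps <- nrow(epi$X)
  ## the agent acts from the state *after* each input; appending a dummy row
  ## makes those post-input states appear as rows 2..steps+1 of H
  Xp <- rbind(epi$X, 0)
  fwd2 <- cpp_gru_forward(w[gru_names], Xp, starts = 1L)
  H <- fwd2$H[2:(steps + 1L), , drop = FALSE]
  V <- as.numeric(H %*% t(w$Wv) + w$bv)
  ## discounted returns to the end of the episode
  R <- numeric(steps)
  acc <- 0
  for (s in steps:1) { acc <- epi$rewards[s] + spec$discount * acc; R[s] <- acc }
  adv <- R - V
  P <- epi$policies
  onehot <- matrix(0, steps, 3L)
  onehot[cbind(seq_len(steps), epi$actions + 1L)] <- 1
  ent <- -rowSums(P * log(pmax(P, 1e-12)))
  dscore_pi <- spec$w_policy * (-adv) * (onehot - P) / steps
  dscore_ent <- spec$w_entropy * P * (log(pmax(P, 1e-12)) + ent) / steps
  dscore <- dscore_pi + dscore_ent
  dV <- spec$w_value * (V - R) / steps
  dH <- dscore %*% w$Wa + dV %*% w$Wv
  gr <- cpp_gru_backward(w[gru_names], Xp, fwd2,
                         rbind(numeric(spec$d), dH), starts = 1L)
  gr$dX <- NULL
  gr$Wa <- t(dscore) %*% H
  gr$ba <- colSums(dscore)
  gr$Wv <- matrix(dV %*% H, 1)
  gr$bv <- sum(dV)
  flatten_weights(gr[names(w)])$theta
}

#' Evaluate a trained meta-RL agent
#'
#' Runs the agent for `n_trials` (sampled or greedy at every step) and
#' returns the mean unit reward per trial, the per-trial penalty count, the
#' trial table as a [session_data()] consumable by the interpretation
#' module, and the per-trial Go logits `log Pr(A1)/Pr(A2)`.
#'
#' @param agent output of [train_a2c()].
#' @param config a `metarl` [task_config()].
#' @param n_trials evaluation trials.
#' @param seed integer seed.
#' @param greedy take the argmax action at every step instead of sampling.
#' @return list with `reward_rate`, `penalties`, `data`, `logits`.
#' @export
evaluate_agent <- function(agent, config = task_config("metarl"),
                           n_trials = 10000L, seed = 1L, greedy = FALSE) {
  with_local_seed(seed, {
    w <- agent$weights
    env <- metarl_env_reset(config)
    h <- numeric(agent$spec$d)
    action <- state <- integer(n_trials); reward <- numeric(n_trials)
    logits <- numeric(n_trials)
    penalties <- 0L
    tr <- 1L
    go_action <- NA_integer_
    while (tr <= n_trials) {
      x <- metarl_env_obs(env)
      h <- gru_step(h, x, w)
      p <- softmax_policy(as.numeric(w$Wa %*% h + w$ba), 1)
      a <- if (greedy) which.max(p) - 1L
           else sample.int(3L, 1L, prob = p) - 1L
      if (env$period == "go") {
        sc <- as.numeric(w$Wa %*% h + w$ba)
        logits[tr] <- sc[1] - sc[2]
        go_action <- a
      }
      res <- metarl_env_step(env, a)
      if (res$reward < 0) penalties <- penalties + 1L
      if (res$trial_done) {
        action[tr] <- if (go_action %in% 0:1) go_action else 0L
        state[tr] <- res$env$state2
        reward[tr] <- res$env$trial_reward
        tr <- tr + 1L
      }
      env <- res$env
    }
    data <- session_data(
      data.frame(subject = "agent", session = "1", trial = seq_len(n_trials),
                 action = action, state = state, reward = reward,
                 mask = TRUE, stringsAsFactors = FALSE),
      task_config("two_stage"))
    list(reward_rate = mean(reward), penalties = penalties, data = data,
         logits = logits)
  })
}

#' Reward rate of fixed reference policies on the meta-RL task
#'
#' Simulates the oracle policy (always the action whose common transition
#' leads to the currently rich state) or the uniform policy at the trial
#' level, confirming the closed forms of [analytic_baselines()].
#'
#' @param config a `metarl` [task_config()].
#' @param policy `"oracle"` or `"uniform"`.
#' @param n_trials simulation length.
#' @param seed integer seed.
#' @return mean unit reward per trial.
#' @export
reference_reward_rate <- function(config = task_config("metarl"),
                                  policy = c("oracle", "uniform"),
                                  n_trials = 100000L, seed = 1L) {
  policy <- match.arg(policy)
  with_local_seed(seed, {
    probs <- config$reward_probs
    trans <- config$transitions
    total <- 0
    for (t in seq_len(n_trials)) {
      a <- if (policy == "oracle")
        which.max(as.numeric(trans %*% probs)) - 1L
      else sample.int(2L, 1L) - 1L
      s <- sample.int(2L, 1L, prob = trans[a + 1L, ]) - 1L
      total <- total + rbinom(1, 1, probs[s + 1L])
      if (runif(1) < config$block$p_switch) probs <- rev(probs)
    }
    total / n_trials
  })
}
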