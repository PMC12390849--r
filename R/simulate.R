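#' Agents for task simulation
#'
#' An agent is a list with elements `init(cfg)` (returns the initial carry
#' state), `policy(carry, cfg)` (returns a probability vector over the
#' task's actions) and `update(carry, obs, cfg)` (consumes the trial outcome
#' `obs = list(action, state, reward, action2)` and returns the new carry).
#' Agents for the original two-stage task additionally provide
#' `policy2(carry, state, cfg)` for the second-stage choice.
#'
#' @return an `agent` object.
#' @export
random_agent <- function() {
  structure(list(
    init = function(cfg) NULL,
    policy = function(carry, cfg) rep(1 / cfg$n_actions, cfg$n_actions),
    policy2 = function(carry, state, cfg) rep(0.5, 2),
    update = function(carry, obs, cfg) carry
  ), class = "agent")
}

#' @param actions fixed action code (0-based) the agent always takes; for
#'   `fixed_agent`.
#' @rdname random_agent
#' @export
fixed_agent <- function(actions = 0L) {
  structure(list(
    init = function(cfg) NULL,
    policy = function(carry, cfg) {
      p <- rep(0, cfg$n_actions); p[actions + 1L] <- 1; p
    },
    policy2 = function(carry, state, cfg) c(1, 0),
    update = function(carry, obs, cfg) carry
  ), class = "agent")
}

#' @param model a cognitive model (see [cognitive_model()]).
#' @param params named numeric parameter vector on the natural scale.
#' @rdname random_agent
#' @export
cognitive_agent <- function(model, params) {
  structure(list(
    init = function(cfg) model$init(params),
    policy = function(carry, cfg) model$policy(carry, params),
    policy2 = function(carry, state, cfg) {
      if (is.null(model$policy2)) rep(0.5, 2)
      else model$policy2(carry, params, state)
    },
    update = function(carry, obs, cfg) model$step(carry, obs, params)
  ), class = "agent")
}

## ---------------------------------------------------------------------------

## Per-task environment state and block bookkeeping.
env_init <- function(cfg, seed) {
  e <- list(probs = cfg$reward_probs, trans = cfg$transitions,
            type = 1L, t_block = 0L, ema = 0.5, switch_at = NA_integer_,
            trans_type = 1L, rev_at = NA_integer_, window = integer(0))
  if (cfg$task == "bandit4") e$means <- NULL       # filled by caller
  if (cfg$task == "two_stage_original")
    e$probs2 <- runif(4, cfg$reward_bounds2[1], cfg$reward_bounds2[2])
  if (cfg$block$rule == "fixed")
    e$rev_at <- sample(seq(cfg$block$reversal_window[1],
                           cfg$block$reversal_window[2]), 1L)
  e
}

## action currently "correct": leads (commonly) to the highest-reward state
env_correct_action <- function(e, cfg) {
  best_state <- which.max(e$probs)
  which.max(e$trans[, best_state]) - 1L
}

## Advance block machinery after a completed trial; returns env state and
## whether a contingency change happened on this trial.
env_block_step <- function(e, cfg, action, reward, t) {
  rule <- cfg$block$rule
  e$t_block <- e$t_block + 1L
  switched <- FALSE
  flip_rewards <- function(e) {
    e$probs <- rev(e$probs)
    e$type <- if (e$probs[1] >= e$probs[2]) 1L else 2L
    e
  }
  if (rule == "fixed") {
    if (e$t_block == e$rev_at) { e <- flip_rewards(e); switched <- TRUE }
    if (e$t_block >= cfg$block$block_len) {
      e$t_block <- 0L
      e$rev_at <- sample(seq(cfg$block$reversal_window[1],
                             cfg$block$reversal_window[2]), 1L)
    }
  } else if (rule == "prob") {
    if (e$t_block >= cfg$block$min_len &&
        runif(1) < cfg$block$p_switch) {
      e <- flip_rewards(e); e$t_block <- 0L; switched <- TRUE
    }
  } else if (rule == "ema") {
    neutral <- e$type == 0L
    if (!neutral) {
      correct <- as.integer(action == env_correct_action(e, cfg))
      e$ema <- e$ema + (correct - e$ema) / cfg$block$tau
      if (is.na(e$switch_at) && e$ema > cfg$block$threshold)
        e$switch_at <- e$t_block + cfg$block$delay
      if (!is.na(e$switch_at) && e$t_block >= e$switch_at) {
        e <- env_ema_transition(e, cfg)
        switched <- TRUE
      }
    } else {
      if (e$t_block > cfg$block$neutral_min &&
          runif(1) < cfg$block$neutral_hazard) {
        e <- env_ema_transition(e, cfg)
        switched <- TRUE
      }
    }
  } else if (rule == "win9of10") {
    best <- which.max(e$probs) - 1L
    if (action == best) {
      e$window <- c(e$window, as.integer(reward > 0))
      if (length(e$window) > cfg$block$window)
        e$window <- tail(e$window, cfg$block$window)
      if (length(e$window) == cfg$block$window &&
          sum(e$window) >= cfg$block$hits) {
        ## move the best probability to a different arm
        others <- setdiff(seq_along(e$probs), best + 1L)
        new_best <- sample(others, 1L)
        p <- sort(e$probs, decreasing = TRUE)
        rest <- sample(setdiff(seq_along(e$probs), new_best))
        probs <- numeric(length(e$probs))
        probs[new_best] <- p[1]
        probs[rest] <- p[-1]
        e$probs <- probs
        e$window <- integer(0)
        switched <- TRUE
      }
    }
    if (t == floor(cfg$n_trials / 2) && !is.null(cfg$reward_probs2)) {
      ## halfway contingency change: same ranking, new probability levels
      rk <- rank(-e$probs)
      e$probs <- sort(cfg$reward_probs2, decreasing = TRUE)[rk]
    }
  } else if (rule == "none" && cfg$task == "two_stage_original") {
    step <- rnorm(4, 0, cfg$drift_sd2)
    e$probs2 <- reflect_bounds(e$probs2 + step, cfg$reward_bounds2)
  }
  list(env = e, switched = switched)
}

## draw a new block after a threshold / hazard trigger (ema rule)
env_ema_transition <- function(e, cfg) {
  e$t_block <- 0L; e$ema <- 0.5; e$switch_at <- NA_integer_
  tr_rev <- isTRUE(cfg$block$transition_reversal)
  if (e$type != 0L) {
    if (tr_rev) {
      opt <- sample(4L, 1L)  # reward flip / transition flip / 2 neutrals
      if (opt == 1L) e$probs <- rev(e$probs)
      else if (opt == 2L) { e$trans <- e$trans[, 2:1]; e$trans_type <- 3L - e$trans_type }
      else {
        if (opt == 4L) { e$trans <- e$trans[, 2:1]; e$trans_type <- 3L - e$trans_type }
        e$probs <- cfg$neutral_probs; e$type <- 0L
      }
    } else if (isTRUE(cfg$block$neutral)) {
      if (runif(1) < 0.5) e$probs <- rev(e$probs)
      else { e$probs <- cfg$neutral_probs; e$type <- 0L }
    } else e$probs <- rev(e$probs)
    if (e$type != 0L) e$type <- if (e$probs[1] >= e$probs[2]) 1L else 2L
  } else {
    e$probs <- if (runif(1) < 0.5) cfg$reward_probs else rev(cfg$reward_probs)
    e$type <- if (e$probs[1] >= e$probs[2]) 1L else 2L
  }
  e
}

reflect_bounds <- function(x, bounds) {
  lo <- bounds[1]; hi <- bounds[2]
  for (i in seq_along(x)) {
    while (x[i] < lo || x[i] > hi) {
      if (x[i] < lo) x[i] <- 2 * lo - x[i]
      if (x[i] > hi) x[i] <- 2 * hi - x[i]
    }
  }
  x
}

#' Simulate a behavioural task
#'
#' Runs an agent through `n_trials` of the configured task and returns the
#' resulting trial table, with the true block boundaries stored in the
#' `blocks` attribute. All randomness (environment and agent choice
#' sampling) flows from one generator seeded by `seed`.
#'
#' @param config a [task_config()].
#' @param agent an agent (see [random_agent()]).
#' @param n_trials number of trials (default from the config).
#' @param seed integer seed.
#' @param subject,session identifiers stored in the output.
#' @return a [session_data()].
#' @export
simulate_task <- function(config, agent, n_trials = config$n_trials,
                          seed = 1L, subject = "sim", session = "1") {
  with_local_seed(seed, {
    e <- env_init(config, seed)
    if (config$task == "bandit4")
      e$means <- drifting_bandit_walk(config, n_trials, seed = NULL)
    carry <- agent$init(config)
    n <- n_trials
    action <- state <- integer(n); reward <- numeric(n)
    action2 <- integer(n)
    blk_start <- 1L; blocks <- list()
    blk_type <- function(e) if (config$task == "bandit4") 1L else e$type
    cur_type <- blk_type(e)
    for (t in seq_len(n)) {
      p <- agent$policy(carry, config)
      if (length(p) != config$n_actions || abs(sum(p) - 1) > 1e-8)
        stop("simulate_task: agent returned a distribution of wrong arity")
      a <- sample.int(config$n_actions, 1L, prob = p) - 1L
      if (config$task == "bandit4") {
        s <- a
        r <- min(config$reward_range[2],
                 max(config$reward_range[1],
                     e$means[t, a + 1L] + rnorm(1, 0, config$drift_sd)))
        a2 <- NA_integer_
      } else if (config$task == "two_stage_original") {
        s <- sample.int(config$n_states, 1L, prob = e$trans[a + 1L, ]) - 1L
        a2 <- {
          p2 <- agent$policy2(carry, s, config)
          sample.int(2L, 1L, prob = p2) - 1L
        }
        r <- rbinom(1, 1, e$probs2[s * 2L + a2 + 1L])
      } else {
        s <- sample.int(config$n_states, 1L, prob = e$trans[a + 1L, ]) - 1L
        r <- rbinom(1, 1, e$probs[s + 1L])
        a2 <- NA_integer_
      }
      action[t] <- a; state[t] <- s; reward[t] <- r; action2[t] <- a2
      res <- env_block_step(e, config, a, r, t)
      if (res$switched) {
        blocks[[length(blocks) + 1L]] <- data.frame(
          subject = subject, session = session,
          start = blk_start, end = t, type = cur_type,
          stringsAsFactors = FALSE)
        blk_start <- t + 1L
        cur_type <- blk_type(res$env)
      }
      e <- res$env
      carry <- agent$update(carry, list(action = a, state = s, reward = r,
                                        action2 = a2), config)
    }
    blocks[[length(blocks) + 1L]] <- data.frame(
      subject = subject, session = session, start = blk_start, end = n,
      type = cur_type, stringsAsFactors = FALSE)
    df <- data.frame(subject = subject, session = session,
                     trial = seq_len(n), action = action, state = state,
                     reward = reward, mask = TRUE, stringsAsFactors = FALSE)
    if (config$task == "two_stage_original") df$action2 <- action2
    session_data(df, config, blocks = do.call(rbind, blocks))
  })
}

#' Drifting arm means for the restless four-armed bandit
#'
#' Generates per-trial mean rewards for each arm as a reflected Gaussian
#' random walk on the reward range (default 0-100, step sd from
#' `config$drift_sd`). A step scale of zero yields constant trajectories.
#'
#' @param config a `bandit4` [task_config()].
#' @param n_trials number of trials.
#' @param seed integer seed (`NULL` to use the current RNG stream).
#' @return `n_trials` x 4 matrix of arm means.
#' @export
drifting_bandit_walk <- function(config, n_trials, seed = 1L) {
  if (config$drift_sd < 0)
    stop("drifting_bandit_walk: step scale must be non-negative")
  run <- function() {
    m <- matrix(0, n_trials, config$n_actions)
    m[1, ] <- runif(config$n_actions, config$reward_range[1],
                    config$reward_range[2])
    if (n_trials > 1) for (t in 2:n_trials) {
      m[t, ] <- reflect_bounds(m[t - 1, ] +
                                 rnorm(config$n_actions, 0, config$drift_sd),
                               config$reward_range)
    }
    m
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
}

#' Analytic reward-rate baselines for binary two-stage tasks
#'
#' Closed-form per-trial reward rates: the oracle always takes the action
#' whose common transition leads to the currently high-reward state, earning
#' `p_common * p_high + (1 - p_common) * p_low`; chance is the mean reward
#' probability over actions.
#'
#' @param config a binary-reward [task_config()] with probabilistic
#'   transitions.
#' @return list with elements `oracle` and `chance`.
#' @export
analytic_baselines <- function(config) {
  if (!config$binary_reward)
    stop("analytic_baselines: unsupported for continuous-reward tasks")
  p_common <- max(config$transitions[1, ])
  p_high <- max(config$reward_probs)
  p_low <- min(config$reward_probs)
  oracle <- p_common * p_high + (1 - p_common) * p_low
  chance <- mean(c(p_high, p_low))
  list(oracle = oracle, chance = chance)
}
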