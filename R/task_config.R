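#' Task configurations
#'
#' Builds the configuration object describing one of the supported
#' reward-learning tasks: action/state counts, reward probabilities or drift
#' parameters, action-to-state transition probabilities, and the rule that
#' switches reward (or transition) contingencies between blocks.
#'
#' Supported tasks:
#' \describe{
#'   \item{`reversal`}{Two-action reversal learning with deterministic
#'     action-to-state transitions and fixed-length blocks (80 trials) whose
#'     reversal trial falls uniformly between trials 30 and 50. Default
#'     reward probabilities 0.7/0.3.}
#'   \item{`reversal_ema`}{Reversal learning with neutral blocks
#'     (0.75/0.25 and 0.5/0.5) where non-neutral blocks end 10 trials after
#'     an exponential moving average (tau = 8) of correct choices crosses
#'     0.75, and neutral blocks end with a 10\% per-trial hazard after trial
#'     15.}
#'   \item{`two_stage`}{Reduced two-stage task: probabilistic transitions
#'     (0.8/0.2), reward probabilities 0.8/0.2 switching with 2\% per-trial
#'     probability after a minimum block length of 10.}
#'   \item{`two_stage_ema`}{Two-stage task with neutral blocks (0.4/0.4);
#'     threshold-triggered switches 20 trials after the moving average
#'     crosses 0.75, neutral hazard 10\% after trial 40.}
#'   \item{`transition_reversal`}{As `two_stage_ema` but the transition
#'     matrix itself also reverses between blocks.}
#'   \item{`reversal3`}{Three-armed reversal learning, 160 trials; reward
#'     probabilities (0.9, 0.5, 0.1) then (0.8, 0.4, 0.2) from the halfway
#'     point; the best arm switches after 9 of the last 10 choices of the
#'     current best arm were rewarded.}
#'   \item{`bandit4`}{Four-armed drifting bandit, continuous rewards 0-100
#'     following a reflected Gaussian random walk (default step sd 4),
#'     150 trials.}
#'   \item{`two_stage_original`}{Original two-stage task: two first-stage
#'     actions with 0.7/0.3 transitions to two second-stage states, each
#'     with two second-stage actions whose reward probabilities drift in
#'     \[0.25, 0.75\] (Gaussian steps, sd 0.025), 200 trials.}
#'   \item{`metarl`}{Two-stage environment used for task-optimized agents:
#'     transitions 0.8/0.2, reward probabilities 0.8/0.2 switching with
#'     per-trial probability 0.025, three within-trial periods.}
#' }
#'
#' @param task task identifier (see Details).
#' @param ... overrides for the task's default fields.
#' @return an object of class `task_config`.
#' @export
task_config <- function(task = c("reversal", "reversal_ema", "two_stage",
                                 "two_stage_ema", "transition_reversal",
                                 "reversal3", "bandit4",
                                 "two_stage_original", "metarl"), ...) {
  task <- match.arg(task)
  base <- switch(task,
    reversal = list(
      n_actions = 2L, n_states = 2L, binary_reward = TRUE,
      reward_range = c(0, 1), reward_probs = c(0.7, 0.3),
      transitions = diag(2),
      block = list(rule = "fixed", block_len = 80L,
                   reversal_window = c(30L, 50L)),
      n_trials = 800L),
    reversal_ema = list(
      n_actions = 2L, n_states = 2L, binary_reward = TRUE,
      reward_range = c(0, 1), reward_probs = c(0.75, 0.25),
      neutral_probs = c(0.5, 0.5), transitions = diag(2),
      block = list(rule = "ema", tau = 8, threshold = 0.75, delay = 10L,
                   neutral = TRUE, neutral_hazard = 0.1, neutral_min = 15L),
      n_trials = 1000L),
    two_stage = list(
      n_actions = 2L, n_states = 2L, binary_reward = TRUE,
      reward_range = c(0, 1), reward_probs = c(0.8, 0.2),
      transitions = rbind(c(0.8, 0.2), c(0.2, 0.8)),
      block = list(rule = "prob", p_switch = 0.02, min_len = 10L),
      n_trials = 1000L),
    two_stage_ema = list(
      n_actions = 2L, n_states = 2L, binary_reward = TRUE,
      reward_range = c(0, 1), reward_probs = c(0.8, 0.2),
      neutral_probs = c(0.4, 0.4),
      transitions = rbind(c(0.8, 0.2), c(0.2, 0.8)),
      block = list(rule = "ema", tau = 8, threshold = 0.75, delay = 20L,
                   neutral = TRUE, neutral_hazard = 0.1, neutral_min = 40L),
      n_trials = 1000L),
    transition_reversal = list(
      n_actions = 2L, n_states = 2L, binary_reward = TRUE,
      reward_range = c(0, 1), reward_probs = c(0.8, 0.2),
      neutral_probs = c(0.4, 0.4),
      transitions = rbind(c(0.8, 0.2), c(0.2, 0.8)),
      block = list(rule = "ema", tau = 8, threshold = 0.75, delay = 20L,
                   neutral = TRUE, neutral_hazard = 0.1, neutral_min = 40L,
                   transition_reversal = TRUE),
      n_trials = 1000L),
    reversal3 = list(
      n_actions = 3L, n_states = 3L, binary_reward = TRUE,
      reward_range = c(0, 1), reward_probs = c(0.9, 0.5, 0.1),
      reward_probs2 = c(0.8, 0.4, 0.2), transitions = diag(3),
      block = list(rule = "win9of10", window = 10L, hits = 9L),
      n_trials = 160L),
    bandit4 = list(
      n_actions = 4L, n_states = 4L, binary_reward = FALSE,
      reward_range = c(0, 100), drift_sd = 4, transitions = diag(4),
      block = list(rule = "none"),
      n_trials = 150L),
    two_stage_original = list(
      n_actions = 2L, n_states = 2L, n_actions2 = 2L, binary_reward = TRUE,
      reward_range = c(0, 1),
      reward_probs = NULL,  # drifting per second-stage action
      drift_sd2 = 0.025, reward_bounds2 = c(0.25, 0.75),
      transitions = rbind(c(0.7, 0.3), c(0.3, 0.7)),
      block = list(rule = "none"),
      n_trials = 200L),
    metarl = list(
      n_actions = 2L, n_states = 2L, binary_reward = TRUE,
      reward_range = c(0, 1), reward_probs = c(0.8, 0.2),
      transitions = rbind(c(0.8, 0.2), c(0.2, 0.8)),
      block = list(rule = "prob", p_switch = 0.025, min_len = 0L),
      violation_penalty = -0.1,
      n_trials = 1000L)
  )
  base$task <- task
  dots <- list(...)
  for (nm in names(dots)) base[[nm]] <- dots[[nm]]
  validate_task_config(structure(base, class = "task_config"))
}

validate_task_config <- function(cfg) {
  stopifnot(inherits(cfg, "task_config"))
  if (!is.null(cfg$reward_probs)) {
    if (any(cfg$reward_probs < 0 | cfg$reward_probs > 1))
      stop("task_config: reward probabilities must lie in [0, 1]")
  }
  if (!is.null(cfg$transitions)) {
    if (any(abs(rowSums(cfg$transitions) - 1) > 1e-12))
      stop("task_config: transition rows must sum to 1")
  }
  if (!is.null(cfg$drift_sd) && cfg$drift_sd < 0)
    stop("task_config: drift step scale must be non-negative")
  cfg
}

#' @export
print.task_config <- function(x, ...) {
  cat("<task_config>", x$task, "-", x$n_actions, "actions,",
      x$n_states, "states\n")
  invisible(x)
}

#' Read or write a task configuration as JSON
#'
#' @param path file path.
#' @return `read_task_config` returns a `task_config`.
#' @export
read_task_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  task <- raw$task
  raw$task <- NULL
  if (!is.null(raw$transitions)) raw$transitions <- as.matrix(raw$transitions)
  do.call(task_config, c(list(task = task), raw))
}

#' @param cfg a `task_config`.
#' @rdname read_task_config
#' @export
write_task_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
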