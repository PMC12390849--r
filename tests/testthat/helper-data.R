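## shared fixtures, all generated in code

## random trial table (arbitrary action/state/reward draws, one session)
random_sessions <- function(cfg, n = 1000L, seed = 1L, n_sessions = 1L,
                            masked = 0L) {
  set.seed(seed)
  per <- n %/% n_sessions
  df <- do.call(rbind, lapply(seq_len(n_sessions), function(s) {
    data.frame(subject = "t", session = as.character(s), trial = seq_len(per),
               action = sample(0:(cfg$n_actions - 1L), per, replace = TRUE),
               state = 0L, reward = 0, mask = TRUE,
               stringsAsFactors = FALSE)
  }))
  if (cfg$task %in% c("reversal", "reversal_ema", "reversal3", "bandit4")) {
    df$state <- df$action
  } else {
    df$state <- sample(0:(cfg$n_states - 1L), nrow(df), replace = TRUE)
  }
  df$reward <- if (cfg$binary_reward) sample(0:1, nrow(df), replace = TRUE)
               else runif(nrow(df), cfg$reward_range[1], cfg$reward_range[2])
  if (!is.null(cfg$n_actions2))
    df$action2 <- sample(0:1, nrow(df), replace = TRUE)
  if (masked > 0L) df$mask[sample(nrow(df), masked)] <- FALSE
  session_data(df, cfg)
}

## parameters drawn on the natural scale, reproducibly
random_params <- function(model, seed = 1L) {
  set.seed(seed)
  setNames(cogrnn:::par_random_init(model$par), model$par$name)
}

## the task a catalogue id belongs to
task_of <- function(id) {
  if (startsWith(id, "ots_")) "two_stage_original"
  else if (startsWith(id, "mf3_")) "reversal3"
  else if (startsWith(id, "mf4_")) "bandit4"
  else if (startsWith(id, "akam_")) "transition_reversal"
  else "two_stage"
}

## 20-subject synthetic population of heterogeneous one-dimensional
## reinforcement learners on the two-stage task
synthetic_population <- function(cfg, n_sub = 20L, n_trials = 400L,
                                 seed = 101L) {
  gen <- cognitive_model("mf1", cfg)
  set.seed(seed)
  pars <- lapply(seq_len(n_sub),
                 function(i) c(alpha = runif(1, 0.2, 0.8),
                               beta = runif(1, 2, 5)))
  dats <- lapply(seq_len(n_sub), function(i)
    simulate_task(cfg, cognitive_agent(gen, pars[[i]]), n_trials = n_trials,
                  seed = seed + i, subject = sprintf("m%02d", i)))
  list(data = session_data(do.call(rbind, lapply(dats, as.data.frame)), cfg),
       params = pars, model = gen, per_subject = dats)
}
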