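#' Cognitive model registry
#'
#' Classical trial-by-trial models are registered under string ids and
#' constructed with [cognitive_model()]. Every model is a list with:
#' `id`; `d` (number of dynamical variables); `par` (parameter table with a
#' bounded-support type per parameter); `init(params)` giving the initial
#' dynamical state; `step(state, obs, params)` consuming one trial's outcome
#' `obs = list(action, state, reward, action2)` (0-based codes); and
#' `policy(state, params)` giving next-trial action probabilities. Models for
#' the original two-stage task additionally expose
#' `policy2(state, params, state_code)`.
#'
#' Parameter supports are enforced during fitting by smooth
#' reparameterization: learning/forgetting rates and probabilities through a
#' logistic map, inverse temperatures through softplus, emission
#' probabilities through `0.5 + 0.5 * logistic`, unconstrained weights and
#' biases through the identity.
#'
#' @param id model id, see [cognitive_catalogue()].
#' @param config the [task_config()] the model will be applied to (used for
#'   known transition probabilities and action counts).
#' @return a `cog_model` object.
#' @export
cognitive_model <- function(id, config) {
  reg <- cognitive_registry()
  if (!id %in% names(reg))
    stop("cognitive_model: unknown id '", id, "'")
  m <- reg[[id]](config)
  m$id <- id
  class(m) <- "cog_model"
  m
}

#' List the available cognitive models
#'
#' @return data frame with columns `id`, `d` and `family`.
#' @export
cognitive_catalogue <- function() {
  reg <- cognitive_registry()
  cfg2 <- task_config("two_stage")
  rows <- lapply(names(reg), function(id) {
    cfg <- switch(substr(id, 1, 4),
                  "ots_" = task_config("two_stage_original"),
                  "mf3_" = task_config("reversal3"),
                  "mf4_" = task_config("bandit4"),
                  cfg2)
    m <- reg[[id]](cfg)
    data.frame(id = id, d = m$d, family = m$family,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.cog_model <- function(x, ...) {
  cat("<cog_model>", x$id, "- d =", x$d, "; parameters:",
      paste(x$par$name, collapse = ", "), "\n")
  invisible(x)
}

## parameter table helper
par_def <- function(name, type) {
  data.frame(name = name, type = type, stringsAsFactors = FALSE)
}

## unbounded -> natural scale
par_natural <- function(theta, par) {
  stopifnot(length(theta) == nrow(par))
  out <- numeric(nrow(par))
  for (i in seq_len(nrow(par))) {
    out[i] <- switch(par$type[i],
      rate = logistic(theta[i]),
      temp = softplus(theta[i]),
      emit = 0.5 + 0.5 * logistic(theta[i]),
      real = theta[i])
  }
  names(out) <- par$name
  out
}

## natural -> unbounded scale
par_unbounded <- function(params, par) {
  out <- numeric(nrow(par))
  for (i in seq_len(nrow(par))) {
    p <- params[[par$name[i]]]
    out[i] <- switch(par$type[i],
      rate = logit(min(max(p, 1e-8), 1 - 1e-8)),
      temp = inv_softplus(max(p, 1e-8)),
      emit = logit(min(max((p - 0.5) / 0.5, 1e-8), 1 - 1e-8)),
      real = p)
  }
  out
}

## random natural-scale initializations for fitting restarts
par_random_init <- function(par) {
  p <- numeric(nrow(par))
  for (i in seq_len(nrow(par))) {
    p[i] <- switch(par$type[i],
      rate = runif(1, 0.1, 0.9),
      temp = runif(1, 0.5, 5),
      emit = runif(1, 0.6, 0.95),
      real = rnorm(1, 0, 0.5))
  }
  names(p) <- par$name
  p
}

#' Run a cognitive model over session data
#'
#' Produces the per-trial policy trace: the model is reset at every session
#' start, emits its policy for trial t from the state built from trials
#' 1..t-1, and is then updated with trial t's outcome. Masked (missing)
#' trials produce no state update.
#'
#' @param model a `cog_model`.
#' @param params named parameter vector on the natural scale.
#' @param data a [session_data()].
#' @return a `policy_trace`: list with `p1` (trials x actions matrix), and
#'   for the original two-stage task `p2` (trials x 2, second-stage
#'   probabilities at the realized state).
#' @export
run_cognitive <- function(model, params, data) {
  n <- nrow(data)
  two_stage2 <- !is.null(model$policy2)
  p1 <- matrix(NA_real_, n, model$n_actions)
  p2 <- if (two_stage2) matrix(NA_real_, n, 2L) else NULL
  starts <- session_starts(data)
  is_start <- rep(FALSE, n); is_start[starts] <- TRUE
  state <- NULL
  step <- model$step; pol <- model$policy
  for (t in seq_len(n)) {
    if (is_start[t]) state <- model$init(params)
    p1[t, ] <- pol(state, params)
    if (two_stage2)
      p2[t, ] <- model$policy2(state, params, data$state[t])
    if (data$mask[t]) {
      obs <- list(action = data$action[t], state = data$state[t],
                  reward = data$reward[t],
                  action2 = if (two_stage2) data$action2[t] else NA_integer_)
      state <- step(state, obs, params)
    }
  }
  structure(list(p1 = p1, p2 = p2, model_id = model$id),
            class = "policy_trace")
}

#' Export a policy trace as a plain table
#'
#' @param trace a `policy_trace`.
#' @param path optional CSV path; if given the table is also written there.
#' @return data frame of per-trial action probabilities.
#' @export
policy_trace_table <- function(trace, path = NULL) {
  df <- as.data.frame(trace$p1)
  names(df) <- paste0("p_a", seq_len(ncol(trace$p1)) - 1L)
  if (!is.null(trace$p2)) {
    df2 <- as.data.frame(trace$p2)
    names(df2) <- c("p2_a0", "p2_a1")
    df <- cbind(df, df2)
  }
  df$trial <- seq_len(nrow(df))
  if (!is.null(path)) write.csv(df, path, row.names = FALSE, quote = FALSE)
  df
}
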