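#' Per-trial logits from a policy trace
#'
#' `L(t) = log(Pr(a_t = A1) / Pr(a_t = A2))`, the scalar state coordinate of
#' one-dimensional models; probabilities are floored at 1e-12.
#'
#' @param policy a `policy_trace`.
#' @param pair 1-based column indices of the two actions (default 1 vs 2).
#' @return numeric vector of per-trial log odds.
#' @export
compute_logits <- function(policy, pair = c(1L, 2L)) {
  log(floor_prob(policy$p1[, pair[1]])) -
    log(floor_prob(policy$p1[, pair[2]]))
}

#' Input conditions of a task
#'
#' Enumerates the discrete trial outcomes (action, state, reward) that act
#' as inputs to a model, with readable labels ("A1,S2,R=1").
#'
#' @param config a binary-reward [task_config()] with two actions.
#' @return list of `obs` lists with a `label` element each.
#' @export
condition_set <- function(config) {
  stopifnot(config$binary_reward, config$n_actions == 2L)
  same <- config$task %in% c("reversal", "reversal_ema")
  conds <- list()
  for (a in 0:1) for (s in 0:1) for (r in 0:1) {
    if (same && s != a) next
    lab <- if (same) sprintf("A%d,R=%d", a + 1L, r)
    else sprintf("A%d,S%d,R=%d", a + 1L, s + 1L, r)
    conds[[length(conds) + 1L]] <- list(action = a, state = s, reward = r,
                                        action2 = NA_integer_, label = lab)
  }
  conds
}

## label of the condition a trial row belongs to
condition_labels <- function(data, config) {
  same <- config$task %in% c("reversal", "reversal_ema")
  r <- as.integer(data$reward > 0.5)
  if (same) sprintf("A%d,R=%d", data$action + 1L, r)
  else sprintf("A%d,S%d,R=%d", data$action + 1L, data$state + 1L, r)
}

#' One-dimensional state map of a fitted model
#'
#' Builds the scalar interface used by the dynamical-systems analyses: a
#' function stepping the logit under a fixed input condition. Supported:
#' one-unit recurrent networks (the hidden unit is mapped through the
#' readout) and the one-dimensional cognitive models (`mf1`, `mb1`,
#' `bayes`), whose scalar state is recovered from the logit in closed form.
#'
#' @param model an [rnn_spec()] with `d = 1` or a d = 1 [cognitive_model()].
#' @param fit fitted weights (RNN) or parameters (cognitive).
#' @return list with `step_L(L, obs)`, the logit scale info, and the
#'   admissible logit range (`c(-Inf, Inf)` unless the model bounds it).
#' @export
as_scalar_map <- function(model, fit) {
  if (inherits(model, "rnn_spec")) {
    if (model$d != 1L) stop("as_scalar_map: requires d = 1")
    gain <- if (model$readout == "full") fit$B[1, 1] - fit$B[2, 1]
            else stop("as_scalar_map: one-unit networks use the full readout")
    if (abs(gain) < 1e-12) stop("as_scalar_map: degenerate readout")
    cfg <- model$config
    step1 <- function(h, obs) {
      if (model$arch == "sgru") {
        code <- encode_obs_code(obs, cfg)
        switching_gru_step(h, code, fit)
      } else if (model$arch %in% c("slin", "slin_sym")) {
        slin_step(h, encode_obs_code(obs, cfg), fit, model)
      } else {
        gru_step(h, encode_obs_vec(obs, cfg), fit)
      }
    }
    rng <- if (model$arch %in% c("gru", "sgru")) sort(gain * c(-1, 1))
           else c(-Inf, Inf)
    list(step_L = function(L, obs) gain * step1(L / gain, obs),
         range = rng)
  } else if (inherits(model, "cog_model")) {
    if (model$d != 1L) stop("as_scalar_map: requires d = 1")
    params <- fit
    if (model$family == "mf") {          # mf1: L = 2 beta q(A1)
      b <- params[["beta"]]
      list(step_L = function(L, obs) {
        q1 <- L / (2 * b)
        st <- model$step(list(q = c(q1, -q1)), obs, params)
        2 * b * st$q[1]
      }, range = c(-Inf, Inf))
    } else if (model$family == "mb") {   # mb1 via the known transitions
      b <- params[["beta"]]
      p <- max(attr_trans(model)[1, ])
      gain <- 2 * b * (2 * p - 1)
      list(step_L = function(L, obs) {
        v1 <- L / gain
        st <- model$step(list(v = c(v1, -v1)), obs, params)
        gain * st$v[1]
      }, range = c(-Inf, Inf))
    } else if (model$family == "bayes") { # L = beta (2 Pr(h=1) - 1)
      b <- params[["beta"]]
      list(step_L = function(L, obs) {
        belief <- (L / b + 1) / 2
        belief <- min(max(belief, 0), 1)
        st <- model$step(list(b = belief), obs, params)
        b * (2 * st$b - 1)
      }, range = c(-b, b))
    } else stop("as_scalar_map: no scalar interface for family ",
                model$family)
  } else stop("as_scalar_map: unsupported model")
}

## closure over the policy environment to read the known transition matrix
attr_trans <- function(model) environment(model$policy)$trans

encode_obs_code <- function(obs, config) {
  r <- as.integer(obs$reward > 0.5)
  if (config$task %in% c("reversal", "reversal_ema"))
    1L + 2L * obs$action + r
  else 1L + 4L * obs$action + 2L * obs$state + r
}

encode_obs_vec <- function(obs, config) {
  r <- obs$reward / config$reward_range[2]
  if (config$n_actions > 2L) {
    onehot <- numeric(config$n_actions); onehot[obs$action + 1L] <- 1
    c(onehot, r)
  } else c(obs$action, obs$state, r)
}

#' Phase portrait of a one-dimensional model
#'
#' For each input condition, evaluates the one-step logit change
#' `dL = L' - L` along a grid of logits (curve) and, when data are supplied,
#' at the logits the model actually visited (scatter). The grid spans the
#' 0.5-99.5 percentile range of the observed logits when data are given.
#'
#' @param model,fit as in [as_scalar_map()].
#' @param config the [task_config()].
#' @param data optional [session_data()] providing observed states.
#' @param n_grid grid resolution (default 512).
#' @param grid_range logit range when no data are given.
#' @return a `portrait` object: list with `conditions`, `grid`, `curves`
#'   (grid x condition matrix of logit changes), `scatter` (data frame), and
#'   `fixed_points` (per condition, see [find_fixed_points()]).
#' @export
phase_portrait <- function(model, fit, config, data = NULL, n_grid = 512L,
                           grid_range = c(-5, 5)) {
  map <- as_scalar_map(model, fit)
  conds <- condition_set(config)
  scatter <- NULL
  if (!is.null(data)) {
    trace <- if (inherits(model, "rnn_spec"))
      rnn_policy_trace(model, fit, data) else run_cognitive(model, fit, data)
    L <- compute_logits(trace)
    key <- paste(data$subject, data$session)
    ok <- key[-length(key)] == key[-1]        # consecutive same-session pairs
    scatter <- data.frame(L = L[-length(L)][ok],
                          dL = diff(L)[ok],
                          condition = condition_labels(data, config)[
                            -length(L)][ok],
                          stringsAsFactors = FALSE)
    grid_range <- quantile(L, c(0.005, 0.995), names = FALSE)
  }
  lo <- max(grid_range[1], map$range[1] * 0.999)
  hi <- min(grid_range[2], map$range[2] * 0.999)
  grid <- seq(lo, hi, length.out = n_grid)
  curves <- sapply(conds, function(cn)
    vapply(grid, function(L) map$step_L(L, cn) - L, 0))
  colnames(curves) <- vapply(conds, `[[`, "", "label")
  fps <- lapply(conds, function(cn)
    find_fixed_points(function(L) map$step_L(L, cn) - L, lo, hi))
  names(fps) <- colnames(curves)
  structure(list(conditions = conds, grid = grid, curves = curves,
                 scatter = scatter, fixed_points = fps, map = map),
            class = "portrait")
}

#' Scatter-only portrait from recorded logits
#'
#' Builds the (logit, logit-change) sample pairs of an arbitrary policy
#' (for example a task-optimized agent) without needing a scalar state map.
#'
#' @param logits per-trial logit vector.
#' @param data the matching [session_data()].
#' @param config the [task_config()].
#' @return data frame with columns `L`, `dL`, `condition`.
#' @export
portrait_scatter <- function(logits, data, config) {
  key <- paste(data$subject, data$session)
  ok <- key[-length(key)] == key[-1]
  data.frame(L = logits[-length(logits)][ok], dL = diff(logits)[ok],
             condition = condition_labels(data, config)[-length(logits)][ok],
             stringsAsFactors = FALSE)
}

#' Fixed points of a one-dimensional logit-change curve
#'
#' Brackets sign changes of `g(L) = dL` on a grid and refines each root by
#' bisection to `|g| < tol`. Stability follows the discrete-map criterion:
#' the fixed point is stable when `-2 < g'(L*) < 0`, with the derivative
#' estimated by central differences. An empty result (no sign change in
#' range) is returned as a zero-row table, not an error.
#'
#' @param g function of the logit returning the logit change.
#' @param lower,upper search range.
#' @param n_grid grid resolution (default 512).
#' @param tol root tolerance on `|g|` (default 1e-8).
#' @return data frame with columns `L_star`, `slope`, `stable`.
#' @export
find_fixed_points <- function(g, lower, upper, n_grid = 512L, tol = 1e-8) {
  grid <- seq(lower, upper, length.out = n_grid)
  vals <- vapply(grid, g, 0)
  out <- data.frame(L_star = numeric(0), slope = numeric(0),
                    stable = logical(0))
  for (i in seq_len(n_grid - 1L)) {
    v1 <- vals[i]; v2 <- vals[i + 1L]
    root <- NA_real_
    if (abs(v1) < tol && (i == 1L || abs(vals[i - 1L]) >= tol)) root <- grid[i]
    else if (v1 * v2 < 0) {
      a <- grid[i]; b <- grid[i + 1L]; fa <- v1
      for (k in seq_len(200L)) {
        m <- (a + b) / 2; fm <- g(m)
        if (abs(fm) < tol) break
        if (fa * fm < 0) b <- m else { a <- m; fa <- fm }
      }
      root <- (a + b) / 2
    }
    if (!is.na(root)) {
      h <- max(1e-6, abs(root) * 1e-6)
      slope <- (g(root + h) - g(root - h)) / (2 * h)
      out <- rbind(out, data.frame(L_star = root, slope = slope,
                                   stable = slope > -2 && slope < 0))
    }
  }
  out
}

#' Preference setpoints
#'
#' Iterates the one-input logit map from a start point (by default the
#' median observed logit, or 0) until `|dL| < tol` (cap `max_iter`), for
#' every input condition, then normalizes the asymptotic logits by the
#' largest absolute fixed point: `u_I = L*_I / max_I |L*_I|`. Diverging
#' conditions are flagged with the sign of the drift.
#'
#' @param model,fit,config as in [phase_portrait()].
#' @param start iteration start (default 0).
#' @param max_iter iteration cap (default 1e4).
#' @param tol convergence tolerance (default 1e-8).
#' @return data frame with columns `condition`, `L_star`, `u`, `converged`.
#' @export
preference_setpoints <- function(model, fit, config, start = 0,
                                 max_iter = 10000L, tol = 1e-8) {
  map <- as_scalar_map(model, fit)
  conds <- condition_set(config)
  res <- lapply(conds, function(cn) {
    L <- start
    conv <- FALSE
    for (i in seq_len(max_iter)) {
      L2 <- map$step_L(L, cn)
      if (!is.finite(L2) || abs(L2) > 1e9) {
        return(data.frame(condition = cn$label, L_star = sign(L2) * Inf,
                          u = NA_real_, converged = FALSE))
      }
      if (abs(L2 - L) < tol) { conv <- TRUE; L <- L2; break }
      L <- L2
    }
    data.frame(condition = cn$label, L_star = L, u = NA_real_,
               converged = conv)
  })
  tab <- do.call(rbind, res)
  norm <- max(abs(tab$L_star[is.finite(tab$L_star)]), na.rm = TRUE)
  tab$u <- if (norm > 0) tab$L_star / norm else 0 * tab$L_star
  tab
}

#' Effective learning rate
#'
#' Relative to a stable fixed point `L*`, the effective learning rate at `L`
#' is the negative secant slope `alpha(L) = -g(L) / (L - L*)`; at `L = L*`
#' it is the negative tangent slope `-g'(L*)` (central differences).
#'
#' @param g logit-change function of one condition.
#' @param L_star a stable fixed point of `g`.
#' @param L numeric vector of evaluation points.
#' @return numeric vector `alpha(L)`.
#' @export
effective_learning_rate <- function(g, L_star, L) {
  vapply(L, function(x) {
    if (abs(x - L_star) < 1e-9) {
      h <- max(1e-6, abs(L_star) * 1e-6)
      -(g(L_star + h) - g(L_star - h)) / (2 * h)
    } else -g(x) / (x - L_star)
  }, 0)
}

#' Two-dimensional state map of a fitted model
#'
#' Planar interface for d = 2 models: preference coordinates (readout-scaled
#' hidden units for RNNs with a diagonal readout, `beta * Q` for the
#' two-value cognitive models) and the one-step map under a fixed input.
#'
#' @param model an [rnn_spec()] (`d = 2`, diagonal readout) or a d = 2
#'   cognitive model whose state is a pair of action values.
#' @param fit fitted weights or parameters.
#' @return list with `step_P(P, obs)` on preference coordinates.
#' @export
as_planar_map <- function(model, fit) {
  if (inherits(model, "rnn_spec")) {
    if (model$d != 2L || model$readout != "diagonal")
      stop("as_planar_map: requires d = 2 with a diagonal readout")
    gain <- fit$B
    cfg <- model$config
    step_h <- function(h, obs) {
      if (model$arch == "gru") gru_step(h, encode_obs_vec(obs, cfg), fit)
      else if (model$arch == "sgru")
        switching_gru_step(h, encode_obs_code(obs, cfg), fit)
      else slin_step(h, encode_obs_code(obs, cfg), fit, model)
    }
    list(step_P = function(P, obs) gain * step_h(P / gain, obs))
  } else if (inherits(model, "cog_model")) {
    if (model$d != 2L || is.null(model$init(fit)$q))
      stop("as_planar_map: requires a two-action-value model")
    b <- fit[["beta"]]
    list(step_P = function(P, obs) {
      st <- model$step(list(q = P / b), obs, fit)
      b * st$q
    })
  } else stop("as_planar_map: unsupported model")
}

#' Two-dimensional vector field and attractors
#'
#' Evaluates the one-step state change at each node of a grid over the two
#' preference coordinates, for every input condition, and locates attractors
#' by iterating the one-input map from each node to convergence.
#'
#' @param model,fit as in [as_planar_map()].
#' @param config the [task_config()].
#' @param grid1,grid2 coordinate grids (default 13 points on \[-2, 2\]).
#' @param max_iter iteration cap for attractor location.
#' @return list with `arrows` (data frame: condition, p1, p2, dp1, dp2,
#'   speed) and `attractors` (data frame of converged points per condition).
#' @export
vector_field_2d <- function(model, fit, config,
                            grid1 = seq(-2, 2, length.out = 13L),
                            grid2 = seq(-2, 2, length.out = 13L),
                            max_iter = 5000L) {
  map <- as_planar_map(model, fit)
  conds <- condition_set(config)
  arrows <- list(); attractors <- list()
  for (cn in conds) {
    g <- expand.grid(p1 = grid1, p2 = grid2)
    dp <- t(apply(g, 1L, function(p) map$step_P(as.numeric(p), cn) - p))
    arrows[[cn$label]] <- data.frame(condition = cn$label, g,
                                     dp1 = dp[, 1], dp2 = dp[, 2],
                                     speed = sqrt(rowSums(dp^2)))
    pts <- unique(t(apply(g, 1L, function(p) {
      x <- as.numeric(p)
      for (i in seq_len(max_iter)) {
        x2 <- map$step_P(x, cn)
        if (!all(is.finite(x2)) || max(abs(x2)) > 1e9)
          return(c(NA_real_, NA_real_))
        if (max(abs(x2 - x)) < 1e-9) return(round(x2, 6))
        x <- x2
      }
      c(NA_real_, NA_real_)
    })))
    pts <- pts[stats::complete.cases(pts), , drop = FALSE]
    if (nrow(pts))
      attractors[[cn$label]] <- data.frame(condition = cn$label,
                                           p1 = pts[, 1], p2 = pts[, 2])
  }
  list(arrows = do.call(rbind, arrows),
       attractors = if (length(attractors)) do.call(rbind, attractors)
                    else NULL)
}

#' Dynamical regression
#'
#' Approximates the one-step dynamics under each input condition with a
#' linear function of the current state: ordinary least squares of each
#' coordinate's change on all current coordinates (plus the continuous
#' reward when `include_reward = TRUE`), fitted separately per condition
#' with an intercept. The slope coefficients are assembled into the
#' input-dependent state-transition matrix `A` (row i = regression of
#' coordinate i's change).
#'
#' @param states T x d matrix of per-trial state coordinates (logits or
#'   preferences).
#' @param inputs length-T vector of input-condition labels (the input acting
#'   between rows t and t + 1).
#' @param rewards optional per-trial continuous rewards.
#' @param valid optional logical vector marking rows whose transition to the
#'   next row is a genuine within-session step.
#' @param include_reward add the reward regressor.
#' @return list keyed by condition: each element has `beta0` (length d),
#'   `A` (d x d), `beta_r` (length d or NULL), `sigma2`, `n`; conditions
#'   with fewer than d + 2 usable transitions or a rank-deficient design are
#'   flagged with `estimable = FALSE`.
#' @export
dynamical_regression <- function(states, inputs, rewards = NULL,
                                 valid = NULL, include_reward = FALSE) {
  states <- as.matrix(states)
  T_ <- nrow(states); d <- ncol(states)
  valid <- valid %||% rep(TRUE, T_ - 1L)
  dS <- states[-1L, , drop = FALSE] - states[-T_, , drop = FALSE]
  S0 <- states[-T_, , drop = FALSE]
  inp <- inputs[-T_][valid]
  dS <- dS[valid, , drop = FALSE]; S0 <- S0[valid, , drop = FALSE]
  r0 <- if (include_reward) rewards[-T_][valid] else NULL
  out <- list()
  for (cn in unique(inp)) {
    rows <- inp == cn
    n <- sum(rows)
    need <- d + 2L + as.integer(include_reward)
    if (n < need) {
      out[[cn]] <- list(estimable = FALSE, n = n)
      next
    }
    X <- S0[rows, , drop = FALSE]
    colnames(X) <- paste0("P", seq_len(d))
    df <- as.data.frame(X)
    if (include_reward) df$r <- r0[rows]
    qrX <- qr(cbind(1, as.matrix(df)))
    if (qrX$rank < ncol(df) + 1L) {
      out[[cn]] <- list(estimable = FALSE, n = n)
      next
    }
    A <- matrix(NA_real_, d, d)
    beta0 <- numeric(d); beta_r <- numeric(d); sig <- numeric(d)
    for (i in seq_len(d)) {
      df$y <- dS[rows, i]
      fit <- lm(y ~ ., data = df)
      cf <- coef(fit)
      beta0[i] <- cf[["(Intercept)"]]
      A[i, ] <- cf[paste0("P", seq_len(d))]
      if (include_reward) beta_r[i] <- cf[["r"]]
      sig[i] <- mean(fit$residuals^2)
    }
    out[[cn]] <- list(estimable = TRUE, beta0 = beta0, A = A,
                      beta_r = if (include_reward) beta_r else NULL,
                      sigma2 = sig, n = n)
  }
  out
}

#' Per-trial state coordinates of a fitted model
#'
#' Preference coordinates used by [dynamical_regression()]: readout scores
#' for RNNs (diagonal or state-logit readouts), `beta * Q` for value-based
#' cognitive models.
#'
#' @param model,fit a fitted model handle.
#' @param data a [session_data()].
#' @return list with `states` (T x d), `inputs` (condition labels), `valid`
#'   (within-session transition mask), `rewards`.
#' @export
state_trajectory <- function(model, fit, data) {
  cfg <- if (inherits(model, "rnn_spec")) model$config
         else attr(data, "task")
  if (inherits(model, "rnn_spec")) {
    tr <- rnn_policy_trace(model, fit, data)
    states <- tr$scores
  } else {
    n <- nrow(data)
    states <- matrix(NA_real_, n, model$d)
    b <- if ("beta" %in% names(fit)) fit[["beta"]] else 1
    starts <- session_starts(data)
    is_start <- rep(FALSE, n); is_start[starts] <- TRUE
    st <- NULL
    for (t in seq_len(n)) {
      if (is_start[t]) st <- model$init(fit)
      states[t, ] <- b * st$q[seq_len(model$d)]
      if (data$mask[t])
        st <- model$step(st, list(action = data$action[t],
                                  state = data$state[t],
                                  reward = data$reward[t],
                                  action2 = data$action2[t] %||% NA), fit)
    }
  }
  key <- paste(data$subject, data$session)
  valid <- key[-length(key)] == key[-1]
  if (cfg$n_actions > 2L) {
    r <- as.integer(data$reward > 0.5)
    labels <- if (cfg$binary_reward)
      sprintf("A%d,R=%d", data$action + 1L, r)
    else sprintf("A%d", data$action + 1L)
  } else labels <- condition_labels(data, cfg)
  list(states = states, inputs = labels, valid = valid,
       rewards = data$reward / cfg$reward_range[2])
}
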