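## The catalogue of classical cognitive models.
##
## Naming: `mf`/`mb` = model-free / model-based value learning; the digit is
## the number of dynamical variables in the base task family. Ids prefixed
## `akam_` are the component models for the transition-reversal two-stage
## task; `mf3_`/`mf4_` are the n-armed human bandit families; `ots_` are the
## original (two-choice-stage) two-stage task models. Action and state codes
## are 0-based; values are indexed code + 1.

cognitive_registry <- function() {
  list(
    bayes = model_bayes,
    mf1 = model_mf1,
    mf2 = function(cfg) model_mf2(cfg, forget = "none"),
    mf2_forget = function(cfg) model_mf2(cfg, forget = "to_zero"),
    mf2_forget_mean = function(cfg) model_mf2(cfg, forget = "to_mean"),
    mf2_dtto = model_mf2_dtto,
    mf1_inertia = function(cfg) model_mf_inertia(cfg, independent = FALSE),
    mf2_inertia = function(cfg) model_mf_inertia(cfg, independent = TRUE),
    rac8 = model_rac8,
    mfq0 = model_mfq0,
    mb1 = model_mb1,
    mb2 = function(cfg) model_mb2(cfg, forget = FALSE),
    mb2_forget = function(cfg) model_mb2(cfg, forget = TRUE),
    mb_mix = model_mb_mix,
    akam_mf = function(cfg) model_akam(cfg, mf = TRUE),
    akam_mf_forget = function(cfg) model_akam(cfg, mf = TRUE, forget_q = TRUE),
    akam_mf_full = function(cfg) model_akam(cfg, mf = TRUE, forget_q = TRUE,
                                            mo = TRUE, multi_cp = TRUE,
                                            multi_mocp = TRUE),
    akam_mb = function(cfg) model_akam(cfg, mb = TRUE),
    akam_mb_forget = function(cfg) model_akam(cfg, mb = TRUE,
                                              forget_q = TRUE,
                                              forget_t = TRUE),
    akam_mb_mf = function(cfg) model_akam(cfg, mf = TRUE, mb = TRUE),
    akam_mb_full = function(cfg) model_akam(cfg, mf = TRUE, mb = TRUE,
                                            mo = TRUE, forget_q = TRUE,
                                            forget_t = TRUE, multi_cp = TRUE,
                                            multi_mocp = TRUE),
    mf3_basic = function(cfg) model_mfn(cfg, forget = FALSE, pers = FALSE),
    mf3_forget = function(cfg) model_mfn(cfg, forget = TRUE, pers = FALSE),
    mf3_forget_pers = function(cfg) model_mfn(cfg, forget = TRUE, pers = TRUE),
    mf3_utility = model_mfn_utility,
    mf4_basic = function(cfg) model_mfn(cfg, forget = FALSE, pers = FALSE),
    mf4_forget = function(cfg) model_mfn(cfg, forget = TRUE, pers = FALSE),
    mf4_forget_pers = function(cfg) model_mfn(cfg, forget = TRUE, pers = TRUE),
    mf4_refpoint = function(cfg) model_mfn_refpoint(cfg, reduced = FALSE),
    mf4_refpoint_reduced = function(cfg) model_mfn_refpoint(cfg, reduced = TRUE),
    ots_mf3 = function(cfg) model_ots(cfg, kind = "mf", anticorr = TRUE),
    ots_mf6 = function(cfg) model_ots(cfg, kind = "mf", anticorr = FALSE),
    ots_mb2 = function(cfg) model_ots(cfg, kind = "mb", anticorr = TRUE),
    ots_mb4 = function(cfg) model_ots(cfg, kind = "mb", anticorr = FALSE),
    ots_mix3 = function(cfg) model_ots(cfg, kind = "mix", anticorr = TRUE),
    ots_mix6 = function(cfg) model_ots(cfg, kind = "mix", anticorr = FALSE),
    ots_utility3 = model_ots_utility
  )
}

## --- Bayesian inference (d = 1) --------------------------------------------
## Latent state h = i means state S_i currently carries the high reward
## probability; the belief is updated by Bayes' rule and then mixed with the
## per-trial switch probability p_r. The policy applies softmax directly to
## (beta * b, beta * (1 - b)).
model_bayes <- function(cfg) {
  list(
    family = "bayes", d = 1L, n_actions = 2L,
    par = rbind(par_def("p_emit", "emit"), par_def("p_r", "rate"),
                par_def("beta", "temp")),
    init = function(params) list(b = 0.5),
    step = function(state, obs, params) {
      pe <- params[["p_emit"]]
      ## Pr(r | h, s): the high state emits reward with probability p_emit
      lik <- function(h) {
        p1 <- if (obs$state == (h - 1L)) pe else 1 - pe
        if (obs$reward > 0.5) p1 else 1 - p1
      }
      num1 <- lik(1L) * state$b
      num2 <- lik(2L) * (1 - state$b)
      if (num1 + num2 <= 0)
        stop("bayes step: zero normalizer in belief update")
      post <- num1 / (num1 + num2)
      pr <- params[["p_r"]]
      list(b = (1 - pr) * post + pr * (1 - post))
    },
    policy = function(state, params)
      softmax_policy(c(state$b, 1 - state$b), params[["beta"]])
  )
}

## --- Model-free, anticorrelated values (d = 1) -----------------------------
model_mf1 <- function(cfg) {
  list(
    family = "mf", d = 1L, n_actions = 2L,
    par = rbind(par_def("alpha", "rate"), par_def("beta", "temp")),
    init = function(params) list(q = c(0, 0)),
    step = function(state, obs, params) {
      a <- obs$action + 1L; u <- 3L - a; r <- obs$reward
      al <- params[["alpha"]]
      q <- state$q
      q[a] <- q[a] + al * (r - q[a])
      q[u] <- q[u] - al * (r + q[u])
      list(q = q)
    },
    policy = function(state, params)
      softmax_policy(state$q, params[["beta"]])
  )
}

## --- Model-free, independent values (d = 2), three forgetting modes --------
model_mf2 <- function(cfg, forget = c("none", "to_zero", "to_mean")) {
  forget <- match.arg(forget)
  par <- rbind(par_def("alpha", "rate"), par_def("beta", "temp"))
  if (forget != "none") par <- rbind(par, par_def("D", "rate"))
  list(
    family = "mf", d = 2L, n_actions = 2L, par = par,
    init = function(params) list(q = c(0, 0)),
    step = function(state, obs, params) {
      a <- obs$action + 1L; u <- 3L - a
      q <- state$q
      q[a] <- q[a] + params[["alpha"]] * (obs$reward - q[a])
      if (forget == "to_zero") q[u] <- params[["D"]] * q[u]
      if (forget == "to_mean") q[u] <- params[["D"]] * q[u] +
          (1 - params[["D"]]) * 0.5
      list(q = q)
    },
    policy = function(state, params)
      softmax_policy(state$q, params[["beta"]])
  )
}

## --- Model-free with the drift-to-the-other rule (d = 2) -------------------
model_mf2_dtto <- function(cfg) {
  list(
    family = "mf", d = 2L, n_actions = 2L,
    par = rbind(par_def("D1", "rate"), par_def("b", "rate"),
                par_def("alpha0", "rate"), par_def("beta", "temp")),
    init = function(params) list(q = c(0, 0)),
    step = function(state, obs, params) {
      a <- obs$action + 1L; u <- 3L - a
      q <- state$q
      if (obs$reward > 0.5) {
        q[a] <- params[["D1"]] * q[a] + 1
        q[u] <- q[u] - params[["b"]]
      } else {
        q[a] <- q[a] + params[["alpha0"]] * (q[u] - q[a])
      }
      list(q = q)
    },
    policy = function(state, params)
      softmax_policy(state$q, params[["beta"]])
  )
}

## --- Model-free with perseveration trace -----------------------------------
## independent = FALSE: anticorrelated values (d = 2 in total);
## independent = TRUE: independent values (d = 3 in total).
model_mf_inertia <- function(cfg, independent) {
  list(
    family = "mf", d = if (independent) 3L else 2L, n_actions = 2L,
    par = rbind(par_def("alpha", "rate"), par_def("beta", "temp"),
                par_def("alpha_pers", "rate"), par_def("k_pers", "real")),
    init = function(params) list(q = c(0, 0), x = c(0, 0)),
    step = function(state, obs, params) {
      a <- obs$action + 1L; u <- 3L - a; r <- obs$reward
      al <- params[["alpha"]]; ap <- params[["alpha_pers"]]
      k <- params[["k_pers"]]
      q <- state$q; x <- state$x
      q[a] <- q[a] + al * (r - q[a])
      if (independent) {
        ## unchosen value unaffected
      } else {
        q[u] <- q[u] - al * (r + q[u])
      }
      x[a] <- x[a] + ap * (k - x[a])
      x[u] <- x[u] - ap * (k + x[u])
      list(q = q, x = x)
    },
    policy = function(state, params)
      softmax_policy(state$q + state$x, params[["beta"]])
  )
}

## --- Reward-as-cue strategy (d = 8) -----------------------------------------
## The previous trial's (state, reward) pair is treated as an augmented state
## with two action values each; only the slot of the visited augmented state
## and chosen action is updated.
model_rac8 <- function(cfg) {
  aug_code <- function(s, r) s * 2L + as.integer(r > 0.5) + 1L
  list(
    family = "mf", d = 8L, n_actions = 2L,
    par = rbind(par_def("alpha", "rate"), par_def("beta", "temp")),
    init = function(params) list(q = matrix(0, 4L, 2L), aug = 1L),
    step = function(state, obs, params) {
      a <- obs$action + 1L
      q <- state$q
      q[state$aug, a] <- q[state$aug, a] +
        params[["alpha"]] * (obs$reward - q[state$aug, a])
      list(q = q, aug = aug_code(obs$state, obs$reward))
    },
    policy = function(state, params)
      softmax_policy(state$q[state$aug, ], params[["beta"]])
  )
}

## --- Model-free Q(0) with second-stage state values (d = 4) ----------------
model_mfq0 <- function(cfg) {
  list(
    family = "mf", d = 4L, n_actions = 2L,
    par = rbind(par_def("alpha", "rate"), par_def("beta", "temp")),
    init = function(params) list(q = c(0, 0), v = c(0, 0)),
    step = function(state, obs, params) {
      a <- obs$action + 1L; s <- obs$state + 1L
      al <- params[["alpha"]]
      q <- state$q; v <- state$v
      q[a] <- q[a] + al * (v[s] - q[a])   # uses the pre-update state value
      v[s] <- v[s] + al * (obs$reward - v[s])
      list(q = q, v = v)
    },
    policy = function(state, params)
      softmax_policy(state$q, params[["beta"]])
  )
}

## --- Model-based with anticorrelated state values (d = 1) ------------------
## First-stage action values are computed through the known transition
## matrix: Q(A_i) = sum_j Pr(S_j | A_i) V(S_j).
model_mb1 <- function(cfg) {
  trans <- cfg$transitions
  list(
    family = "mb", d = 1L, n_actions = 2L,
    par = rbind(par_def("alpha", "rate"), par_def("beta", "temp")),
    init = function(params) list(v = c(0, 0)),
    step = function(state, obs, params) {
      s <- obs$state + 1L; u <- 3L - s; r <- obs$reward
      al <- params[["alpha"]]
      v <- state$v
      v[s] <- v[s] + al * (r - v[s])
      v[u] <- v[u] - al * (r + v[u])
      list(v = v)
    },
    policy = function(state, params)
      softmax_policy(as.numeric(trans %*% state$v), params[["beta"]])
  )
}

## --- Model-based with independent state values (d = 2) ---------------------
model_mb2 <- function(cfg, forget) {
  trans <- cfg$transitions
  par <- rbind(par_def("alpha", "rate"), par_def("beta", "temp"))
  if (forget) par <- rbind(par, par_def("D", "rate"))
  list(
    family = "mb", d = 2L, n_actions = 2L, par = par,
    init = function(params) list(v = c(0, 0)),
    step = function(state, obs, params) {
      s <- obs$state + 1L; u <- 3L - s
      v <- state$v
      v[s] <- v[s] + params[["alpha"]] * (obs$reward - v[s])
      if (forget) v[u] <- params[["D"]] * v[u]
      list(v = v)
    },
    policy = function(state, params)
      softmax_policy(as.numeric(trans %*% state$v), params[["beta"]])
  )
}

## --- Mixture of d = 1 model-free and d = 1 model-based (d = 2) -------------
model_mb_mix <- function(cfg) {
  trans <- cfg$transitions
  list(
    family = "mix", d = 2L, n_actions = 2L,
    par = rbind(par_def("alpha_mf", "rate"), par_def("alpha_mb", "rate"),
                par_def("w", "rate"), par_def("beta", "temp")),
    init = function(params) list(q = c(0, 0), v = c(0, 0)),
    step = function(state, obs, params) {
      a <- obs$action + 1L; ua <- 3L - a
      s <- obs$state + 1L; us <- 3L - s
      r <- obs$reward
      q <- state$q; v <- state$v
      amf <- params[["alpha_mf"]]; amb <- params[["alpha_mb"]]
      q[a] <- q[a] + amf * (r - q[a])
      q[ua] <- q[ua] - amf * (r + q[ua])
      v[s] <- v[s] + amb * (r - v[s])
      v[us] <- v[us] - amb * (r + v[us])
      list(q = q, v = v)
    },
    policy = function(state, params) {
      qmb <- as.numeric(trans %*% state$v)
      w <- params[["w"]]
      softmax_policy((1 - w) * state$q + w * qmb, params[["beta"]])
    }
  )
}

## --- Component models for the transition-reversal two-stage task -----------
## State slots: second-stage state values v (2); model-free action values
## qmf (2); learned transition probabilities p = (P(S1|A1), P(S1|A2));
## motor-level values qmo (previous-state x action, 2 x 2); choice
## perseveration xcp (scalar EMA of +-0.5 choice codes); motor-level
## perseveration xmocp (per previous state, 2). `slast`/`sprev` track
## s_{t-1} and s_{t-2} (both initialised to state S1).
model_akam <- function(cfg, mf = FALSE, mo = FALSE, mb = FALSE,
                       forget_q = FALSE, forget_t = FALSE,
                       multi_cp = FALSE, multi_mocp = FALSE) {
  par <- rbind(par_def("alpha_q", "rate"),
               par_def("bias_c", "real"), par_def("bias_r", "real"),
               par_def("p_c", "real"))
  if (mf || mo) par <- rbind(par, par_def("alpha", "rate"),
                             par_def("lambda", "rate"))
  if (mf) par <- rbind(par, par_def("g_mf", "temp"))
  if (mo) par <- rbind(par, par_def("g_mo", "temp"))
  if (mb) par <- rbind(par, par_def("alpha_t", "rate"),
                       par_def("g_mb", "temp"))
  if (forget_q) par <- rbind(par, par_def("f_q", "rate"))
  if (forget_t && mb) par <- rbind(par, par_def("f_t", "rate"))
  if (multi_cp) par <- rbind(par, par_def("alpha_c", "rate"))
  if (multi_mocp) par <- rbind(par, par_def("alpha_m", "rate"),
                               par_def("p_m", "real"))
  d <- 2L + 2L * (mf) + 2L * (mb) + 4L * (mo) +
    1L * (multi_cp) + 2L * (multi_mocp)
  list(
    family = "akam", d = as.integer(d), n_actions = 2L, par = par,
    init = function(params) list(
      v = c(0, 0), qmf = c(0, 0), p = c(0.5, 0.5),
      qmo = matrix(0, 2L, 2L), xcp = 0, xmocp = c(0, 0),
      slast = 0L, sprev = 0L),
    step = function(state, obs, params) {
      a <- obs$action + 1L; ua <- 3L - a
      s <- obs$state + 1L; us <- 3L - s
      r <- obs$reward
      st <- state
      xt <- if (obs$action == 0L) -0.5 else 0.5   # single-trial choice code
      if (mf) {
        lam <- params[["lambda"]]
        tgt <- lam * r + (1 - lam) * st$v[s]
        st$qmf[a] <- st$qmf[a] + params[["alpha"]] * (tgt - st$qmf[a])
        if (forget_q) st$qmf[ua] <- (1 - params[["f_q"]]) * st$qmf[ua]
      }
      if (mo) {
        lam <- params[["lambda"]]
        sp <- st$sprev + 1L                        # s_{t-2}
        tgt <- lam * r + (1 - lam) * st$v[sp]
        st$qmo[sp, a] <- st$qmo[sp, a] +
          params[["alpha"]] * (tgt - st$qmo[sp, a])
        if (forget_q) {
          other <- cbind(c(sp, 3L - sp, 3L - sp), c(ua, a, ua))
          st$qmo[other] <- (1 - params[["f_q"]]) * st$qmo[other]
        }
      }
      if (mb) {
        at <- params[["alpha_t"]]
        obs_s1 <- as.numeric(s == 1L)
        st$p[a] <- st$p[a] + at * (obs_s1 - st$p[a])
        if (forget_t) {
          ft <- params[["f_t"]]
          st$p[ua] <- st$p[ua] + ft * (0.5 - st$p[ua])
        }
      }
      st$v[s] <- st$v[s] + params[["alpha_q"]] * (r - st$v[s])
      if (forget_q) st$v[us] <- (1 - params[["f_q"]]) * st$v[us]
      if (multi_cp) st$xcp <- st$xcp + params[["alpha_c"]] * (xt - st$xcp)
      else st$xcp <- xt
      if (multi_mocp) {
        sp <- st$sprev + 1L
        st$xmocp[sp] <- st$xmocp[sp] +
          params[["alpha_m"]] * (xt - st$xmocp[sp])
      }
      st$sprev <- st$slast
      st$slast <- obs$state
      st
    },
    policy = function(state, params) {
      qnet <- c(0, 0)
      if (mf) qnet <- qnet + params[["g_mf"]] * state$qmf
      if (mo) qnet <- qnet + params[["g_mo"]] * state$qmo[state$slast + 1L, ]
      if (mb) {
        trans <- rbind(c(state$p[1], 1 - state$p[1]),
                       c(state$p[2], 1 - state$p[2]))
        qnet <- qnet + params[["g_mb"]] * as.numeric(trans %*% state$v)
      }
      xs <- if (state$slast == 0L) -0.5 else 0.5
      x2 <- params[["bias_c"]] + params[["bias_r"]] * xs +
        params[["p_c"]] * state$xcp
      if (multi_mocp) x2 <- x2 + params[["p_m"]] * state$xmocp[state$slast + 1L]
      softmax_policy(qnet + c(0, x2), 1)
    }
  )
}

## --- n-armed model-free family (human tasks) --------------------------------
## Continuous rewards are rescaled to [0, 1] before entering update rules;
## the policy's inverse temperature absorbs the scale.
model_mfn <- function(cfg, forget, pers) {
  n <- cfg$n_actions
  rscale <- cfg$reward_range[2]
  par <- rbind(par_def("alpha", "rate"), par_def("beta", "temp"))
  if (forget) par <- rbind(par, par_def("D", "rate"))
  if (pers) par <- rbind(par, par_def("D_pers", "rate"),
                         par_def("k_pers", "real"))
  list(
    family = "mf", d = as.integer(if (pers) 2L * n else n), n_actions = n,
    par = par,
    init = function(params) list(q = rep(0, n), x = rep(0, n)),
    step = function(state, obs, params) {
      a <- obs$action + 1L
      r <- obs$reward / rscale
      q <- state$q; x <- state$x
      q[a] <- q[a] + params[["alpha"]] * (r - q[a])
      if (forget) q[-a] <- params[["D"]] * q[-a]
      if (pers) {
        x[a] <- params[["D_pers"]] * x[a] + params[["k_pers"]]
        x[-a] <- params[["D_pers"]] * x[-a]
      }
      list(q = q, x = x)
    },
    policy = function(state, params)
      softmax_policy(state$q + state$x, params[["beta"]])
  )
}

## --- n-armed model-free with unchosen updating and reward utilities --------
model_mfn_utility <- function(cfg) {
  n <- cfg$n_actions
  list(
    family = "mf", d = as.integer(n), n_actions = n,
    par = rbind(par_def("alpha_c", "rate"), par_def("alpha_u", "rate"),
                par_def("u_c0", "real"), par_def("u_c1", "real"),
                par_def("u_u0", "real"), par_def("u_u1", "real"),
                par_def("beta", "temp")),
    init = function(params) list(q = rep(0, n)),
    step = function(state, obs, params) {
      a <- obs$action + 1L
      rew <- obs$reward > 0.5
      uc <- if (rew) params[["u_c1"]] else params[["u_c0"]]
      uu <- if (rew) params[["u_u1"]] else params[["u_u0"]]
      q <- state$q
      q[a] <- q[a] + params[["alpha_c"]] * (uc - q[a])
      q[-a] <- q[-a] + params[["alpha_u"]] * (uu - q[-a])
      list(q = q)
    },
    policy = function(state, params)
      softmax_policy(state$q, params[["beta"]])
  )
}

## --- n-armed model-free with reward reference points (drifting bandit) -----
model_mfn_refpoint <- function(cfg, reduced) {
  n <- cfg$n_actions
  rscale <- cfg$reward_range[2]
  par <- rbind(par_def("alpha_c", "rate"), par_def("alpha_u", "rate"),
               par_def("r_c", "real"), par_def("r_u", "real"),
               par_def("beta", "temp"))
  if (!reduced) par <- rbind(par, par_def("beta_c", "temp"),
                             par_def("beta_u", "temp"))
  list(
    family = "mf", d = as.integer(n), n_actions = n, par = par,
    init = function(params) list(q = rep(0, n)),
    step = function(state, obs, params) {
      a <- obs$action + 1L
      r <- obs$reward / rscale
      bc <- if (reduced) params[["alpha_c"]] else params[["beta_c"]]
      bu <- if (reduced) params[["alpha_u"]] else params[["beta_u"]]
      q <- state$q
      q[a] <- (1 - params[["alpha_c"]]) * q[a] + bc * (r - params[["r_c"]])
      q[-a] <- (1 - params[["alpha_u"]]) * q[-a] + bu * (r - params[["r_u"]])
      list(q = q)
    },
    policy = function(state, params)
      softmax_policy(state$q, params[["beta"]])
  )
}

## --- Original two-stage task ------------------------------------------------
## Values per choice state: first stage q0 (A1/A2), second stages q1 (B1/B2
## at S1) and q2 (C1/C2 at S2). In the anticorrelated variants each state is
## summarized by the value of its first action. `kind`: "mf" (TD-lambda
## first stage), "mb" (max-rule first stage), "mix" (weighted
## combination).
model_ots <- function(cfg, kind, anticorr) {
  trans <- cfg$transitions
  par <- rbind(par_def("alpha2", "rate"), par_def("beta1", "temp"),
               par_def("beta2", "temp"))
  if (kind %in% c("mf", "mix"))
    par <- rbind(par, par_def("alpha1", "rate"), par_def("lambda", "rate"))
  if (kind == "mix") par <- rbind(par, par_def("w", "rate"))
  d <- switch(kind,
              mf = if (anticorr) 3L else 6L,
              mb = if (anticorr) 2L else 4L,
              mix = if (anticorr) 3L else 6L)
  list(
    family = paste0("ots_", kind), d = d, n_actions = 2L, par = par,
    init = function(params) list(q0 = c(0, 0), qs = matrix(0, 2L, 2L)),
    step = function(state, obs, params) {
      a <- obs$action + 1L; ua <- 3L - a
      s <- obs$state + 1L
      a2 <- obs$action2 + 1L; ua2 <- 3L - a2
      r <- obs$reward
      a2l <- params[["alpha2"]]
      q0 <- state$q0; qs <- state$qs
      qs[s, a2] <- qs[s, a2] + a2l * (r - qs[s, a2])
      if (anticorr) qs[s, ua2] <- qs[s, ua2] - a2l * (r + qs[s, ua2])
      if (kind %in% c("mf", "mix")) {
        a1l <- params[["alpha1"]]; lam <- params[["lambda"]]
        tgt <- lam * r + (1 - lam) * qs[s, a2]   # updated second-stage value
        q0[a] <- q0[a] + a1l * (tgt - q0[a])
        if (anticorr) q0[ua] <- q0[ua] - a1l * (tgt + q0[ua])
      }
      list(q0 = q0, qs = qs)
    },
    policy = function(state, params) {
      qmb <- as.numeric(trans %*% apply(state$qs, 1L, max))
      q1 <- switch(kind,
                   mf = state$q0,
                   mb = qmb,
                   mix = (1 - params[["w"]]) * state$q0 + params[["w"]] * qmb)
      softmax_policy(q1, params[["beta1"]])
    },
    policy2 = function(state, params, state_code)
      softmax_policy(state$qs[state_code + 1L, ], params[["beta2"]])
  )
}

## --- Original two-stage task, reward-utility variant (d = 3) ---------------
## Anticorrelated values at every choice state; rewards move the chosen
## first-stage and second-stage values toward utility setpoints, and the
## motor twin of the chosen second-stage action at the *unchosen* state
## moves toward +-u_other.
model_ots_utility <- function(cfg) {
  list(
    family = "ots_utility", d = 3L, n_actions = 2L,
    par = rbind(par_def("alpha1", "rate"), par_def("alpha2", "rate"),
                par_def("u_other", "real"), par_def("u_1st_zero", "real"),
                par_def("u_2nd_zero", "real"),
                par_def("beta1", "temp"), par_def("beta2", "temp")),
    ## scalar value of the first action at each state (anticorrelation)
    init = function(params) list(q = c(0, 0, 0)),  # S0, S1, S2
    step = function(state, obs, params) {
      rew <- obs$reward > 0.5
      a1 <- obs$action          # 0/1 at S0
      s <- obs$state            # 0 -> S1, 1 -> S2
      a2 <- obs$action2         # 0/1 at the visited state
      q <- state$q
      u0 <- if (rew) 1 else params[["u_1st_zero"]]
      u2 <- if (rew) 1 else params[["u_2nd_zero"]]
      uo <- if (rew) params[["u_other"]] else -params[["u_other"]]
      upd_anti <- function(v, chosen_first, alpha, u) {
        ## v is the value of the state's first action; updating the second
        ## action is the mirrored update of -v
        if (chosen_first) v + alpha * (u - v) else -((-v) + alpha * (u + v))
      }
      q[1] <- upd_anti(q[1], a1 == 0L, params[["alpha1"]], u0)
      vis <- s + 2L; unv <- (1L - s) + 2L
      q[vis] <- upd_anti(q[vis], a2 == 0L, params[["alpha2"]], u2)
      q[unv] <- upd_anti(q[unv], a2 == 0L, params[["alpha2"]], uo)
      list(q = q)
    },
    policy = function(state, params)
      softmax_policy(c(state$q[1], -state$q[1]), params[["beta1"]]),
    policy2 = function(state, params, state_code) {
      v <- state$q[state_code + 2L]
      softmax_policy(c(v, -v), params[["beta2"]])
    }
  )
}
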