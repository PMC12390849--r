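## Literal reference implementations of every cognitive model's defining
## update equations, written as plain per-trial loops independent of the
## package's model registry. Used as the oracle in equivalence tests.
## Conventions shared with the package (documented initial conditions):
## values and traces start at 0, beliefs and transition estimates at 0.5,
## the reward-as-cue augmented state starts at (S1, r = 0), and the
## motor-context states s_{t-1}, s_{t-2} start at S1.

ref_softmax <- function(s, beta = 1) {
  e <- exp(beta * s - max(beta * s))
  e / sum(e)
}

## dispatch on the catalogue id
reference_policies <- function(id, params, data, cfg) {
  a <- data$action + 1L
  s <- data$state + 1L
  r <- data$reward
  n <- nrow(data)
  p <- params
  switch(id,
    bayes = {
      b <- 0.5
      P <- matrix(NA, n, 2)
      for (t in 1:n) {
        P[t, ] <- ref_softmax(c(b, 1 - b), p["beta"])
        l1 <- if (s[t] == 1) { if (r[t] == 1) p["p_emit"] else 1 - p["p_emit"] }
              else { if (r[t] == 1) 1 - p["p_emit"] else p["p_emit"] }
        l2 <- if (s[t] == 2) { if (r[t] == 1) p["p_emit"] else 1 - p["p_emit"] }
              else { if (r[t] == 1) 1 - p["p_emit"] else p["p_emit"] }
        post <- l1 * b / (l1 * b + l2 * (1 - b))
        b <- (1 - p["p_r"]) * post + p["p_r"] * (1 - post)
      }
      P
    },
    mf1 = {
      q <- c(0, 0); P <- matrix(NA, n, 2)
      for (t in 1:n) {
        P[t, ] <- ref_softmax(q, p["beta"])
        c_ <- a[t]; u <- 3 - a[t]
        q[c_] <- q[c_] + p["alpha"] * (r[t] - q[c_])
        q[u] <- q[u] - p["alpha"] * (r[t] + q[u])
      }
      P
    },
    mf2 = ref_mf2(a, r, n, p, mode = "none"),
    mf2_forget = ref_mf2(a, r, n, p, mode = "zero"),
    mf2_forget_mean = ref_mf2(a, r, n, p, mode = "mean"),
    mf2_dtto = {
      q <- c(0, 0); P <- matrix(NA, n, 2)
      for (t in 1:n) {
        P[t, ] <- ref_softmax(q, p["beta"])
        c_ <- a[t]; u <- 3 - a[t]
        if (r[t] == 1) {
          q[c_] <- p["D1"] * q[c_] + 1
          q[u] <- q[u] - p["b"]
        } else {
          q[c_] <- q[c_] + p["alpha0"] * (q[u] - q[c_])
        }
      }
      P
    },
    mf1_inertia = ref_inertia(a, r, n, p, independent = FALSE),
    mf2_inertia = ref_inertia(a, r, n, p, independent = TRUE),
    rac8 = {
      q <- matrix(0, 4, 2)          # rows: augmented state (s, r)
      aug <- 1                      # (S1, r = 0) before any outcome
      P <- matrix(NA, n, 2)
      for (t in 1:n) {
        P[t, ] <- ref_softmax(q[aug, ], p["beta"])
        q[aug, a[t]] <- q[aug, a[t]] + p["alpha"] * (r[t] - q[aug, a[t]])
        aug <- (s[t] - 1) * 2 + r[t] + 1
      }
      P
    },
    mfq0 = {
      q <- c(0, 0); v <- c(0, 0); P <- matrix(NA, n, 2)
      for (t in 1:n) {
        P[t, ] <- ref_softmax(q, p["beta"])
        q[a[t]] <- q[a[t]] + p["alpha"] * (v[s[t]] - q[a[t]])
        v[s[t]] <- v[s[t]] + p["alpha"] * (r[t] - v[s[t]])
      }
      P
    },
    mb1 = {
      v <- c(0, 0); P <- matrix(NA, n, 2); Tr <- cfg$transitions
      for (t in 1:n) {
        P[t, ] <- ref_softmax(as.numeric(Tr %*% v), p["beta"])
        vi <- s[t]; u <- 3 - s[t]
        v[vi] <- v[vi] + p["alpha"] * (r[t] - v[vi])
        v[u] <- v[u] - p["alpha"] * (r[t] + v[u])
      }
      P
    },
    mb2 = ref_mb2(s, r, n, p, cfg, forget = FALSE),
    mb2_forget = ref_mb2(s, r, n, p, cfg, forget = TRUE),
    mb_mix = {
      q <- c(0, 0); v <- c(0, 0); P <- matrix(NA, n, 2); Tr <- cfg$transitions
      for (t in 1:n) {
        qnet <- (1 - p["w"]) * q + p["w"] * as.numeric(Tr %*% v)
        P[t, ] <- ref_softmax(qnet, p["beta"])
        c_ <- a[t]; ua <- 3 - a[t]; vi <- s[t]; uv <- 3 - s[t]
        q[c_] <- q[c_] + p["alpha_mf"] * (r[t] - q[c_])
        q[ua] <- q[ua] - p["alpha_mf"] * (r[t] + q[ua])
        v[vi] <- v[vi] + p["alpha_mb"] * (r[t] - v[vi])
        v[uv] <- v[uv] - p["alpha_mb"] * (r[t] + v[uv])
      }
      P
    },
    akam_mf = ref_akam(a, s, r, n, p, mf = TRUE),
    akam_mf_forget = ref_akam(a, s, r, n, p, mf = TRUE, fq = TRUE),
    akam_mf_full = ref_akam(a, s, r, n, p, mf = TRUE, fq = TRUE, mo = TRUE,
                            mcp = TRUE, mmo = TRUE),
    akam_mb = ref_akam(a, s, r, n, p, mb = TRUE),
    akam_mb_forget = ref_akam(a, s, r, n, p, mb = TRUE, fq = TRUE, ft = TRUE),
    akam_mb_mf = ref_akam(a, s, r, n, p, mf = TRUE, mb = TRUE),
    akam_mb_full = ref_akam(a, s, r, n, p, mf = TRUE, mb = TRUE, mo = TRUE,
                            fq = TRUE, ft = TRUE, mcp = TRUE, mmo = TRUE),
    mf3_basic = ref_mfn(a, r / cfg$reward_range[2], n, p, cfg$n_actions,
                        forget = FALSE, pers = FALSE),
    mf3_forget = ref_mfn(a, r / cfg$reward_range[2], n, p, cfg$n_actions,
                         forget = TRUE, pers = FALSE),
    mf3_forget_pers = ref_mfn(a, r / cfg$reward_range[2], n, p,
                              cfg$n_actions, forget = TRUE, pers = TRUE),
    mf3_utility = {
      na <- cfg$n_actions; q <- rep(0, na); P <- matrix(NA, n, na)
      for (t in 1:n) {
        P[t, ] <- ref_softmax(q, p["beta"])
        uc <- if (r[t] == 1) p["u_c1"] else p["u_c0"]
        uu <- if (r[t] == 1) p["u_u1"] else p["u_u0"]
        for (j in 1:na) {
          if (j == a[t]) q[j] <- q[j] + p["alpha_c"] * (uc - q[j])
          else q[j] <- q[j] + p["alpha_u"] * (uu - q[j])
        }
      }
      P
    },
    mf4_basic = ref_mfn(a, r / cfg$reward_range[2], n, p, cfg$n_actions,
                        forget = FALSE, pers = FALSE),
    mf4_forget = ref_mfn(a, r / cfg$reward_range[2], n, p, cfg$n_actions,
                         forget = TRUE, pers = FALSE),
    mf4_forget_pers = ref_mfn(a, r / cfg$reward_range[2], n, p,
                              cfg$n_actions, forget = TRUE, pers = TRUE),
    mf4_refpoint = ref_refpoint(a, r / cfg$reward_range[2], n, p,
                                cfg$n_actions, reduced = FALSE),
    mf4_refpoint_reduced = ref_refpoint(a, r / cfg$reward_range[2], n, p,
                                        cfg$n_actions, reduced = TRUE),
    ots_mf3 = ref_ots(data, p, cfg, kind = "mf", anticorr = TRUE),
    ots_mf6 = ref_ots(data, p, cfg, kind = "mf", anticorr = FALSE),
    ots_mb2 = ref_ots(data, p, cfg, kind = "mb", anticorr = TRUE),
    ots_mb4 = ref_ots(data, p, cfg, kind = "mb", anticorr = FALSE),
    ots_mix3 = ref_ots(data, p, cfg, kind = "mix", anticorr = TRUE),
    ots_mix6 = ref_ots(data, p, cfg, kind = "mix", anticorr = FALSE),
    ots_utility3 = ref_ots_utility(data, p, cfg),
    stop("no reference for ", id)
  )
}

ref_mf2 <- function(a, r, n, p, mode) {
  q <- c(0, 0); P <- matrix(NA, n, 2)
  for (t in 1:n) {
    P[t, ] <- ref_softmax(q, p["beta"])
    c_ <- a[t]; u <- 3 - a[t]
    q[c_] <- q[c_] + p["alpha"] * (r[t] - q[c_])
    if (mode == "zero") q[u] <- p["D"] * q[u]
    if (mode == "mean") q[u] <- p["D"] * q[u] + (1 - p["D"]) * 0.5
  }
  P
}

ref_inertia <- function(a, r, n, p, independent) {
  q <- c(0, 0); x <- c(0, 0); P <- matrix(NA, n, 2)
  for (t in 1:n) {
    P[t, ] <- ref_softmax(q + x, p["beta"])
    c_ <- a[t]; u <- 3 - a[t]
    q[c_] <- q[c_] + p["alpha"] * (r[t] - q[c_])
    if (!independent) q[u] <- q[u] - p["alpha"] * (r[t] + q[u])
    x[c_] <- x[c_] + p["alpha_pers"] * (p["k_pers"] - x[c_])
    x[u] <- x[u] - p["alpha_pers"] * (p["k_pers"] + x[u])
  }
  P
}

ref_mb2 <- function(s, r, n, p, cfg, forget) {
  v <- c(0, 0); P <- matrix(NA, n, 2); Tr <- cfg$transitions
  for (t in 1:n) {
    P[t, ] <- ref_softmax(as.numeric(Tr %*% v), p["beta"])
    vi <- s[t]; u <- 3 - s[t]
    v[vi] <- v[vi] + p["alpha"] * (r[t] - v[vi])
    if (forget) v[u] <- p["D"] * v[u]
  }
  P
}

ref_mfn <- function(a, r, n, p, na, forget, pers) {
  q <- rep(0, na); x <- rep(0, na); P <- matrix(NA, n, na)
  for (t in 1:n) {
    P[t, ] <- ref_softmax(q + x, p["beta"])
    q[a[t]] <- q[a[t]] + p["alpha"] * (r[t] - q[a[t]])
    if (forget) for (j in setdiff(1:na, a[t])) q[j] <- p["D"] * q[j]
    if (pers) {
      x[a[t]] <- p["D_pers"] * x[a[t]] + p["k_pers"]
      for (j in setdiff(1:na, a[t])) x[j] <- p["D_pers"] * x[j]
    }
  }
  P
}

ref_refpoint <- function(a, r, n, p, na, reduced) {
  q <- rep(0, na); P <- matrix(NA, n, na)
  bc <- if (reduced) p["alpha_c"] else p["beta_c"]
  bu <- if (reduced) p["alpha_u"] else p["beta_u"]
  for (t in 1:n) {
    P[t, ] <- ref_softmax(q, p["beta"])
    for (j in 1:na) {
      if (j == a[t]) q[j] <- (1 - p["alpha_c"]) * q[j] + bc * (r[t] - p["r_c"])
      else q[j] <- (1 - p["alpha_u"]) * q[j] + bu * (r[t] - p["r_u"])
    }
  }
  P
}

## transition-reversal two-stage component models
ref_akam <- function(a, s, r, n, p, mf = FALSE, mo = FALSE, mb = FALSE,
                     fq = FALSE, ft = FALSE, mcp = FALSE, mmo = FALSE) {
  v <- c(0, 0); qmf <- c(0, 0)
  pt <- c(0.5, 0.5)                  # P(S1 | A1), P(S1 | A2)
  qmo <- matrix(0, 2, 2)             # previous-state x action
  xcp <- 0; xmocp <- c(0, 0)
  slast <- 1; sprev <- 1
  P <- matrix(NA, n, 2)
  for (t in 1:n) {
    qnet <- c(0, 0)
    if (mf) qnet <- qnet + p["g_mf"] * qmf
    if (mo) qnet <- qnet + p["g_mo"] * qmo[slast, ]
    if (mb) {
      Tr <- rbind(c(pt[1], 1 - pt[1]), c(pt[2], 1 - pt[2]))
      qnet <- qnet + p["g_mb"] * as.numeric(Tr %*% v)
    }
    xs <- if (slast == 1) -0.5 else 0.5
    x2 <- p["bias_c"] + p["bias_r"] * xs + p["p_c"] * xcp
    if (mmo) x2 <- x2 + p["p_m"] * xmocp[slast]
    P[t, ] <- ref_softmax(qnet + c(0, x2), 1)
    ## updates
    xt <- if (a[t] == 1) -0.5 else 0.5
    c_ <- a[t]; ua <- 3 - a[t]; vi <- s[t]; uv <- 3 - s[t]
    if (mf) {
      tgt <- p["lambda"] * r[t] + (1 - p["lambda"]) * v[vi]
      qmf[c_] <- qmf[c_] + p["alpha"] * (tgt - qmf[c_])
      if (fq) qmf[ua] <- (1 - p["f_q"]) * qmf[ua]
    }
    if (mo) {
      tgt <- p["lambda"] * r[t] + (1 - p["lambda"]) * v[sprev]
      qmo[sprev, c_] <- qmo[sprev, c_] + p["alpha"] * (tgt - qmo[sprev, c_])
      if (fq) {
        for (ss in 1:2) for (aa in 1:2)
          if (!(ss == sprev && aa == c_))
            qmo[ss, aa] <- (1 - p["f_q"]) * qmo[ss, aa]
      }
    }
    if (mb) {
      o1 <- as.numeric(vi == 1)
      pt[c_] <- pt[c_] + p["alpha_t"] * (o1 - pt[c_])
      if (ft) pt[ua] <- pt[ua] + p["f_t"] * (0.5 - pt[ua])
    }
    v[vi] <- v[vi] + p["alpha_q"] * (r[t] - v[vi])
    if (fq) v[uv] <- (1 - p["f_q"]) * v[uv]
    if (mcp) xcp <- xcp + p["alpha_c"] * (xt - xcp) else xcp <- xt
    if (mmo) xmocp[sprev] <- xmocp[sprev] + p["alpha_m"] * (xt - xmocp[sprev])
    sprev <- slast; slast <- vi
  }
  P
}

## original two-stage task families; returns list(p1, p2)
ref_ots <- function(data, p, cfg, kind, anticorr) {
  a <- data$action + 1L; s <- data$state + 1L
  a2 <- data$action2 + 1L; r <- data$reward
  n <- nrow(data); Tr <- cfg$transitions
  q0 <- c(0, 0); qs <- matrix(0, 2, 2)
  P1 <- matrix(NA, n, 2); P2 <- matrix(NA, n, 2)
  for (t in 1:n) {
    qmb <- as.numeric(Tr %*% c(max(qs[1, ]), max(qs[2, ])))
    first <- switch(kind, mf = q0, mb = qmb,
                    mix = (1 - p["w"]) * q0 + p["w"] * qmb)
    P1[t, ] <- ref_softmax(first, p["beta1"])
    P2[t, ] <- ref_softmax(qs[s[t], ], p["beta2"])
    c2 <- a2[t]; u2 <- 3 - a2[t]
    qs[s[t], c2] <- qs[s[t], c2] + p["alpha2"] * (r[t] - qs[s[t], c2])
    if (anticorr)
      qs[s[t], u2] <- qs[s[t], u2] - p["alpha2"] * (r[t] + qs[s[t], u2])
    if (kind %in% c("mf", "mix")) {
      tgt <- p["lambda"] * r[t] + (1 - p["lambda"]) * qs[s[t], c2]
      c1 <- a[t]; u1 <- 3 - a[t]
      q0[c1] <- q0[c1] + p["alpha1"] * (tgt - q0[c1])
      if (anticorr) q0[u1] <- q0[u1] - p["alpha1"] * (tgt + q0[u1])
    }
  }
  list(p1 = P1, p2 = P2)
}

ref_ots_utility <- function(data, p, cfg) {
  a <- data$action; s <- data$state; a2 <- data$action2; r <- data$reward
  n <- nrow(data)
  q <- c(0, 0, 0)   # value of the first action at S0, S1, S2
  P1 <- matrix(NA, n, 2); P2 <- matrix(NA, n, 2)
  for (t in 1:n) {
    P1[t, ] <- ref_softmax(c(q[1], -q[1]), p["beta1"])
    v <- q[s[t] + 2]
    P2[t, ] <- ref_softmax(c(v, -v), p["beta2"])
    rew <- r[t] == 1
    u0 <- if (rew) 1 else p["u_1st_zero"]
    u2 <- if (rew) 1 else p["u_2nd_zero"]
    uo <- if (rew) p["u_other"] else -p["u_other"]
    upd <- function(v, first, alpha, u)
      if (first) v + alpha * (u - v) else -((-v) + alpha * (u + v))
    q[1] <- upd(q[1], a[t] == 0, p["alpha1"], u0)
    vis <- s[t] + 2; unv <- (1 - s[t]) + 2
    q[vis] <- upd(q[vis], a2[t] == 0, p["alpha2"], u2)
    q[unv] <- upd(q[unv], a2[t] == 0, p["alpha2"], uo)
  }
  list(p1 = P1, p2 = P2)
}
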