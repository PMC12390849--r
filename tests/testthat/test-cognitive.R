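cfg2 <- task_config("two_stage")
cfgr <- task_config("reversal")

## one update of a model from a given dynamical state
step1 <- function(id, cfg, state, obs, params) {
  m <- cognitive_model(id, cfg)
  m$step(state, obs, params)
}

test_that("softmax policy matches closed forms and is shift invariant", {
  expect_equal(softmax_policy(c(3, 7), beta = 0), c(0.5, 0.5))
  expect_equal(softmax_policy(c(1, 0), beta = log(3)), c(0.75, 0.25))
  p1 <- softmax_policy(c(0.3, -1, 2), beta = 1.7)
  p2 <- softmax_policy(c(0.3, -1, 2) + 11.3, beta = 1.7)
  expect_equal(p1, p2)
  expect_equal(sum(p1), 1)
  expect_error(softmax_policy(c(1, Inf)), "non-finite")
})

test_that("belief updates follow Bayes' rule with switch mixing", {
  p <- c(p_emit = 0.8, p_r = 0.1, beta = 1)
  ## reward observed in S1: posterior 0.8, mixed to 0.74
  st <- step1("bayes", cfgr, list(b = 0.5),
              list(action = 0L, state = 0L, reward = 1), p)
  expect_equal(st$b, 0.8 * 0.9 + 0.2 * 0.1)
  ## uninformative emission leaves the belief at 0.5
  st <- step1("bayes", cfgr, list(b = 0.5),
              list(action = 0L, state = 0L, reward = 1),
              c(p_emit = 0.5, p_r = 0.1, beta = 1))
  expect_equal(st$b, 0.5)
  ## p_r = 0.5 fully mixes any posterior back to 0.5
  st <- step1("bayes", cfgr, list(b = 0.9),
              list(action = 0L, state = 0L, reward = 1),
              c(p_emit = 0.8, p_r = 0.5, beta = 1))
  expect_equal(st$b, 0.5)
  ## deterministic emission pins the belief after one observation
  st <- step1("bayes", cfgr, list(b = 0.5),
              list(action = 0L, state = 0L, reward = 1),
              c(p_emit = 1, p_r = 0, beta = 1))
  expect_equal(st$b, 1)
})

test_that("anticorrelated and independent value updates match the equations", {
  obs <- list(action = 0L, state = 0L, reward = 1)
  st <- step1("mf1", cfgr, list(q = c(0, 0)), obs, c(alpha = 0.5, beta = 1))
  expect_equal(st$q, c(0.5, -0.5))
  st <- step1("mf1", cfgr, list(q = c(0.3, -0.3)), obs,
              c(alpha = 0, beta = 1))
  expect_equal(st$q, c(0.3, -0.3))                      # frozen learning
  ## independent values, the three forgetting modes
  obs0 <- list(action = 0L, state = 0L, reward = 0)
  st <- step1("mf2", cfg2, list(q = c(1, 1)), obs0, c(alpha = 1, beta = 1))
  expect_equal(st$q, c(0, 1))
  st <- step1("mf2_forget", cfg2, list(q = c(0, 1)), obs0,
              c(alpha = 0.5, D = 0.9, beta = 1))
  expect_equal(st$q[2], 0.9)
  st <- step1("mf2_forget_mean", cfg2, list(q = c(0, 4)), obs0,
              c(alpha = 0.5, D = 0, beta = 1))
  expect_equal(st$q[2], 0.5)                            # full decay to 1/2
})

test_that("drift-to-the-other updates match the defining rule", {
  p <- c(D1 = 0.5, b = 0.1, alpha0 = 0.5, beta = 1)
  st <- step1("mf2_dtto", cfgr, list(q = c(1, 0)),
              list(action = 0L, state = 0L, reward = 0), p)
  expect_equal(st$q, c(0.5, 0))        # unrewarded: drift to the other
  st <- step1("mf2_dtto", cfgr, list(q = c(0, 0)),
              list(action = 0L, state = 0L, reward = 1), p)
  expect_equal(st$q, c(1, -0.1))       # rewarded: D1 q + 1 and -b
  st <- step1("mf2_dtto", cfgr, list(q = c(0.8, 0.2)),
              list(action = 0L, state = 0L, reward = 0),
              c(D1 = 0.5, b = 0.1, alpha0 = 1, beta = 1))
  expect_equal(st$q[1], st$q[2])       # complete drift
})

test_that("perseveration traces move toward +-k_pers", {
  p <- c(alpha = 0.5, beta = 1, alpha_pers = 1, k_pers = 1)
  st <- step1("mf1_inertia", cfgr, list(q = c(0, 0), x = c(0, 0)),
              list(action = 0L, state = 0L, reward = 0), p)
  expect_equal(st$x, c(1, -1))
  p0 <- c(alpha = 0.5, beta = 1, alpha_pers = 0, k_pers = 1)
  st <- step1("mf1_inertia", cfgr, list(q = c(0, 0), x = c(0.4, -0.4)),
              list(action = 1L, state = 1L, reward = 0), p0)
  expect_equal(st$x, c(0.4, -0.4))     # frozen trace
})

test_that("reward-as-cue updates exactly one augmented-state slot", {
  p <- c(alpha = 0.5, beta = 1)
  m <- cognitive_model("rac8", cfg2)
  st <- m$init(p)
  st2 <- m$step(st, list(action = 0L, state = 1L, reward = 1), p)
  expect_equal(sum(st2$q != 0), 1L)
  expect_equal(st2$q[st$aug, 1], 0.5)
  expect_equal(st2$aug, 1L + 1L * 2L + 1L)   # new cue (S2, r = 1)
  ## four rewarded updates under four distinct cues -> four nonzero slots
  st <- m$init(p); seen <- list(c(0L,0L,1), c(0L,1L,1), c(1L,0L,1), c(1L,1L,1))
  for (o in seen)
    st <- m$step(st, list(action = o[1], state = o[2], reward = o[3]), p)
  expect_equal(sum(st$q != 0), 4L)
  st0 <- m$step(m$init(p), list(action = 0L, state = 0L, reward = 1),
                c(alpha = 0, beta = 1))
  expect_true(all(st0$q == 0))
})

test_that("model-based values go through the transition matrix", {
  m <- cognitive_model("mb1", cfg2)
  p <- c(alpha = 0.5, beta = 1)
  pol <- m$policy(list(v = c(1, -1)), p)
  ## Q_mb = (0.6, -0.6) under 0.8/0.2 transitions
  expect_equal(pol, softmax_policy(c(0.6, -0.6), 1))
  ## learned transitions: alpha_T = 1 pins the visited row
  ma <- cognitive_model("akam_mb", task_config("transition_reversal"))
  pp <- c(alpha_q = 0.5, bias_c = 0, bias_r = 0, p_c = 0, alpha_t = 1,
          g_mb = 1)
  st <- ma$step(ma$init(pp), list(action = 0L, state = 0L, reward = 1), pp)
  expect_equal(st$p[1], 1)
  ## f_t = 1 resets the unchosen action's row to 0.5
  pf <- c(pp, f_q = 0, f_t = 1)
  mf <- cognitive_model("akam_mb_forget", task_config("transition_reversal"))
  st <- mf$init(pf); st$p <- c(0.9, 0.9)
  st <- mf$step(st, list(action = 0L, state = 0L, reward = 1), pf)
  expect_equal(st$p[2], 0.5)
})

test_that("net action values assemble bias, rotation and perseveration", {
  cfgt <- task_config("transition_reversal")
  m <- cognitive_model("akam_mf", cfgt)
  ## all gains zero except a pure constant bias
  p <- c(alpha_q = 0.5, bias_c = 1, bias_r = 0, p_c = 0, alpha = 0.5,
         lambda = 0.5, g_mf = 0)
  pol <- m$policy(m$init(p), p)
  expect_equal(log(pol[2] / pol[1]), 1)     # score difference A2 - A1 = B_c
  p0 <- c(alpha_q = 0.5, bias_c = 0, bias_r = 0, p_c = 0, alpha = 0.5,
          lambda = 0.5, g_mf = 0)
  expect_equal(m$policy(m$init(p0), p0), c(0.5, 0.5))   # null mixture
  ## lambda = 1: the first-stage update is driven by the reward only
  p1 <- c(alpha_q = 0, bias_c = 0, bias_r = 0, p_c = 0, alpha = 1,
          lambda = 1, g_mf = 1)
  st <- m$init(p1); st$v <- c(5, 5)
  st <- m$step(st, list(action = 0L, state = 0L, reward = 1), p1)
  expect_equal(st$qmf[1], 1)               # target is r, not V
})

test_that("human bandit variants follow their utility rules", {
  cfg3 <- task_config("reversal3")
  m <- cognitive_model("mf3_utility", cfg3)
  p <- c(alpha_c = 0.5, alpha_u = 0, u_c0 = 0, u_c1 = 2, u_u0 = 0, u_u1 = 0,
         beta = 1)
  st <- m$step(m$init(p), list(action = 0L, state = 0L, reward = 1), p)
  expect_equal(st$q, c(1, 0, 0))           # alpha_u = 0 freezes unchosen
  ## reference-point variant: r = R_c keeps a zero chosen value at zero
  cfg4 <- task_config("bandit4")
  mr <- cognitive_model("mf4_refpoint", cfg4)
  pr <- c(alpha_c = 0.7, alpha_u = 0.2, r_c = 0.62, r_u = 0.3, beta = 1,
          beta_c = 1, beta_u = 0)
  st <- mr$step(mr$init(pr), list(action = 1L, state = 1L, reward = 62), pr)
  expect_equal(st$q[2], 0)
})

test_that("original two-stage models implement the max rule and mixtures", {
  cfgo <- task_config("two_stage_original")
  m <- cognitive_model("ots_mb2", cfgo)
  p <- c(alpha2 = 0.5, beta1 = 1, beta2 = 1)
  st <- m$init(p); st$qs <- rbind(c(1, 0), c(0, -1))
  pol <- m$policy(st, p)
  ## Q_mb(A1) = 0.7 * max(S1) + 0.3 * max(S2) = 0.7
  expect_equal(log(pol[1] / pol[2]), (0.7 * 1 + 0.3 * 0) -
                                     (0.3 * 1 + 0.7 * 0))
  ## w = 0 collapses the mixture to pure model-free values
  mx <- cognitive_model("ots_mix3", cfgo)
  pm <- c(alpha2 = 0.5, beta1 = 2, beta2 = 1, alpha1 = 0.5, lambda = 0.5,
          w = 0)
  st <- mx$init(pm); st$q0 <- c(0.4, -0.4); st$qs <- rbind(c(1, 0), c(0, 0))
  expect_equal(mx$policy(st, pm), softmax_policy(c(0.4, -0.4), 2))
  ## utility variant: motor twin at the unchosen state moves toward U_other
  mu <- cognitive_model("ots_utility3", cfgo)
  pu <- c(alpha1 = 0.5, alpha2 = 0.5, u_other = 0.8, u_1st_zero = 0,
          u_2nd_zero = 0, beta1 = 1, beta2 = 1)
  st <- mu$step(mu$init(pu), list(action = 0L, state = 0L, action2 = 0L,
                                  reward = 1), pu)
  expect_equal(st$q[3], 0.5 * 0.8)         # C1 at unchosen S2 -> U_other
})

test_that("anticorrelated models keep Q(A1) + Q(A2) = 0 over long runs", {
  set.seed(42)
  m <- cognitive_model("mf1", cfgr)
  p <- c(alpha = 0.37, beta = 2)
  st <- m$init(p)
  worst <- 0
  for (t in 1:10000) {
    st <- m$step(st, list(action = sample(0:1, 1), state = 0L,
                          reward = sample(0:1, 1)), p)
    worst <- max(worst, abs(sum(st$q)))
  }
  expect_lt(worst, 1e-12)
})

test_that("values stay bounded by the reward magnitude", {
  set.seed(7)
  for (id in c("mf1", "mf2", "mf2_forget")) {
    m <- cognitive_model(id, cfg2)
    p <- random_params(m, seed = 11)
    st <- m$init(p)
    for (t in 1:2000) {
      st <- m$step(st, list(action = sample(0:1, 1),
                            state = sample(0:1, 1),
                            reward = sample(0:1, 1)), p)
      expect_true(all(abs(st$q) <= 1 + 1e-12))
    }
  }
})

test_that("declared dynamical-variable counts match the catalogue", {
  tab <- cognitive_catalogue()
  expect_equal(tab$d[tab$id == "rac8"], 8L)
  expect_equal(tab$d[tab$id == "akam_mb_full"], 13L)
  expect_equal(tab$d[tab$id == "akam_mf_full"], 11L)
  expect_equal(tab$d[tab$id == "mf3_forget_pers"], 6L)
  expect_equal(tab$d[tab$id == "ots_mix6"], 6L)
})
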