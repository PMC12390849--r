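cfgr <- task_config("reversal")
cfg2 <- task_config("two_stage")

test_that("logits are the log odds and inherit softmax shift invariance", {
  tr <- structure(list(p1 = rbind(c(0.5, 0.5), c(0.75, 0.25)), p2 = NULL),
                  class = "policy_trace")
  expect_equal(compute_logits(tr), c(0, log(3)))
  s <- c(1.2, -0.4)
  p1 <- softmax_policy(s, 2); p2 <- softmax_policy(s + 3.7, 2)
  l <- function(p) log(p[1] / p[2])
  expect_equal(l(p1), l(p2))
})

test_that("the mf1 phase portrait is linear with slope -alpha and L* = 2 beta", {
  m <- cognitive_model("mf1", cfgr)
  p <- c(alpha = 0.4, beta = 2)
  pp <- phase_portrait(m, p, cfgr, n_grid = 201, grid_range = c(-6, 6))
  g <- pp$curves[, "A1,R=1"]
  fitln <- lm(g ~ pp$grid)
  expect_equal(unname(coef(fitln)[2]), -0.4, tolerance = 1e-6)
  fp <- pp$fixed_points[["A1,R=1"]]
  expect_equal(fp$L_star, 2 * 2, tolerance = 1e-6)
  expect_true(fp$stable)
  ## alpha = 0 freezes the state: the logit change is identically zero
  pp0 <- phase_portrait(m, c(alpha = 0, beta = 2), cfgr, n_grid = 51)
  expect_true(all(abs(pp0$curves) < 1e-12))
})

test_that("Bayesian fixed points are symmetric about 0 and exclude 0", {
  m <- cognitive_model("bayes", cfgr)
  p <- c(p_emit = 0.8, p_r = 0.05, beta = 3)
  pp <- phase_portrait(m, p, cfgr, n_grid = 401)
  f1 <- pp$fixed_points[["A1,R=1"]]
  f2 <- pp$fixed_points[["A2,R=1"]]
  expect_equal(nrow(f1), 1L)
  expect_gt(abs(f1$L_star), 0.5)
  expect_equal(f1$L_star, -f2$L_star, tolerance = 1e-6)
})

test_that("fixed-point search classifies stability by the discrete-map criterion", {
  fp <- find_fixed_points(function(L) -0.5 * L, -3, 3)
  expect_equal(fp$L_star, 0, tolerance = 1e-8)
  expect_true(fp$stable)                       # g' = -0.5
  fp <- find_fixed_points(function(L) -2.5 * (L - 1), -3, 3)
  expect_equal(fp$L_star, 1, tolerance = 1e-8)
  expect_false(fp$stable)                      # g' = -2.5 < -2
  fp <- find_fixed_points(function(L) 0.3 * L, -3, 3)
  expect_false(fp$stable)                      # g' > 0
  none <- find_fixed_points(function(L) L + 10, -3, 3)
  expect_equal(nrow(none), 0L)                 # no sign change: empty, no error
})

test_that("stability labels agree with long-run simulation", {
  m <- cognitive_model("mf1", cfgr)
  p <- c(alpha = 0.3, beta = 1.5)
  map <- as_scalar_map(m, p)
  cond <- condition_set(cfgr)[[2]]             # A1, R = 1
  fp <- find_fixed_points(function(L) map$step_L(L, cond) - L, -5, 5)
  expect_true(fp$stable)
  set.seed(9)
  for (i in 1:100) {
    L <- fp$L_star + runif(1, -1, 1)
    for (k in 1:200) L <- map$step_L(L, cond)
    expect_lt(abs(L - fp$L_star), 1e-6)
  }
})

test_that("preference setpoints normalize to max |u| = 1", {
  m <- cognitive_model("mf1", cfgr)
  sp <- preference_setpoints(m, c(alpha = 0.5, beta = 1), cfgr)
  expect_equal(sp$u[sp$condition == "A1,R=1"], 1)
  expect_equal(sp$u[sp$condition == "A2,R=1"], -1)
  expect_equal(max(abs(sp$u)), 1)
  expect_true(all(sp$converged))
  expect_true(all(abs(sp$u) <= 1))
})

test_that("setpoint normalization is the plain ratio to the largest L*", {
  ## handcrafted d = 1 model: each condition pulls the value all the way to
  ## its own target, so the fixed points are exactly the targets
  targets <- c("A1,R=0" = 2, "A1,R=1" = 1, "A2,R=0" = 0, "A2,R=1" = -2)
  fake <- structure(list(
    family = "mf", d = 1L, n_actions = 2L,
    par = data.frame(name = "beta", type = "temp"),
    init = function(params) list(q = c(0, 0)),
    step = function(state, obs, params) {
      lab <- sprintf("A%d,R=%d", obs$action + 1L, as.integer(obs$reward))
      q1 <- targets[[lab]] / (2 * params[["beta"]])
      list(q = c(q1, -q1))
    },
    policy = function(state, params)
      softmax_policy(state$q, params[["beta"]])
  ), class = "cog_model")
  sp <- preference_setpoints(fake, c(beta = 0.5), cfgr)
  expect_equal(sp$u[match(names(targets), sp$condition)],
               c(1, 0.5, 0, -1))
})

test_that("the effective learning rate generalizes the constant-rate case", {
  g_lin <- function(L) 0.35 * (2 - L)
  expect_equal(effective_learning_rate(g_lin, 2, c(-3, 0, 1.9, 2, 5)),
               rep(0.35, 5))
  ## quadratic map: alpha(L) = -g'(L) - alpha'(L) (L - L*) holds numerically
  g_quad <- function(L) -0.3 * (L - 1) - 0.05 * (L - 1)^2
  L <- seq(-0.5, 2.5, length.out = 101)
  a <- effective_learning_rate(g_quad, 1, L)
  h <- 1e-5
  gp <- (g_quad(L + h) - g_quad(L - h)) / (2 * h)
  ap <- (effective_learning_rate(g_quad, 1, L + h) -
         effective_learning_rate(g_quad, 1, L - h)) / (2 * h)
  expect_lt(max(abs(a - (-gp - ap * (L - 1)))), 1e-6)
  ## at L* the rate equals the negative tangent slope
  expect_equal(effective_learning_rate(g_quad, 1, 1), 0.3, tolerance = 1e-6)
})

test_that("two-dimensional fields show the model-free and drift signatures", {
  m <- cognitive_model("mf2", cfgr)
  p <- c(alpha = 0.3, beta = 2)
  vf <- vector_field_2d(m, p, cfgr, grid1 = seq(-1, 1, length.out = 5),
                        grid2 = seq(-1, 1, length.out = 5))
  a1 <- vf$arrows[vf$arrows$condition == "A1,R=1", ]
  expect_true(all(a1$dp2 == 0))               # only the chosen value moves
  a2 <- vf$arrows[vf$arrows$condition == "A2,R=1", ]
  expect_true(all(a2$dp1 == 0))
  ## drift-to-the-other, unrewarded: the attractor set is the diagonal
  md <- cognitive_model("mf2_dtto", cfgr)
  pd <- c(D1 = 0.7, b = 0.05, alpha0 = 0.5, beta = 1)
  vfd <- vector_field_2d(md, pd, cfgr, grid1 = seq(-1, 1, length.out = 4),
                         grid2 = seq(-1, 1, length.out = 4))
  att <- vfd$attractors[vfd$attractors$condition == "A1,R=0", ]
  expect_true(all(abs(att$p1 - att$p2) < 1e-5))
  ## a frozen model has a zero field
  vf0 <- vector_field_2d(m, c(alpha = 0, beta = 2), cfgr,
                         grid1 = 0, grid2 = 0)
  expect_true(all(vf0$arrows$speed == 0))
})

test_that("dynamical regression recovers noiseless linear dynamics exactly", {
  m <- cognitive_model("mf2", cfg2)
  p <- c(alpha = 0.3, beta = 2)
  dat <- simulate_task(cfg2, cognitive_agent(m, p), n_trials = 3000, seed = 4)
  st <- state_trajectory(m, p, dat)
  dr <- dynamical_regression(st$states, st$inputs, valid = st$valid)
  for (cn in names(dr)) {
    expect_true(dr[[cn]]$estimable)
    a <- as.integer(substr(cn, 2, 2))      # acting action 1/2
    A <- dr[[cn]]$A
    expect_equal(A[a, a], -0.3, tolerance = 1e-6)
    expect_equal(A[3 - a, 3 - a], 0, tolerance = 1e-6)
    expect_equal(A[a, 3 - a], 0, tolerance = 1e-6)
    expect_lt(max(dr[[cn]]$sigma2), 1e-12)
  }
  ## reward slot: rewarded A1 condition has beta0 = alpha * beta * r
  expect_equal(dr[["A1,S1,R=1"]]$beta0[1], 0.3 * 2, tolerance = 1e-6)
})

test_that("the one-dimensional regression matches the mf1 algebra", {
  m <- cognitive_model("mf1", cfgr)
  p <- c(alpha = 0.25, beta = 3)
  dat <- simulate_task(cfgr, cognitive_agent(m, p), n_trials = 3000, seed = 5)
  tr <- run_cognitive(m, p, dat)
  L <- compute_logits(tr)
  st <- state_trajectory(m, p, dat)
  dr <- dynamical_regression(matrix(L, ncol = 1), st$inputs,
                             valid = st$valid)
  ## under (A1, r = 1): dL = alpha (2 beta - L)
  expect_equal(dr[["A1,R=1"]]$beta0[1], 2 * 0.25 * 3, tolerance = 1e-6)
  expect_equal(dr[["A1,R=1"]]$A[1, 1], -0.25, tolerance = 1e-6)
  ## constant-change construction: beta0 = c and zero slope
  states <- matrix(cumsum(rep(0.1, 50)), ncol = 1)
  drc <- dynamical_regression(states, rep("I", 50))
  expect_equal(drc[["I"]]$beta0[1], 0.1, tolerance = 1e-9)
  expect_equal(drc[["I"]]$A[1, 1], 0, tolerance = 1e-9)
})

test_that("model-free one-step maps are fully reconstructed by regression", {
  ## the regression coefficients reproduce the update rule: simulate fresh
  ## data and predict every state change from the fitted coefficients
  m <- cognitive_model("mf2_forget", cfg2)
  p <- c(alpha = 0.45, beta = 2.5, D = 0.85)
  dat <- simulate_task(cfg2, cognitive_agent(m, p), n_trials = 2000, seed = 6)
  st <- state_trajectory(m, p, dat)
  dr <- dynamical_regression(st$states, st$inputs, valid = st$valid)
  dS <- diff(st$states)[st$valid, ]
  S0 <- st$states[-nrow(st$states), ][st$valid, ]
  inp <- st$inputs[-length(st$inputs)][st$valid]
  pred <- t(vapply(seq_len(nrow(S0)), function(i) {
    cf <- dr[[inp[i]]]
    as.numeric(cf$beta0 + cf$A %*% S0[i, ])
  }, numeric(2)))
  expect_lt(max(abs(pred - dS)), 1e-8)
})

test_that("scatter portraits label trials by their input condition", {
  m <- cognitive_model("mf1", cfgr)
  p <- c(alpha = 0.4, beta = 2)
  dat <- simulate_task(cfgr, cognitive_agent(m, p), n_trials = 500, seed = 7)
  pp <- phase_portrait(m, p, cfgr, data = dat)
  expect_equal(nrow(pp$scatter), 499L)
  ## every scatter point lies on its condition's curve
  map <- as_scalar_map(m, p)
  conds <- condition_set(cfgr)
  labs <- vapply(conds, `[[`, "", "label")
  for (i in sample(499, 50)) {
    cn <- conds[[match(pp$scatter$condition[i], labs)]]
    expect_equal(pp$scatter$dL[i],
                 map$step_L(pp$scatter$L[i], cn) - pp$scatter$L[i],
                 tolerance = 1e-8)
  }
})
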