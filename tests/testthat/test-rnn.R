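cfg2 <- task_config("two_stage")
cfgr <- task_config("reversal")

zero_gru_weights <- function(d, k) {
  z <- function(...) array(0, dim = c(...))
  list(Wir = z(d, k), Wiz = z(d, k), Win = z(d, k), Whr = z(d, d),
       Whz = z(d, d), Whn = z(d, d), bir = rep(0, d), biz = rep(0, d),
       bin = rep(0, d), bhr = rep(0, d), bhz = rep(0, d), bhn = rep(0, d))
}

test_that("gru_step matches hand evaluation and stays in (-1, 1)", {
  w <- zero_gru_weights(1, 3)
  expect_equal(gru_step(0, c(0, 0, 0), w), 0)       # zero net fixed point
  ## all weights zero: z = 0.5, n = 0, so h' = h / 2
  expect_equal(gru_step(0.8, c(1, 1, 1), w), 0.4)
  expect_error(gru_step(c(0, 0), c(0, 0, 0), w), "dimension")
  set.seed(3)
  spec <- rnn_spec(cfg2, d = 4, arch = "gru")
  wr <- rnn_init(spec, 5)
  h <- rep(0, 4)
  for (t in 1:10000) {
    h <- gru_step(h, runif(3), wr)
    if (t %% 1000 == 0) expect_true(all(abs(h) < 1))
  }
})

test_that("switching and linear steps follow their update rules", {
  d <- 1; K <- 4
  w <- list(Whr = array(0, c(d, d, K)), Whz = array(0, c(d, d, K)),
            Whn = array(0, c(d, d, K)), bir = matrix(0, d, K),
            biz = matrix(0, d, K), bin = matrix(0, d, K),
            bhr = matrix(0, d, K), bhz = matrix(0, d, K),
            bhn = matrix(0, d, K))
  ## identical weight sets behave as an input-blind recurrence
  expect_equal(switching_gru_step(0.8, 1, w), switching_gru_step(0.8, 3, w))
  expect_error(switching_gru_step(0, 9, w), "unknown input code")
  ## d = 1 affine contraction h' = 0.9 h + 0.1 approaches h* = 1
  ws <- list(W = array(0.9, c(1, 1, 2)), b = matrix(0.1, 1, 2))
  h <- 0
  for (i in 1:500) h <- slin_step(h, 1, ws)
  expect_equal(h, 1, tolerance = 1e-5)
  wI <- list(W = array(diag(2), c(2, 2, 2)), b = matrix(0, 2, 2))
  expect_equal(slin_step(c(0.3, -0.2), 2, wI), c(0.3, -0.2))   # identity
  ## symmetric variant rejects asymmetric weights
  spec_sym <- rnn_spec(cfg2, d = 2, arch = "slin_sym")
  wa <- list(W = array(c(0, 1, 0, 0), c(2, 2, 1)), b = matrix(0, 2, 1))
  expect_error(slin_step(c(0, 0), 1, wa, spec_sym), "asymmetric")
  wsym <- rnn_init(spec_sym, 1)
  for (c in 1:dim(wsym$W)[3])
    expect_equal(wsym$W[, , c], t(wsym$W[, , c]))
})

test_that("input encodings enumerate the task's discrete conditions", {
  ## reversal: 4 codes, 1 + 2 a + r
  dat <- random_sessions(cfgr, n = 200, seed = 2)
  enc <- encode_input(dat, cfgr, "selector")
  expect_equal(enc$codes, 1L + 2L * dat$action + as.integer(dat$reward))
  expect_equal(sort(unique(enc$codes)), 1:4)
  ## two-stage: 8 codes, bijective over (a, s, r)
  dat2 <- random_sessions(cfg2, n = 400, seed = 2)
  enc2 <- encode_input(dat2, cfg2, "selector")
  key <- paste(dat2$action, dat2$state, dat2$reward)
  expect_equal(length(unique(paste(enc2$codes, key))), 8L)
  expect_equal(sort(unique(enc2$codes)), 1:8)
  ## continuous rewards: vector component rescaled, selector rejected
  cfg4 <- task_config("bandit4")
  dat4 <- random_sessions(cfg4, n = 50, seed = 2)
  dat4$reward[1] <- 62
  encv <- encode_input(dat4, cfg4, "vector")
  expect_equal(encv$X[1, 5], 0.62)
  expect_error(rnn_spec(cfg4, d = 1, arch = "sgru"), "continuous")
})

test_that("readout layers produce the documented policies", {
  spec <- rnn_spec(cfg2, d = 2, arch = "gru", readout = "diagonal")
  w <- rnn_init(spec, 1)
  w$B <- c(1, 1)
  expect_equal(readout_policy(c(log(3), 0), spec, w), c(0.75, 0.25))
  w$B <- c(0, 0)
  expect_equal(readout_policy(c(5, -3), spec, w), c(0.5, 0.5))
  ## full readout nests the diagonal one
  specf <- rnn_spec(cfg2, d = 2, arch = "gru", readout = "full")
  wf <- rnn_init(specf, 1)
  wf$B <- diag(c(1.3, 0.7))
  specd <- rnn_spec(cfg2, d = 2, arch = "gru", readout = "diagonal")
  wd <- wf; wd$B <- c(1.3, 0.7)
  h <- c(0.2, -0.5)
  expect_equal(readout_policy(h, specf, wf), readout_policy(h, specd, wd))
  expect_error(rnn_spec(cfg2, d = 3, readout = "diagonal", arch = "gru"),
               "diagonal readout")
})

test_that("a vanilla GRU transforms exactly into a switching GRU", {
  for (task in c("reversal", "two_stage")) {
    cfg <- task_config(task)
    dat <- random_sessions(cfg, n = 1000, seed = 4, n_sessions = 2)
    spec <- rnn_spec(cfg, d = 2, arch = "gru")
    w <- rnn_init(spec, 9)
    sw <- gru_to_switching(w, spec)
    t1 <- rnn_policy_trace(spec, w, dat)
    t2 <- rnn_policy_trace(sw$spec, sw$weights, dat)
    expect_lt(max(abs(t1$p1 - t2$p1)), 1e-10)
  }
})

test_that("the hidden state is Markovian: replay equals restart", {
  spec <- rnn_spec(cfg2, d = 3, arch = "gru")
  w <- rnn_init(spec, 2)
  set.seed(8)
  xs <- matrix(runif(60), 20, 3)
  h <- rep(0, 3)
  for (t in 1:10) h <- gru_step(h, xs[t, ], w)
  saved <- h
  full <- saved
  for (t in 11:20) full <- gru_step(full, xs[t, ], w)
  resumed <- saved
  for (t in 11:20) resumed <- gru_step(resumed, xs[t, ], w)
  expect_identical(full, resumed)
})

test_that("backpropagation matches finite differences for all architectures", {
  dat <- random_sessions(cfg2, n = 200, seed = 5, n_sessions = 2)
  targets <- cogrnn:::make_targets(dat)
  wt <- rep(1, nrow(dat))
  for (arch in c("gru", "sgru", "slin")) {
    spec <- rnn_spec(cfg2, d = 2, arch = arch,
                     encoding = if (arch == "gru") "vector" else "selector")
    w <- rnn_init(spec, 3)
    enc <- encode_input(dat, cfg2, spec$encoding)
    lg <- cogrnn:::rnn_loss_grad(spec, w, enc, targets, wt, l1 = 1e-3)
    flat <- cogrnn:::flatten_weights(w)
    g_an <- cogrnn:::flatten_weights(lg$grads[flat$names])$theta
    f <- function(th) cogrnn:::rnn_loss_grad(
      spec, cogrnn:::restore_weights(th, flat), enc, targets, wt, 1e-3)$loss
    set.seed(1)
    idx <- sample(length(flat$theta), min(20, length(flat$theta)))
    g_num <- vapply(idx, function(i) {
      e <- rep(0, length(flat$theta)); e[i] <- 1e-5
      (f(flat$theta + e) - f(flat$theta - e)) / 2e-5
    }, 0)
    expect_lt(max(abs(g_num - g_an[idx])), 1e-6, label = arch)
  }
})

test_that("a one-unit switching GRU recovers a d = 1 generator's policy", {
  gen <- cognitive_model("mf1", cfg2)
  gp <- c(alpha = 0.5, beta = 3)
  dat <- simulate_task(cfg2, cognitive_agent(gen, gp), n_trials = 20000,
                       seed = 21)
  spec <- rnn_spec(cfg2, d = 1)
  expect_equal(spec$arch, "sgru")     # d = 1 defaults to switching GRU
  r <- train_rnn(spec, dat, 1:14000, 14001:16000,
                 fit_config(l1_grid = 1e-5, patience = 200,
                            max_epochs = 2500), seed = 1)
  test_idx <- 16001:20000
  nll_rnn <- negative_log_likelihood(rnn_policy_trace(spec, r$weights, dat),
                                     dat, test_idx)$nll_per_trial
  nll_gen <- negative_log_likelihood(run_cognitive(gen, gp, dat),
                                     dat, test_idx)$nll_per_trial
  expect_lt(nll_rnn - nll_gen, 0.01)
})
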