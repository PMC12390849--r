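cfg2 <- task_config("two_stage")

test_that("the distillation loss is cross-entropy with its Gibbs minimum", {
  set.seed(1)
  p_t <- matrix(runif(20), 10, 2); p_t <- p_t / rowSums(p_t)
  teacher <- structure(list(p1 = p_t, p2 = NULL), class = "policy_trace")
  same <- structure(list(p1 = p_t, p2 = NULL), class = "policy_trace")
  ent <- -sum(p_t * log(p_t))
  expect_equal(distillation_loss(teacher, same), ent)
  ## any other student does worse (Gibbs inequality), on random candidates
  for (k in 1:25) {
    q <- matrix(runif(20), 10, 2); q <- q / rowSums(q)
    st <- structure(list(p1 = q, p2 = NULL), class = "policy_trace")
    expect_gte(distillation_loss(teacher, st), ent)
  }
  ## a one-hot teacher reduces the loss to the choice likelihood
  onehot <- matrix(0, 10, 2); onehot[cbind(1:10, sample(1:2, 10, TRUE))] <- 1
  t1 <- structure(list(p1 = onehot, p2 = NULL), class = "policy_trace")
  q <- matrix(runif(20), 10, 2); q <- q / rowSums(q)
  st <- structure(list(p1 = q, p2 = NULL), class = "policy_trace")
  expect_equal(distillation_loss(t1, st), -sum(log(q[onehot == 1])))
  ## misaligned traces are rejected
  short <- structure(list(p1 = q[1:5, ], p2 = NULL), class = "policy_trace")
  expect_error(distillation_loss(teacher, short), "misaligned")
})

test_that("symmetry augmentation makes four flipped copies", {
  dat <- random_sessions(cfg2, n = 100, seed = 2)
  aug <- augment_by_symmetry(dat, cfg2)
  expect_equal(nrow(aug), 400L)
  expect_equal(length(unique(paste(aug$subject, aug$session))), 4L)
  ## code relabeling: the action flip of (A1, S2, r) is (A2, S2, r)
  fa <- aug[aug$copy == "fa", ]
  expect_equal(fa$action, 1L - dat$action)
  expect_equal(fa$state, dat$state)
  expect_equal(fa$reward, dat$reward)
  ## group closure: flipping the flipped copies gives the same four variants
  key <- function(d) paste(d$action, d$state, collapse = ";")
  variants1 <- sort(vapply(split(as.data.frame(aug), aug$copy), key, ""))
  aug2 <- augment_by_symmetry(
    session_data(within(as.data.frame(aug)[aug$copy == "fa", ],
                        copy <- NULL), cfg2), cfg2)
  expect_true(all(vapply(split(as.data.frame(aug2), aug2$copy), key, "")
                  %in% variants1))
  ## tasks without the two-action/two-state symmetry are rejected
  expect_error(augment_by_symmetry(random_sessions(task_config("reversal3"),
                                                   50, 1),
                                   task_config("reversal3")),
               "symmetry")
  expect_error(augment_by_symmetry(random_sessions(task_config("reversal"),
                                                   50, 1),
                                   task_config("reversal")),
               "symmetry")
})

test_that("an action/state-symmetric model scores all copies equally", {
  dat <- random_sessions(cfg2, n = 200, seed = 3)
  aug <- augment_by_symmetry(dat, cfg2)
  ## the Bayesian observer is symmetric under the joint action/state flip
  m <- cognitive_model("bayes", cfg2)
  p <- c(p_emit = 0.8, p_r = 0.05, beta = 2)
  nll_of <- function(tag) {
    d <- session_data(as.data.frame(aug)[aug$copy == tag, ], cfg2)
    negative_log_likelihood(run_cognitive(m, p, d), d)$nll_per_trial
  }
  expect_equal(nll_of("orig"), nll_of("fas"), tolerance = 1e-12)
})

test_that("teacher policies respect embedding symmetry and identity", {
  subs <- c("a", "b")
  d1 <- random_sessions(cfg2, n = 80, seed = 4)
  d2 <- d1; d2$subject <- "b"; d1$subject <- "a"
  both <- session_data(rbind(as.data.frame(d1), as.data.frame(d2)), cfg2)
  spec <- teacher_spec(cfg2, subs, d = 4, embedding_dim = 2)
  w <- rnn_init(spec, 5)
  ## identical data and identical embeddings give identical traces
  w$E[2, ] <- w$E[1, ]
  tr <- teacher_forward(spec, w, both)
  expect_equal(tr$p1[1:80, ], tr$p1[81:160, ])
  ## zero embeddings: the teacher ignores subject identity
  w2 <- rnn_init(spec, 5)
  w2$E[] <- 0
  tr2 <- teacher_forward(spec, w2, both)
  expect_equal(tr2$p1[1:80, ], tr2$p1[81:160, ])
  expect_error(teacher_forward(spec, w, within(as.data.frame(both),
                                               subject <- "zz")),
               "unknown subject")
})

test_that("a subject-embedding teacher recovers heterogeneous learners", {
  pop <- synthetic_population(cfg2, n_sub = 3L, n_trials = 1500L, seed = 61)
  data <- pop$data
  spec <- teacher_spec(cfg2, unique(data$subject), d = 8, embedding_dim = 2)
  n <- nrow(data)
  set.seed(2)
  test_idx <- sort(sample(n, round(0.2 * n)))
  rest <- setdiff(seq_len(n), test_idx)
  val_idx <- sort(sample(rest, round(0.1 * n)))
  train_idx <- setdiff(rest, val_idx)
  r <- train_rnn(spec, data, train_idx, val_idx,
                 fit_config(l1_grid = 1e-4, patience = 80, max_epochs = 600),
                 seed = 1)
  tr <- teacher_forward(spec, r$weights, data)
  for (i in 1:3) {
    sub <- sprintf("m%02d", i)
    rows <- intersect(test_idx, which(data$subject == sub))
    nll_t <- negative_log_likelihood(tr, data, rows)$nll_per_trial
    gen_tr <- run_cognitive(pop$model, pop$params[[i]], data)
    nll_g <- negative_log_likelihood(gen_tr, data, rows)$nll_per_trial
    expect_lt(nll_t - nll_g, 0.05)
  }
})

test_that("augmentation hides side bias from a model; raw data keeps it", {
  ## a biased agent prefers A1 regardless of value; in the
  ## transition-reversal task the flipped copies are statistically
  ## indistinguishable from plausible sessions, so the bias cancels
  cfgt <- task_config("transition_reversal")
  biased <- structure(list(
    init = function(cfg) NULL,
    policy = function(carry, cfg) c(0.8, 0.2),
    update = function(carry, obs, cfg) carry), class = "agent")
  dat <- simulate_task(cfgt, biased, n_trials = 1500, seed = 8)
  aug <- augment_by_symmetry(dat, cfgt)
  spec <- rnn_spec(cfgt, d = 1)
  fitc <- fit_config(l1_grid = 1e-4, patience = 60, max_epochs = 400)
  raw <- train_rnn(spec, dat, 1:1200, 1201:1500, fitc, seed = 1)
  n <- nrow(dat)
  aug_train <- as.vector(outer(1:1200, (0:3) * n, `+`))
  aug_val <- as.vector(outer(1201:1500, (0:3) * n, `+`))
  sym <- train_rnn(spec, aug, aug_train, aug_val, fitc, seed = 1)
  nll_raw <- negative_log_likelihood(rnn_policy_trace(spec, raw$weights, dat),
                                     dat, 1201:1500)$nll_per_trial
  bias_nll <- -(0.8 * log(0.8) + 0.2 * log(0.2))
  expect_lt(nll_raw, log(2) - 0.05)            # bias learned from raw data
  expect_equal(nll_raw, bias_nll, tolerance = 0.1)
  ## the augmented data are exactly action-balanced, so the true side is
  ## not recoverable: the augmentation-trained model scores the original
  ## and the action-flipped data equally, while the raw-trained model
  ## strongly prefers the true side
  expect_equal(mean(aug$action), 0.5)
  flipped <- dat; flipped$action <- 1L - flipped$action
  flipped <- session_data(as.data.frame(flipped), cfgt)
  score <- function(w, d) negative_log_likelihood(
    rnn_policy_trace(spec, w, d), d, 1201:1500)$nll_per_trial
  expect_lt(abs(score(sym$weights, dat) - score(sym$weights, flipped)), 0.02)
  expect_lt(score(raw$weights, dat) + 0.3, score(raw$weights, flipped))
})

test_that("the distillation pipeline guards its index discipline", {
  pop <- synthetic_population(cfg2, n_sub = 4L, n_trials = 200L, seed = 71)
  fitc <- fit_config(l1_grid = 1e-4, seeds = 1, patience = 30,
                     max_epochs = 120)
  res <- distill_pipeline(pop$data, "m01", cfg2, student_d = 1,
                          teacher_d = 4, embedding_grid = 1L, fit = fitc,
                          seed = 2)
  idx <- res$idx
  expect_equal(length(intersect(idx$m_train, idx$m_test)), 0L)
  expect_equal(length(intersect(idx$m_val, idx$m_test)), 0L)
  expect_true(all(pop$data$subject[idx$m_test] == "m01"))
  expect_true(is.finite(res$student_nll) && is.finite(res$solo_nll))
  expect_error(distill_pipeline(pop$data, "m01", cfg2, m_trials = 0,
                                fit = fitc),
               "M-training")
  expect_error(distill_pipeline(pop$data, "nope", cfg2, fit = fitc),
               "unknown target")
})
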