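#' Negative log-likelihood of observed choices under a policy trace
#'
#' Sums `-log Pr(observed action)` over sessions and trials. Masked
#' (missing) trials are excluded; probabilities are floored at 1e-12 (with a
#' warning) before taking logs. For the original two-stage task the
#' second-stage choice at the realized state contributes a second term per
#' trial.
#'
#' @param policy a `policy_trace` (from [run_cognitive()] or
#'   [rnn_policy_trace()]).
#' @param data the [session_data()] the trace was computed on.
#' @param idx optional row indices restricting the loss to a trial subset
#'   (the full sequence is always used to build the trace).
#' @return list with `nll` (total), `n` (number of scored trials) and
#'   `nll_per_trial`.
#' @export
negative_log_likelihood <- function(policy, data, idx = NULL) {
  keep <- data$mask
  if (!is.null(idx)) {
    sel <- rep(FALSE, nrow(data)); sel[idx] <- TRUE
    keep <- keep & sel
  }
  p <- policy$p1[cbind(seq_len(nrow(data)), data$action + 1L)]
  ll <- numeric(nrow(data))
  ll[keep] <- log(floor_prob(p[keep]))
  if (!is.null(policy$p2)) {
    p2 <- policy$p2[cbind(seq_len(nrow(data)), data$action2 + 1L)]
    ll[keep] <- ll[keep] + log(floor_prob(p2[keep]))
  }
  n <- sum(keep)
  list(nll = -sum(ll[keep]), n = n, nll_per_trial = -sum(ll[keep]) / n)
}

floor_prob <- function(p) {
  if (any(p < 1e-12, na.rm = TRUE))
    warning("probability floored at 1e-12 in the loss")
  pmax(p, 1e-12)
}

#' Fitting configuration
#'
#' @param lr Adam learning rate (default 0.005).
#' @param l1_grid L1 coefficients on recurrent weights tried as
#'   hyperparameters.
#' @param patience early-stopping patience in epochs (default 200).
#' @param max_epochs training-epoch cap.
#' @param seeds random seeds tried as hyperparameters.
#' @param n_restarts random restarts per seed for cognitive-model fits.
#' @param inner_val_folds how many of the nine held-in folds to use as inner
#'   validation folds in [nested_cv()] (9 = the full inner loop).
#' @return a `fit_config` list.
#' @export
fit_config <- function(lr = 0.005, l1_grid = 10^seq(-5, -1), patience = 200L,
                       max_epochs = 2000L, seeds = 1:3, n_restarts = 3L,
                       inner_val_folds = 9L) {
  stopifnot(length(l1_grid) >= 1L, patience >= 1L)
  structure(list(lr = lr, l1_grid = l1_grid, patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs), seeds = seeds,
                 n_restarts = as.integer(n_restarts),
                 inner_val_folds = as.integer(inner_val_folds)),
            class = "fit_config")
}

## --- Adam -------------------------------------------------------------------

adam_new <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(opt, g, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  opt$m <- b1 * opt$m + (1 - b1) * g
  opt$v <- b2 * opt$v + (1 - b2) * g^2
  mhat <- opt$m / (1 - b1^opt$t)
  vhat <- opt$v / (1 - b2^opt$t)
  opt$delta <- -lr * mhat / (sqrt(vhat) + eps)
  opt
}

## flatten / restore weight lists
flatten_weights <- function(w) {
  skel <- lapply(w, function(a) dim(a) %||% length(a))
  list(theta = unlist(w, use.names = FALSE), skeleton = skel,
       names = names(w))
}

restore_weights <- function(theta, flat) {
  out <- list(); pos <- 1L
  for (i in seq_along(flat$names)) {
    dm <- flat$skeleton[[i]]
    len <- prod(dm)
    vals <- theta[pos:(pos + len - 1L)]
    out[[flat$names[i]]] <- if (length(dm) > 1L) array(vals, dm) else vals
    pos <- pos + len
  }
  structure(out, class = "rnn_weights")
}

## --- RNN loss and gradient ---------------------------------------------------

## targets: list(Y) for single-choice-stage tasks (T x n_actions target
## probabilities) or list(y1, y2, s) for the original two-stage task.
make_targets <- function(data, trace = NULL) {
  n <- nrow(data)
  if (!is.null(data$action2) && !all(is.na(data$action2))) {
    if (is.null(trace))
      list(y1 = as.numeric(data$action == 0L),
           y2 = as.numeric(data$action2 == 0L), s = data$state)
    else list(y1 = trace$p1[, 1], y2 = trace$p2[, 1], s = data$state)
  } else {
    if (is.null(trace)) {
      Y <- matrix(0, n, max(data$action) + 1L)
      Y[cbind(seq_len(n), data$action + 1L)] <- 1
      list(Y = Y)
    } else list(Y = trace$p1)
  }
}

recurrent_names <- function(spec) switch(spec$arch,
  gru = c("Whr", "Whz", "Whn"), sgru = c("Whr", "Whz", "Whn"),
  slin = , slin_sym = "W")

## loss + gradient for one epoch; wt_train weights the scored trials
rnn_loss_grad <- function(spec, w, enc, targets, wt_train, l1) {
  fwd <- rnn_hidden(spec, w, enc)
  H <- fwd$H
  S <- rnn_scores(spec, w, H)
  n_tr <- sum(wt_train)
  if (spec$ots) {
    dS <- matrix(0, nrow(S), 3L)
    p1 <- logistic(S[, 1])
    i2 <- cbind(seq_len(nrow(S)), 2L + targets$s)
    p2 <- logistic(S[i2])
    loss <- -sum(wt_train * (targets$y1 * log(floor_prob(p1)) +
                             (1 - targets$y1) * log(floor_prob(1 - p1)) +
                             targets$y2 * log(floor_prob(p2)) +
                             (1 - targets$y2) * log(floor_prob(1 - p2))))
    dS[, 1] <- wt_train * (p1 - targets$y1)
    dS[i2] <- dS[i2] + wt_train * (p2 - targets$y2)
  } else {
    P <- cpp_row_softmax(S)
    loss <- -sum(wt_train * rowSums(targets$Y * log(floor_prob(P))))
    dS <- wt_train * (P - targets$Y)
  }
  if (spec$readout == "full") {
    dH <- dS %*% w$B
    dB <- t(dS) %*% H
  } else {
    dH <- sweep(dS, 2L, w$B, `*`)
    dB <- colSums(dS * H)
  }
  gr <- rnn_backward(spec, w, enc, fwd, dH)
  gr$B <- dB
  if (spec$embedding_dim > 0L) {
    embcols <- (spec$input_dim - spec$embedding_dim + 1L):spec$input_dim
    dE <- rowsum(gr$dX[, embcols, drop = FALSE], enc$subject_row,
                 reorder = FALSE)
    full <- matrix(0, length(spec$subjects), spec$embedding_dim)
    full[as.integer(rownames(dE)), ] <- dE
    gr$E <- full
  }
  gr$dX <- NULL
  for (nm in recurrent_names(spec)) {
    loss_pen <- l1 * sum(abs(w[[nm]]))
    loss <- loss + loss_pen
    gr[[nm]] <- gr[[nm]] + l1 * sign(w[[nm]])
  }
  list(loss = loss, n = n_tr, grads = gr, scores = S)
}

rnn_backward <- function(spec, w, enc, fwd, dH) {
  starts <- as.integer(enc$starts)
  if (spec$arch == "gru") {
    cpp_gru_backward(w[c("Wir", "Wiz", "Win", "Whr", "Whz", "Whn", "bir",
                         "biz", "bin", "bhr", "bhz", "bhn")],
                     enc$X, fwd, dH, starts)
  } else if (spec$arch == "sgru") {
    cpp_sgru_backward(w[c("Whr", "Whz", "Whn", "bir", "biz", "bin", "bhr",
                          "bhz", "bhn")], enc$codes, fwd, dH, starts)
  } else {
    cpp_slin_backward(w[c("W", "b")], enc$codes, fwd, dH, starts)
  }
}

## validation loss at the current weights, from precomputed scores
rnn_eval_loss <- function(spec, S, targets, wt) {
  if (sum(wt) == 0) return(NA_real_)
  if (spec$ots) {
    p1 <- logistic(S[, 1])
    p2 <- logistic(S[cbind(seq_len(nrow(S)), 2L + targets$s)])
    -sum(wt * (targets$y1 * log(floor_prob(p1)) +
               (1 - targets$y1) * log(floor_prob(1 - p1)) +
               targets$y2 * log(floor_prob(p2)) +
               (1 - targets$y2) * log(floor_prob(1 - p2)))) / sum(wt)
  } else {
    P <- cpp_row_softmax(S)
    -sum(wt * rowSums(targets$Y * log(floor_prob(P)))) / sum(wt)
  }
}

#' Train a recurrent choice model
#'
#' Full-batch Adam on the trial-summed cross-entropy (plus an L1 penalty
#' on recurrent weights), with early stopping on the validation loss: the
#' returned weights are those of the epoch with the best validation loss,
#' not the last epoch. Deterministic given `seed`.
#'
#' @param spec an [rnn_spec()].
#' @param data a [session_data()].
#' @param train_idx,val_idx disjoint row-index sets; the full sequence is
#'   always fed, the losses are evaluated on each set.
#' @param config a [fit_config()]; `config$l1_grid[1]` is used as the L1
#'   coefficient here (grids are searched by [nested_cv()]).
#' @param seed initialization seed.
#' @param teacher optional `policy_trace` of a teacher model: when given,
#'   training targets are the teacher's action probabilities (knowledge
#'   distillation) rather than the observed actions.
#' @param init_weights optional warm-start weights.
#' @return list with `weights`, `spec`, per-trial `train_nll` and `val_nll`
#'   at the selected epoch, `best_epoch` and the validation `curve`.
#' @export
train_rnn <- function(spec, data, train_idx, val_idx, config = fit_config(),
                      seed = 1L, teacher = NULL, init_weights = NULL) {
  if (length(intersect(train_idx, val_idx)) > 0L)
    stop("train_rnn: train and validation indices overlap")
  enc <- encode_input(data, spec$config, spec$encoding)
  w <- init_weights %||% rnn_init(spec, seed)
  if (spec$embedding_dim > 0L) enc <- append_embedding(enc, data, spec, w$E)
  targets <- make_targets(data, teacher)
  n <- nrow(data)
  wt_tr <- numeric(n); wt_tr[train_idx] <- 1; wt_tr <- wt_tr * data$mask
  wt_va <- numeric(n); wt_va[val_idx] <- 1; wt_va <- wt_va * data$mask
  l1 <- config$l1_grid[1]

  flat <- flatten_weights(w)
  theta <- flat$theta
  opt <- adam_new(length(theta))
  best <- list(val = Inf, theta = theta, epoch = 0L, train = NA_real_)
  curve <- numeric(0)
  for (epoch in seq_len(config$max_epochs)) {
    w <- restore_weights(theta, flat)
    if (spec$embedding_dim > 0L)
      enc$X[, (spec$input_dim - spec$embedding_dim + 1L):spec$input_dim] <-
        w$E[enc$subject_row, , drop = FALSE]
    lg <- rnn_loss_grad(spec, w, enc, targets, wt_tr, l1)
    if (!is.finite(lg$loss))
      stop("train_rnn: non-finite training loss at epoch ", epoch)
    val <- rnn_eval_loss(spec, lg$scores, targets, wt_va)
    curve[epoch] <- val
    if (is.finite(val) && val < best$val - 1e-9) {
      best <- list(val = val, theta = theta, epoch = epoch,
                   train = lg$loss / max(lg$n, 1L))
    }
    if (epoch - best$epoch >= config$patience) break
    g <- flatten_weights(lg$grads[flat$names])$theta
    opt <- adam_step(opt, g, config$lr)
    theta <- theta + opt$delta
    if (spec$arch == "slin_sym") {
      w2 <- restore_weights(theta, flat)
      for (c in seq_len(dim(w2$W)[3])) w2$W[, , c] <- sym_project(w2$W[, , c])
      theta <- flatten_weights(w2)$theta
    }
  }
  w <- restore_weights(best$theta, flat)
  list(weights = w, spec = spec, train_nll = best$train, val_nll = best$val,
       best_epoch = best$epoch, curve = curve)
}

## --- Cognitive-model maximum likelihood --------------------------------------

#' Fit a cognitive model by maximum likelihood
#'
#' Gradient-based optimization (BFGS on smoothly reparameterized parameters)
#' of the trial-summed negative log-likelihood on the training trials, with
#' `n_restarts` random initializations drawn from `seed`.
#'
#' @param model a [cognitive_model()].
#' @param data a [session_data()].
#' @param train_idx row indices scored by the objective (full sequences are
#'   always fed).
#' @param config a [fit_config()].
#' @param seed initialization seed.
#' @return list with `params` (natural scale), `nll` (per scored trial),
#'   `model`.
#' @export
fit_cognitive <- function(model, data, train_idx = seq_len(nrow(data)),
                          config = fit_config(), seed = 1L) {
  obj <- function(theta) {
    params <- par_natural(theta, model$par)
    suppressWarnings({   # degenerate parameter draws may floor probabilities
      tr <- run_cognitive(model, params, data)
      negative_log_likelihood(tr, data, train_idx)$nll
    })
  }
  best <- NULL
  with_local_seed(seed, {
    for (r in seq_len(config$n_restarts)) {
      theta0 <- par_unbounded(as.list(par_random_init(model$par)), model$par)
      fit <- tryCatch(
        optim(theta0, obj, method = "BFGS",
              control = list(maxit = 300, reltol = 1e-10)),
        error = function(e) NULL)
      if (is.null(fit)) next
      if (is.null(best) || fit$value < best$value) best <- fit
    }
  })
  if (is.null(best)) stop("fit_cognitive: all restarts failed")
  params <- par_natural(best$par, model$par)
  n <- negative_log_likelihood(run_cognitive(model, params, data),
                               data, train_idx)$n
  list(params = params, nll = best$value / n, model = model)
}

#' Train any supported model on a train/validation split
#'
#' Dispatches on the model handle: [rnn_spec()] objects are trained with
#' [train_rnn()]; [cognitive_model()] objects with [fit_cognitive()]
#' (cognitive models have no early stopping; the validation set only enters
#' hyperparameter selection).
#'
#' @param model an `rnn_spec` or `cog_model`.
#' @param data a [session_data()].
#' @param train_idx,val_idx disjoint trial-index sets.
#' @param config a [fit_config()].
#' @param seed integer seed.
#' @return list with `fit` (weights or parameters), `trace` accessor inputs,
#'   and per-trial `train_nll`/`val_nll`.
#' @export
train_model <- function(model, data, train_idx, val_idx,
                        config = fit_config(), seed = 1L) {
  if (inherits(model, "rnn_spec")) {
    r <- train_rnn(model, data, train_idx, val_idx, config, seed)
    list(kind = "rnn", model = model, fit = r$weights,
         train_nll = r$train_nll, val_nll = r$val_nll,
         best_epoch = r$best_epoch)
  } else if (inherits(model, "cog_model")) {
    r <- fit_cognitive(model, data, train_idx, config, seed)
    tr <- run_cognitive(model, r$params, data)
    val <- if (length(val_idx))
      negative_log_likelihood(tr, data, val_idx)$nll_per_trial else NA_real_
    list(kind = "cog", model = model, fit = r$params,
         train_nll = r$nll, val_nll = val)
  } else stop("train_model: unsupported model handle")
}

## policy trace of a fitted model (output of train_model)
fitted_trace <- function(fit, data) {
  if (fit$kind == "rnn") rnn_policy_trace(fit$model, fit$fit, data)
  else run_cognitive(fit$model, fit$fit, data)
}

## --- Nested cross-validation --------------------------------------------------

#' Nested cross-validation over blocks
#'
#' For each outer fold f: the fold's blocks are the test set; the inner loop
#' walks over the held-in folds, holding out one as validation and training
#' on the remaining eight, once per hyperparameter setting (L1 coefficient
#' and seed for RNNs, seed for cognitive models). The inner candidate with
#' the best trial-weighted likelihood on the nine held-in folds (training
#' plus validation trials) is refitted nowhere - its fitted model is
#' evaluated once on the unseen test fold. The aggregate score is the
#' trial-weighted mean over test folds.
#'
#' @param model an `rnn_spec` or `cog_model`.
#' @param data a [session_data()].
#' @param partition a [segment_blocks()] partition with 10 folds.
#' @param config a [fit_config()]; `config$inner_val_folds` < 9 restricts the
#'   inner loop to the first k validation folds (an efficiency knob for
#'   hyperparameter-free models, for which nested CV collapses to plain
#'   cross-validation).
#' @return a `cv_report`: data frame with one row per outer fold
#'   (`fold`, `n_test`, `test_nll`, `l1`, `seed`, `val_fold`), with the
#'   trial-weighted aggregate in `attr(, "aggregate")`.
#' @export
nested_cv <- function(model, data, partition, config = fit_config()) {
  folds <- sort(unique(partition$fold))
  is_rnn <- inherits(model, "rnn_spec")
  grid <- if (is_rnn)
    expand.grid(l1 = config$l1_grid, seed = config$seeds)
  else expand.grid(l1 = NA_real_, seed = config$seeds)
  rows <- list()
  for (f in folds) {
    test_idx <- fold_indices(partition, f)
    inner <- setdiff(folds, f)
    heldin_idx <- fold_indices(partition, inner)
    val_folds <- inner[seq_len(min(config$inner_val_folds, length(inner)))]
    cand <- list()
    for (v in val_folds) {
      tr_idx <- fold_indices(partition, setdiff(inner, v))
      va_idx <- fold_indices(partition, v)
      for (gi in seq_len(nrow(grid))) {
        cfg_i <- config
        if (is_rnn) cfg_i$l1_grid <- grid$l1[gi]
        fit <- train_model(model, data, tr_idx, va_idx, cfg_i,
                           seed = grid$seed[gi])
        tr <- fitted_trace(fit, data)
        score <- negative_log_likelihood(tr, data, heldin_idx)$nll_per_trial
        cand[[length(cand) + 1L]] <- list(fit = fit, score = score,
                                          l1 = grid$l1[gi],
                                          seed = grid$seed[gi], val_fold = v)
      }
    }
    best <- cand[[which.min(vapply(cand, `[[`, 0, "score"))]]
    tr <- fitted_trace(best$fit, data)
    te <- negative_log_likelihood(tr, data, test_idx)
    rows[[length(rows) + 1L]] <- data.frame(
      fold = f, n_test = te$n, test_nll = te$nll_per_trial,
      l1 = best$l1, seed = best$seed, val_fold = best$val_fold)
  }
  report <- do.call(rbind, rows)
  agg <- sum(report$test_nll * report$n_test) / sum(report$n_test)
  structure(report, aggregate = agg, class = c("cv_report", "data.frame"))
}

#' @export
print.cv_report <- function(x, ...) {
  print.data.frame(x, ...)
  cat("trial-weighted mean test NLL:", attr(x, "aggregate"), "\n")
  invisible(x)
}

#' Interspersed train/validation/test split
#'
#' Samples disjoint trial-index sets of exactly the requested sizes without
#' replacement. The full trial sequence is still fed to models; only the
#' losses are evaluated per index set.
#'
#' @param n_trials number of trials in the block.
#' @param counts integer vector `c(train, val, test)`.
#' @param seed integer seed.
#' @return list with sorted index vectors `train`, `val`, `test`.
#' @export
interspersed_split <- function(n_trials, counts, seed = 1L) {
  stopifnot(length(counts) == 3L)
  if (sum(counts) > n_trials)
    stop("interspersed_split: counts exceed the number of trials")
  with_local_seed(seed, {
    perm <- sample.int(n_trials)
    list(train = sort(perm[seq_len(counts[1])]),
         val = sort(perm[counts[1] + seq_len(counts[2])]),
         test = sort(perm[counts[1] + counts[2] + seq_len(counts[3])]))
  })
}

#' Estimate the dimensionality of behaviour
#'
#' Given per-fold test likelihoods for models of increasing hidden size, the
#' estimated dimensionality d* is the number of dynamical variables at which
#' predictive performance is optimized: the largest d whose model
#' significantly outperforms every model with fewer dynamical variables
#' (paired one-sided t-tests over outer folds at the given significance
#' level). Equivalently: d* satisfies both (1) it beats all smaller d and
#' (2) no larger d beats all models smaller than itself. When no model beats
#' all smaller ones, d* is the smallest candidate.
#'
#' @param reports named list: names are the d values (as integers), elements
#'   are `cv_report` objects or numeric vectors of per-fold test NLLs
#'   (aligned folds).
#' @param significance test level (default 0.05, no multiple-testing
#'   correction).
#' @return the estimated dimensionality `d_star` (integer) with the
#'   significance table in `attr(, "tests")`.
#' @export
estimate_dimensionality <- function(reports, significance = 0.05) {
  ds <- sort(as.integer(names(reports)))
  if (length(ds) < 1L) stop("estimate_dimensionality: no reports")
  get_nll <- function(d) {
    r <- reports[[as.character(d)]]
    if (inherits(r, "cv_report") || is.data.frame(r)) r$test_nll else r
  }
  if (length(get_nll(ds[1])) < 2L)
    stop("estimate_dimensionality: need at least 2 folds")
  beats <- function(d_big, d_small) {
    x <- get_nll(d_big); y <- get_nll(d_small)
    if (isTRUE(all.equal(x, y))) return(FALSE)
    if (sd(x - y) < 1e-12) return(mean(x - y) < 0)  # constant difference
    t.test(x, y, paired = TRUE, alternative = "less")$p.value < significance
  }
  tests <- expand.grid(d = ds, d_ref = ds)
  tests <- tests[tests$d > tests$d_ref, ]
  tests$significant <- mapply(beats, tests$d, tests$d_ref)
  crit1 <- vapply(ds, function(d) {
    smaller <- ds[ds < d]
    length(smaller) == 0L ||
      all(tests$significant[tests$d == d & tests$d_ref %in% smaller])
  }, logical(1))
  d_star <- max(ds[crit1])
  structure(d_star, tests = tests)
}
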