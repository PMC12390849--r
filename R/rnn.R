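#' Tiny recurrent choice models
#'
#' Constructs the specification of a tiny recurrent network: a vanilla GRU
#' (vector inputs), a switching GRU (per-input-condition recurrent weights
#' and biases), or a switching linear network (SLIN), with a fully connected
#' or diagonal readout. The hidden state starts at zero at every session (or
#' training-block) boundary; the policy at trial t is read from the hidden
#' state *before* trial t's input is consumed, so the first trial of a
#' sequence is predicted from h = 0.
#'
#' @param config a [task_config()].
#' @param d hidden size (number of dynamical variables), `>= 1`.
#' @param arch architecture: `"gru"`, `"sgru"` (switching GRU), `"slin"` or
#'   `"slin_sym"` (symmetric-weight SLIN). Default: switching GRU for
#'   `d = 1`, vanilla GRU for `d >= 2`.
#' @param encoding input encoding: `"vector"` (numeric input vector) or
#'   `"selector"` (discrete input code selecting a weight set). Defaults to
#'   the architecture's natural encoding.
#' @param readout `"full"` (dense readout matrix) or `"diagonal"`
#'   (one weight per unit; requires `d` equal to the number of output
#'   scores).
#' @param embedding_dim width of a subject-embedding appended to the input
#'   (teacher networks only; vector encoding only). 0 disables it.
#' @param subjects character vector of subject ids (required when
#'   `embedding_dim > 0`).
#' @return an `rnn_spec` object.
#' @export
rnn_spec <- function(config, d, arch = NULL, encoding = NULL,
                     readout = "full", embedding_dim = 0L,
                     subjects = NULL) {
  if (is.null(arch)) arch <- if (d == 1L) "sgru" else "gru"
  arch <- match.arg(arch, c("gru", "sgru", "slin", "slin_sym"))
  if (is.null(encoding)) encoding <- if (arch == "gru") "vector" else "selector"
  encoding <- match.arg(encoding, c("vector", "selector"))
  if (arch != "gru" && encoding != "selector")
    stop("rnn_spec: switching architectures require the selector encoding")
  if (encoding == "selector" && !config$binary_reward)
    stop("rnn_spec: selector encoding unsupported for continuous rewards")
  ots <- config$task == "two_stage_original"
  n_out <- if (ots) 3L else config$n_actions
  readout <- match.arg(readout, c("full", "diagonal"))
  if (readout == "diagonal" && d != n_out)
    stop("rnn_spec: diagonal readout requires d = ", n_out)
  if (embedding_dim > 0L && encoding != "vector")
    stop("rnn_spec: subject embeddings require the vector encoding")
  if (embedding_dim > 0L && is.null(subjects))
    stop("rnn_spec: subjects required when embedding_dim > 0")
  enc_info <- encoding_info(config, encoding)
  structure(list(
    arch = arch, d = as.integer(d), encoding = encoding, readout = readout,
    n_out = n_out, ots = ots, task = config$task, config = config,
    n_codes = enc_info$n_codes,
    input_dim = enc_info$input_dim + embedding_dim,
    embedding_dim = as.integer(embedding_dim), subjects = subjects
  ), class = "rnn_spec")
}

#' @export
print.rnn_spec <- function(x, ...) {
  cat("<rnn_spec>", x$arch, "d =", x$d, "-", x$encoding, "input,",
      x$readout, "readout; task:", x$task, "\n")
  invisible(x)
}

## input alphabet / dimension for a task + encoding
encoding_info <- function(config, encoding) {
  if (encoding == "selector") {
    n_codes <- if (config$task %in% c("reversal", "reversal_ema"))
      4L else 8L
    list(n_codes = n_codes, input_dim = 0L)
  } else {
    dim <- if (config$task == "two_stage_original") 4L
    else if (config$n_actions > 2L) config$n_actions + 1L
    else 3L
    list(n_codes = 0L, input_dim = dim)
  }
}

#' Encode trials as network inputs
#'
#' Vector encoding: two-action tasks give the 3-vector
#' `(action, state, reward)` with rewards rescaled to \[0, 1\]; n-armed tasks
#' give a one-hot action plus the rescaled reward; the original two-stage
#' task gives `(action, state, action2, reward)`. Selector encoding maps the
#' discrete trial outcome bijectively to an integer code:
#' `1 + 2*action + reward` (4 codes, reversal family) or
#' `1 + 4*action + 2*state + reward` (8 codes, two-stage family).
#'
#' @param data a [session_data()].
#' @param config the task configuration.
#' @param encoding `"vector"` or `"selector"`.
#' @return list with `X` (matrix, vector encoding) or `codes` (integer
#'   vector), plus `starts` (session-start rows).
#' @export
encode_input <- function(data, config, encoding) {
  starts <- session_starts(data)
  if (encoding == "selector") {
    if (!config$binary_reward)
      stop("encode_input: selector encoding needs binary rewards")
    r <- as.integer(data$reward > 0.5)
    codes <- if (config$task %in% c("reversal", "reversal_ema"))
      1L + 2L * data$action + r
    else
      1L + 4L * data$action + 2L * data$state + r
    list(codes = as.integer(codes), starts = starts)
  } else {
    rscale <- config$reward_range[2]
    X <- if (config$task == "two_stage_original") {
      cbind(data$action, data$state, data$action2, data$reward / rscale)
    } else if (config$n_actions > 2L) {
      onehot <- matrix(0, nrow(data), config$n_actions)
      onehot[cbind(seq_len(nrow(data)), data$action + 1L)] <- 1
      cbind(onehot, data$reward / rscale)
    } else {
      cbind(data$action, data$state, data$reward / rscale)
    }
    X[is.na(X)] <- 0
    list(X = X, starts = starts)
  }
}

## append per-trial subject-embedding columns (teacher networks)
append_embedding <- function(enc, data, spec, emb) {
  idx <- match(data$subject, spec$subjects)
  if (anyNA(idx)) stop("unknown subject id in data")
  enc$X <- cbind(enc$X, emb[idx, , drop = FALSE])
  enc$subject_row <- idx
  enc
}

#' Initialize network weights
#'
#' Small uniform initialization on `(-1/sqrt(d), 1/sqrt(d))`.
#'
#' @param spec an [rnn_spec()].
#' @param seed integer seed.
#' @return named list of weight arrays (class `rnn_weights`).
#' @export
rnn_init <- function(spec, seed = 1L) {
  d <- spec$d; k <- spec$input_dim; K <- spec$n_codes
  sc <- 1 / sqrt(d)
  with_local_seed(seed, {
    U <- function(...) array(runif(prod(c(...)), -sc, sc), dim = c(...))
    w <- switch(spec$arch,
      gru = list(Wir = U(d, k), Wiz = U(d, k), Win = U(d, k),
                 Whr = U(d, d), Whz = U(d, d), Whn = U(d, d),
                 bir = U(d, 1)[, 1], biz = U(d, 1)[, 1], bin = U(d, 1)[, 1],
                 bhr = U(d, 1)[, 1], bhz = U(d, 1)[, 1], bhn = U(d, 1)[, 1]),
      sgru = list(Whr = U(d, d, K), Whz = U(d, d, K), Whn = U(d, d, K),
                  bir = U(d, K), biz = U(d, K), bin = U(d, K),
                  bhr = U(d, K), bhz = U(d, K), bhn = U(d, K)),
      slin = ,
      slin_sym = list(W = U(d, d, K), b = U(d, K)))
    if (spec$arch == "slin_sym")
      for (c in seq_len(K)) w$W[, , c] <- sym_project(w$W[, , c])
    w$B <- if (spec$readout == "full") U(spec$n_out, d) else U(d, 1)[, 1]
    if (spec$embedding_dim > 0L)
      w$E <- U(length(spec$subjects), spec$embedding_dim)
    structure(w, class = "rnn_weights")
  })
}

sym_project <- function(W) (W + t(W)) / 2

## --- single-step updates (used by sweeps and interactive agents) -----------

#' Single recurrent update steps
#'
#' Apply one hidden-state update. `gru_step` takes a numeric input vector;
#' `switching_gru_step` and `slin_step` take a 1-based input code selecting
#' the weight set.
#'
#' @param h hidden state vector.
#' @param x input vector (`gru_step`) or integer code (switching variants).
#' @param weights an `rnn_weights` list.
#' @param spec the corresponding [rnn_spec()] (for constraint checks).
#' @return the updated hidden state.
#' @export
gru_step <- function(h, x, weights) {
  w <- weights
  if (length(h) != nrow(w$Whr) || length(x) != ncol(w$Wir))
    stop("gru_step: dimension mismatch")
  r <- logistic(w$Wir %*% x + w$bir + w$Whr %*% h + w$bhr)
  z <- logistic(w$Wiz %*% x + w$biz + w$Whz %*% h + w$bhz)
  n <- tanh(w$Win %*% x + w$bin + r * (w$Whn %*% h + w$bhn))
  as.numeric((1 - z) * n + z * h)
}

#' @rdname gru_step
#' @export
switching_gru_step <- function(h, x, weights) {
  w <- weights
  K <- dim(w$Whr)[3]
  if (!(x %in% seq_len(K))) stop("switching_gru_step: unknown input code ", x)
  r <- logistic(w$bir[, x] + w$Whr[, , x] %*% h + w$bhr[, x])
  z <- logistic(w$biz[, x] + w$Whz[, , x] %*% h + w$bhz[, x])
  n <- tanh(w$bin[, x] + r * (w$Whn[, , x] %*% h + w$bhn[, x]))
  as.numeric((1 - z) * n + z * h)
}

#' @rdname gru_step
#' @export
slin_step <- function(h, x, weights, spec = NULL) {
  w <- weights
  K <- dim(w$W)[3]
  if (!(x %in% seq_len(K))) stop("slin_step: unknown input code ", x)
  if (!is.null(spec) && spec$arch == "slin_sym") {
    W <- matrix(w$W[, , x], length(h), length(h))
    if (max(abs(W - t(W))) > 1e-10)
      stop("slin_step: asymmetric weights under the symmetric variant")
  }
  as.numeric(w$W[, , x] %*% h + w$b[, x])
}

## --- full-sequence forward ---------------------------------------------------

## hidden states for every trial (T x d), resetting at `starts`
rnn_hidden <- function(spec, weights, enc) {
  starts <- as.integer(enc$starts)
  if (spec$arch == "gru") {
    fwd <- cpp_gru_forward(weights[c("Wir", "Wiz", "Win", "Whr", "Whz",
                                     "Whn", "bir", "biz", "bin", "bhr",
                                     "bhz", "bhn")],
                           enc$X, starts)
  } else if (spec$arch == "sgru") {
    fwd <- cpp_sgru_forward(weights[c("Whr", "Whz", "Whn", "bir", "biz",
                                      "bin", "bhr", "bhz", "bhn")],
                            enc$codes, starts)
  } else {
    fwd <- cpp_slin_forward(weights[c("W", "b")], enc$codes, starts)
  }
  fwd
}

## readout scores for a matrix of hidden states
rnn_scores <- function(spec, weights, H) {
  if (spec$readout == "full") H %*% t(weights$B)
  else sweep(H, 2L, weights$B, `*`)
}

#' Readout layer: hidden state to action probabilities
#'
#' Linear readout (full or diagonal, no bias) followed by softmax. For the
#' original two-stage task the three readout scores are the logits of the
#' three choice states and `readout_policy` returns the first-stage policy.
#'
#' @param h hidden state vector.
#' @param spec an [rnn_spec()].
#' @param weights an `rnn_weights` list.
#' @return probability vector.
#' @export
readout_policy <- function(h, spec, weights) {
  s <- as.numeric(rnn_scores(spec, weights, matrix(h, 1L)))
  if (spec$ots) c(logistic(s[1]), 1 - logistic(s[1]))
  else softmax_policy(s, 1)
}

#' Per-trial policies of a recurrent model over session data
#'
#' @param spec an [rnn_spec()].
#' @param weights fitted weights.
#' @param data a [session_data()].
#' @return a `policy_trace` (see [run_cognitive()]).
#' @export
rnn_policy_trace <- function(spec, weights, data) {
  enc <- encode_input(data, spec$config, spec$encoding)
  if (spec$embedding_dim > 0L) enc <- append_embedding(enc, data, spec, weights$E)
  H <- rnn_hidden(spec, weights, enc)$H
  S <- rnn_scores(spec, weights, H)
  if (spec$ots) {
    p1 <- cbind(logistic(S[, 1]), 1 - logistic(S[, 1]))
    ps <- logistic(S[cbind(seq_len(nrow(S)), 2L + data$state)])
    p2 <- cbind(ps, 1 - ps)
  } else {
    p1 <- cpp_row_softmax(S)
    p2 <- NULL
  }
  structure(list(p1 = p1, p2 = p2, model_id = paste0(spec$arch, spec$d),
                 scores = S),
            class = "policy_trace")
}

#' Transform a vanilla GRU into an equivalent switching GRU
#'
#' For discrete inputs, a vanilla GRU is a switching GRU whose recurrent
#' weights do not vary with the input: each input condition's biases absorb
#' the input projection, `b_i.^(x) = W_i. x + b_i.`, while `b_h.` and `W_h.`
#' are shared across conditions.
#'
#' @param weights vanilla-GRU weights.
#' @param spec the vanilla [rnn_spec()].
#' @return list with the switching spec and weights.
#' @export
gru_to_switching <- function(weights, spec) {
  if (spec$arch != "gru") stop("gru_to_switching: expected a vanilla GRU")
  cfg <- spec$config
  sspec <- rnn_spec(cfg, spec$d, arch = "sgru", readout = spec$readout)
  K <- sspec$n_codes
  Xc <- code_vectors(cfg)
  d <- spec$d
  rep_b <- function(b) matrix(b, d, K)
  w <- list(Whr = array(weights$Whr, c(d, d, K)),
            Whz = array(weights$Whz, c(d, d, K)),
            Whn = array(weights$Whn, c(d, d, K)),
            bir = weights$Wir %*% t(Xc) + rep_b(weights$bir),
            biz = weights$Wiz %*% t(Xc) + rep_b(weights$biz),
            bin = weights$Win %*% t(Xc) + rep_b(weights$bin),
            bhr = rep_b(weights$bhr), bhz = rep_b(weights$bhz),
            bhn = rep_b(weights$bhn),
            B = weights$B)
  list(spec = sspec, weights = structure(w, class = "rnn_weights"))
}

## vector encodings of each selector code, in code order
code_vectors <- function(config) {
  if (config$task %in% c("reversal", "reversal_ema")) {
    g <- expand.grid(r = 0:1, a = 0:1)
    cbind(g$a, g$a, g$r)   # state equals action in the reversal task
  } else {
    g <- expand.grid(r = 0:1, s = 0:1, a = 0:1)
    cbind(g$a, g$s, g$r)
  }
}
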