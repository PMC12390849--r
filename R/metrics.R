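#' Stay probabilities by trial type
#'
#' Fraction of trials on which the previous action is repeated, stratified
#' by the previous trial's transition type (common/rare, for probabilistic
#' transition tasks) and reward. Transitions across session boundaries are
#' never counted. Trial types with no observations are reported with
#' `n = 0` and `stay = NA`, not 0.
#'
#' @param data a [session_data()].
#' @param config the matching [task_config()].
#' @return data frame with columns `transition` (`common`/`rare`/`-`),
#'   `rewarded`, `n`, `stay`.
#' @export
stay_probability <- function(data, config) {
  key <- paste(data$subject, data$session)
  n <- nrow(data)
  ok <- which(key[-n] == key[-1])          # t with a valid (t, t+1) pair
  ok <- ok[data$mask[ok] & data$mask[ok + 1L]]
  stay <- data$action[ok + 1L] == data$action[ok]
  rewarded <- data$reward[ok] > 0.5
  deterministic <- all(config$transitions %in% c(0, 1))
  if (deterministic) {
    types <- expand.grid(transition = "-", rewarded = c(TRUE, FALSE),
                         stringsAsFactors = FALSE)
    trans_lab <- rep("-", length(ok))
  } else {
    common <- config$transitions[cbind(data$action[ok] + 1L,
                                       data$state[ok] + 1L)] >= 0.5
    trans_lab <- ifelse(common, "common", "rare")
    types <- expand.grid(transition = c("common", "rare"),
                         rewarded = c(TRUE, FALSE), stringsAsFactors = FALSE)
  }
  out <- lapply(seq_len(nrow(types)), function(i) {
    sel <- trans_lab == types$transition[i] & rewarded == types$rewarded[i]
    data.frame(transition = types$transition[i],
               rewarded = types$rewarded[i], n = sum(sel),
               stay = if (sum(sel)) mean(stay[sel]) else NA_real_)
  })
  do.call(rbind, out)
}

#' Reversal-aligned choice curve
#'
#' Mean probability of choosing the action that was highest-rewarded before
#' the reversal, as a function of trial lag around each block switch, with a
#' normal-approximation confidence band across blocks. Requires the block
#' boundaries recorded by the simulator (or supplied via the `blocks`
#' attribute).
#'
#' @param data a [session_data()] with a `blocks` attribute.
#' @param config the [task_config()].
#' @param window number of trials on each side of the reversal.
#' @param level confidence level for the band.
#' @return data frame with columns `lag` (-window..window-1; lag 0 is the
#'   first post-reversal trial), `p_high`, `lo`, `hi`, `n`.
#' @export
reversal_curve <- function(data, config, window = 10L, level = 0.95) {
  blocks <- attr(data, "blocks")
  if (is.null(blocks))
    stop("reversal_curve: no block boundaries available")
  blocks <- blocks[blocks$type != 0L, , drop = FALSE]  # skip neutral blocks
  zc <- stats::qnorm(1 - (1 - level) / 2)
  rows <- list()
  for (i in seq_len(nrow(blocks) - 1L)) {
    if (blocks$start[i + 1L] != blocks$end[i] + 1L) next  # not adjacent
    if (blocks$type[i + 1L] == blocks$type[i]) next
    rev_t <- blocks$end[i]                  # last trial of the old block
    pre_best <- best_action(config, blocks$type[i])
    for (lag in seq(-window, window - 1L)) {
      t <- rev_t + lag + 1L                 # lag 0 = first trial after
      if (t < 1L || t > nrow(data)) next
      if (lag < 0 && t < blocks$start[i]) next
      if (lag >= 0 && t > blocks$end[i + 1L]) next
      if (!data$mask[t]) next
      rows[[length(rows) + 1L]] <- data.frame(
        lag = lag, high = as.integer(data$action[t] == pre_best))
    }
  }
  if (!length(rows))
    stop("reversal_curve: no reversals found in the block table")
  df <- do.call(rbind, rows)
  agg <- lapply(sort(unique(df$lag)), function(l) {
    x <- df$high[df$lag == l]
    p <- mean(x); se <- sqrt(p * (1 - p) / length(x))
    data.frame(lag = l, p_high = p, lo = max(0, p - zc * se),
               hi = min(1, p + zc * se), n = length(x))
  })
  do.call(rbind, agg)
}

## best first-stage action for a block type (1: state S1 rich, 2: S2 rich)
best_action <- function(config, type) {
  probs <- if (type == 2L) rev(config$reward_probs) else config$reward_probs
  best_state <- which.max(probs)
  which.max(config$transitions[, best_state]) - 1L
}

#' Behaviour-feature identifier
#'
#' Model-agnostic validation tool: simulates class-balanced behavioural
#' sequences from a positive-class and a negative-class generator on
#' identical task settings, trains a tiny recurrent classifier (8-unit
#' switching GRU encoder whose final state feeds a logistic head) to discern
#' the classes, and reports held-out accuracy. An accuracy near 0.5 when the
#' generators coincide guards against leakage.
#'
#' @param positive,negative agents (see [random_agent()]) generating the two
#'   classes.
#' @param config a binary-reward [task_config()].
#' @param n_sequences sequences per class.
#' @param seq_len trials per sequence.
#' @param seed integer seed.
#' @param d encoder size (default 8).
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @return list with `accuracy` (held-out), `scores` (held-out logistic
#'   scores), `labels`, the trained `weights`/`spec`, and `score_fn(data)`
#'   applicable to new sequences.
#' @export
feature_identifier <- function(positive, negative, config,
                               n_sequences = 100L, seq_len = 300L, seed = 1L,
                               d = 8L, epochs = 300L, lr = 0.01) {
  sims <- with_local_seed(seed, {
    lapply(seq_len(2L * n_sequences), function(i) {
      ag <- if (i <= n_sequences) positive else negative
      simulate_task(config, ag, n_trials = seq_len,
                    seed = sample.int(.Machine$integer.max %/% 2L, 1L),
                    subject = sprintf("s%03d", i), session = "1")
    })
  })
  y <- rep(c(1, 0), each = n_sequences)
  spec <- rnn_spec(config, d = d, arch = "sgru")
  enc_of <- function(datasets) {
    codes <- integer(0); starts <- integer(0); ends <- integer(0)
    for (dat in datasets) {
      cd <- encode_input(dat, config, "selector")$codes
      starts <- c(starts, length(codes) + 1L)
      codes <- c(codes, cd, 1L)            # trailing dummy input
      ends <- c(ends, length(codes))       # state after the full sequence
    }
    list(codes = codes, starts = starts, ends = ends)
  }
  enc <- enc_of(sims)
  w0 <- rnn_init(spec, seed)
  w <- list(Whr = w0$Whr, Whz = w0$Whz, Whn = w0$Whn, bir = w0$bir,
            biz = w0$biz, bin = w0$bin, bhr = w0$bhr, bhz = w0$bhz,
            bhn = w0$bhn,
            head_w = rep(0, d), head_b = 0)
  n_all <- length(y)
  test <- with_local_seed(seed + 1L, sample(n_all, round(0.3 * n_all)))
  train <- setdiff(seq_len(n_all), test)
  flat <- flatten_weights(w)
  theta <- flat$theta
  opt <- adam_new(length(theta))
  rec <- c("Whr", "Whz", "Whn", "bir", "biz", "bin", "bhr", "bhz", "bhn")
  for (ep in seq_len(epochs)) {
    w <- restore_weights(theta, flat)
    fwd <- cpp_sgru_forward(w[rec], enc$codes, enc$starts)
    Hend <- fwd$H[enc$ends, , drop = FALSE]
    sc <- as.numeric(Hend %*% w$head_w + w$head_b)
    p <- logistic(sc)
    dsc <- numeric(n_all)
    dsc[train] <- (p - y)[train] / length(train)
    dH <- matrix(0, length(enc$codes), d)
    dH[enc$ends, ] <- dsc * matrix(w$head_w, n_all, d, byrow = TRUE)
    gr <- cpp_sgru_backward(w[rec], enc$codes, fwd, dH, enc$starts)
    gr$head_w <- as.numeric(t(Hend) %*% dsc)
    gr$head_b <- sum(dsc)
    g <- flatten_weights(gr[flat$names])$theta
    opt <- adam_step(opt, g, lr)
    theta <- theta + opt$delta
  }
  w <- restore_weights(theta, flat)
  score_fn <- function(datasets) {
    e <- enc_of(datasets)
    fwd <- cpp_sgru_forward(w[rec], e$codes, e$starts)
    as.numeric(fwd$H[e$ends, , drop = FALSE] %*% w$head_w + w$head_b)
  }
  sc <- score_fn(sims)
  acc <- mean((sc[test] > 0) == (y[test] > 0.5))
  list(accuracy = acc, scores = sc[test], labels = y[test],
       weights = w, spec = spec, score_fn = score_fn)
}
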