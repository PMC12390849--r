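#' Session data: trial-by-trial behavioural records
#'
#' The universal input of the package: a data frame with one row per trial
#' and columns `subject`, `session`, `trial`, `action`, `state`, `reward`,
#' `mask` (and optionally `action2` for the original two-stage task).
#' Action and state codes are 0-based integers (code 0 is the action usually
#' written A1 and the state usually written S1). `mask = FALSE` marks missing
#' trials, which keep placeholder codes but are excluded from all losses.
#'
#' @param df data frame of trials (see Details).
#' @param config the `task_config` the data belong to.
#' @param blocks optional data frame of true block boundaries
#'   (`subject`, `session`, `start`, `end`, `type`) recorded by a simulator.
#' @return a `session_data` object (a data frame with attributes `task` and
#'   optionally `blocks`).
#' @export
session_data <- function(df, config, blocks = NULL) {
  need <- c("subject", "session", "trial", "action", "state", "reward", "mask")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("session_data: missing column(s): ", paste(miss, collapse = ", "))
  df$subject <- as.character(df$subject)
  df$session <- as.character(df$session)
  df$trial <- as.integer(df$trial)
  df$action <- as.integer(df$action)
  df$state <- as.integer(df$state)
  df$reward <- as.numeric(df$reward)
  df$mask <- as.logical(df$mask)
  if ("action2" %in% names(df)) df$action2 <- as.integer(df$action2)
  out <- structure(as.data.frame(df, stringsAsFactors = FALSE),
                   task = config, blocks = blocks,
                   class = c("session_data", "data.frame"))
  validate_session_data(out)
}

validate_session_data <- function(data) {
  cfg <- attr(data, "task")
  ok <- data$mask
  if (any(data$action[ok] < 0L | data$action[ok] >= cfg$n_actions))
    stop("session_data: action code out of range for a ", cfg$n_actions,
         "-action task")
  if (any(data$state[ok] < 0L | data$state[ok] >= cfg$n_states))
    stop("session_data: state code out of range")
  rng <- cfg$reward_range
  if (any(data$reward[ok] < rng[1] - 1e-9 | data$reward[ok] > rng[2] + 1e-9))
    stop("session_data: reward outside task range")
  if (!is.null(cfg$n_actions2) && "action2" %in% names(data)) {
    if (any(data$action2[ok] < 0L | data$action2[ok] >= cfg$n_actions2))
      stop("session_data: second-stage action code out of range")
  }
  key <- paste(data$subject, data$session)
  for (k in unique(key)) {
    tr <- data$trial[key == k]
    if (is.unsorted(tr, strictly = TRUE))
      stop("session_data: trials within a session must be strictly increasing")
  }
  data
}

#' @export
print.session_data <- function(x, ...) {
  cfg <- attr(x, "task")
  cat("<session_data>", nrow(x), "trials,",
      length(unique(x$subject)), "subject(s),",
      length(unique(paste(x$subject, x$session))), "session(s); task:",
      cfg$task, "\n")
  invisible(x)
}

#' Read and write session tables
#'
#' Sessions are stored as plain CSV with a header row and one row per trial
#' (columns `subject,session,trial,action,state,reward,mask[,action2]`);
#' codes are validated against `task_config`.
#'
#' @param path CSV file path.
#' @param task_config the task the file belongs to.
#' @return `read_sessions` returns a validated `session_data`.
#' @export
read_sessions <- function(path, task_config) {
  if (!file.exists(path)) stop("read_sessions: no such file: ", path)
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("read_sessions: parse error: ",
                                          conditionMessage(e)))
  bad <- which(!stats::complete.cases(df[c("subject", "session", "trial",
                                           "action")]))
  if (length(bad))
    stop("read_sessions: malformed row(s): ", paste(bad, collapse = ", "))
  session_data(df, task_config)
}

#' @param data a `session_data`.
#' @rdname read_sessions
#' @export
write_sessions <- function(data, path) {
  write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Segment sessions into cross-validation blocks
#'
#' Cuts every session into consecutive, non-overlapping blocks of
#' approximately `target_len` trials (blocks never span sessions) and deals
#' the blocks into `n_folds` folds. A trailing fragment shorter than half
#' the target length is merged into the preceding block of the same session.
#' Fold assignment shuffles the blocks once with `seed` and deals them
#' round-robin, balancing temporal structure across folds.
#'
#' @param data a `session_data`.
#' @param target_len target block length in trials (default 150).
#' @param n_folds number of folds (default 10).
#' @param seed integer seed for the fold shuffle.
#' @return a `block_partition`: data frame with columns `subject`, `session`,
#'   `start`, `end` (row indices into `data`) and `fold` (0-based).
#' @export
segment_blocks <- function(data, target_len = 150L, n_folds = 10L, seed = 1L) {
  stopifnot(target_len >= 2L, n_folds >= 2L, nrow(data) > 0L)
  key <- paste(data$subject, data$session)
  blocks <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    n <- length(idx)
    n_blk <- max(1L, round(n / target_len))
    cuts <- floor(seq(0L, n, length.out = n_blk + 1L))
    for (b in seq_len(n_blk)) {
      s <- cuts[b] + 1L
      e <- cuts[b + 1L]
      if (e < s) next
      blocks[[length(blocks) + 1L]] <- data.frame(
        subject = data$subject[idx[1]], session = data$session[idx[1]],
        start = idx[s], end = idx[e], stringsAsFactors = FALSE)
    }
  }
  blocks <- do.call(rbind, blocks)
  ## merge sub-half fragments into the preceding block of the same session
  keep <- rep(TRUE, nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    len <- blocks$end[i] - blocks$start[i] + 1L
    if (len < target_len / 2 && i > 1L &&
        blocks$session[i] == blocks$session[i - 1L] &&
        blocks$subject[i] == blocks$subject[i - 1L] && keep[i - 1L]) {
      blocks$end[i - 1L] <- blocks$end[i]
      keep[i] <- FALSE
    }
  }
  blocks <- blocks[keep, , drop = FALSE]
  if (nrow(blocks) < n_folds)
    stop("segment_blocks: fewer blocks (", nrow(blocks),
         ") than folds (", n_folds, ")")
  ord <- with_local_seed(seed, sample.int(nrow(blocks)))
  fold <- integer(nrow(blocks))
  fold[ord] <- (seq_along(ord) - 1L) %% n_folds
  blocks$fold <- fold
  rownames(blocks) <- NULL
  structure(blocks, target_len = target_len, n_folds = n_folds,
            class = c("block_partition", "data.frame"))
}

## row indices of the trials belonging to a set of folds
fold_indices <- function(partition, folds) {
  rows <- partition$fold %in% folds
  unlist(mapply(seq, partition$start[rows], partition$end[rows],
                SIMPLIFY = FALSE), use.names = FALSE)
}

## block start rows, used to reset recurrent state during training
partition_starts <- function(partition) sort(partition$start)
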