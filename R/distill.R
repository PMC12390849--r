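#' Teacher network specification
#'
#' A teacher is a (default 20-unit) vanilla GRU over all subjects' data in
#' which each subject's one-hot id is projected through a trainable linear
#' layer into an embedding vector appended to every trial's input.
#'
#' @param config a [task_config()].
#' @param subjects character vector of subject ids.
#' @param d hidden size (default 20).
#' @param embedding_dim embedding width (default 2).
#' @return an [rnn_spec()] with subject embeddings.
#' @export
teacher_spec <- function(config, subjects, d = 20L, embedding_dim = 2L) {
  rnn_spec(config, d = d, arch = "gru", encoding = "vector",
           readout = "full", embedding_dim = embedding_dim,
           subjects = subjects)
}

#' Teacher policies for multi-subject data
#'
#' @param spec a [teacher_spec()].
#' @param weights trained teacher weights.
#' @param data multi-subject [session_data()]; every subject must be known
#'   to the spec.
#' @return a `policy_trace` aligned with `data`.
#' @export
teacher_forward <- function(spec, weights, data) {
  if (!all(data$subject %in% spec$subjects))
    stop("teacher_forward: unknown subject id")
  rnn_policy_trace(spec, weights, data)
}

#' Distillation loss
#'
#' Cross-entropy between the teacher's and the student's next-trial action
#' probabilities, summed over masked-in trials:
#' `-sum_t sum_a pT(a) log pS(a)`.
#'
#' @param teacher,student aligned `policy_trace` objects.
#' @param mask logical vector of scored trials (default: all).
#' @return total loss (numeric scalar).
#' @export
distillation_loss <- function(teacher, student, mask = NULL) {
  if (!identical(dim(teacher$p1), dim(student$p1)))
    stop("distillation_loss: misaligned policy traces")
  mask <- mask %||% rep(TRUE, nrow(teacher$p1))
  ce <- -rowSums(teacher$p1 * log(floor_prob(student$p1)))
  if (!is.null(teacher$p2)) {
    if (is.null(student$p2)) stop("distillation_loss: misaligned traces")
    ce <- ce - rowSums(teacher$p2 * log(floor_prob(student$p2)))
  }
  sum(ce[mask])
}

#' Symmetry augmentation for two-action, two-state tasks
#'
#' Returns the original data plus the action-flipped, state-flipped and
#' doubly flipped copies (4x the size). Rewards, masks and block structure
#' are unchanged within each copy; flipped copies get suffixed session ids.
#'
#' @param data a [session_data()].
#' @param config the matching [task_config()]; tasks without the symmetry
#'   (more than two actions/states, or tasks where action and state are the
#'   same coordinate) are rejected.
#' @return an augmented [session_data()] with a `copy` column
#'   (`orig`, `fa`, `fs`, `fas`).
#' @export
augment_by_symmetry <- function(data, config) {
  if (config$n_actions != 2L || config$n_states != 2L ||
      isTRUE(all.equal(config$transitions, diag(2))))
    stop("augment_by_symmetry: task lacks the action/state flip symmetry")
  flip <- function(df, fa, fs, tag) {
    if (fa) df$action <- 1L - df$action
    if (fs) df$state <- 1L - df$state
    df$session <- paste0(df$session, "_", tag)
    df$copy <- tag
    df
  }
  base <- as.data.frame(data)
  base$copy <- "orig"
  out <- rbind(base,
               flip(as.data.frame(data), TRUE, FALSE, "fa"),
               flip(as.data.frame(data), FALSE, TRUE, "fs"),
               flip(as.data.frame(data), TRUE, TRUE, "fas"))
  session_data(out, config, blocks = attr(data, "blocks"))
}

#' Knowledge-distillation pipeline
#'
#' Trains a subject-embedding teacher on the group data, then distils it
#' into a tiny per-subject student, and fits a "solo" network of the same
#' size directly to the target subject's choices for comparison.
#'
#' Under the `"m_split"` protocol, the target subject M's trials are split
#' into 25\% held-out M-test and 75\% pool, of which `m_trials` are sampled
#' and divided 90/10 into M-training and M-validation; all other subjects
#' contribute 90/10 O-training/O-validation trials. The teacher is trained
#' on M+O training trials (never touching M-test); the student is trained on
#' the symmetry-augmented M-training trials against the teacher's
#' probabilities, selected on M-validation, and evaluated on M-test against
#' actual choices. Under `"cross_subject"` the teacher is trained on the
#' other subjects only.
#'
#' @param data multi-subject [session_data()].
#' @param target subject id of the target individual.
#' @param config the [task_config()].
#' @param student_d student hidden size (default 1).
#' @param teacher_d teacher hidden size (default 20).
#' @param embedding_grid embedding widths tried on M-validation.
#' @param m_trials number of target-subject trials used for training +
#'   validation (default: the whole 75\% pool).
#' @param protocol `"m_split"` or `"cross_subject"`.
#' @param fit a [fit_config()].
#' @param seed integer seed.
#' @param augment use symmetry augmentation for the student (default TRUE).
#' @return list with per-trial held-out NLLs (`student_nll`, `solo_nll`,
#'   `teacher_nll`), the fitted models, and the index sets used.
#' @export
distill_pipeline <- function(data, target, config, student_d = 1L,
                             teacher_d = 20L, embedding_grid = c(1L, 2L),
                             m_trials = NULL, protocol = "m_split",
                             fit = fit_config(l1_grid = 1e-4, seeds = 1L),
                             seed = 1L, augment = TRUE) {
  protocol <- match.arg(protocol, c("m_split", "cross_subject"))
  subjects <- unique(data$subject)
  if (!target %in% subjects) stop("distill_pipeline: unknown target subject")
  m_rows <- which(data$subject == target)
  o_rows <- which(data$subject != target)
  with_local_seed(seed, {
    perm <- sample(m_rows)
    n_test <- floor(0.25 * length(m_rows))
    m_test <- sort(perm[seq_len(n_test)])
    pool <- sort(perm[-seq_len(n_test)])
    if (!is.null(m_trials)) {
      if (m_trials < 1L) stop("distill_pipeline: no M-training trials")
      pool <- sort(sample(pool, min(m_trials, length(pool))))
    }
    n_val <- max(1L, floor(0.1 * length(pool)))
    vsel <- sample(seq_along(pool), n_val)
    m_val <- pool[vsel]; m_train <- pool[-vsel]
    if (length(m_train) == 0L)
      stop("distill_pipeline: no M-training trials")
    ovsel <- sample(seq_along(o_rows), max(1L, floor(0.1 * length(o_rows))))
    o_val <- o_rows[ovsel]; o_train <- o_rows[-ovsel]
  })

  t_train <- if (protocol == "m_split") c(m_train, o_train) else o_train
  t_val <- if (protocol == "m_split") c(m_val, o_val) else o_val
  stopifnot(length(intersect(t_train, m_test)) == 0L)

  ## teacher, embedding width selected on M-validation
  teachers <- lapply(embedding_grid, function(ed) {
    sp <- teacher_spec(config, subjects, d = teacher_d, embedding_dim = ed)
    r <- train_rnn(sp, data, t_train, t_val, fit, seed = seed)
    tr <- rnn_policy_trace(sp, r$weights, data)
    mval <- negative_log_likelihood(tr, data, m_val)$nll_per_trial
    list(spec = sp, weights = r$weights, m_val = mval)
  })
  teacher <- teachers[[which.min(vapply(teachers, `[[`, 0, "m_val"))]]

  ## target-subject view, optionally augmented fourfold
  m_data <- session_data(as.data.frame(data)[m_rows, ], config)
  map_idx <- function(rows) match(rows, m_rows)   # rows within m_data
  s_train0 <- map_idx(m_train); s_val0 <- map_idx(m_val)
  s_test0 <- map_idx(m_test)
  if (augment) {
    s_data <- augment_by_symmetry(m_data, config)
    nm <- nrow(m_data)
    rep_idx <- function(i) as.vector(outer(i, (0:3) * nm, `+`))
    s_train <- rep_idx(s_train0)
    s_val <- rep_idx(s_val0)
  } else {
    s_data <- m_data
    s_train <- s_train0; s_val <- s_val0
  }
  t_sub <- s_data
  t_sub$subject <- target   # teacher scores augmented copies as subject M
  teacher_trace <- teacher_forward(teacher$spec, teacher$weights, t_sub)

  sspec <- rnn_spec(config, d = student_d)
  student <- train_rnn(sspec, s_data, s_train, s_val, fit, seed = seed,
                       teacher = teacher_trace)
  solo <- train_rnn(sspec, m_data, s_train0, s_val0, fit, seed = seed)

  s_trace <- rnn_policy_trace(sspec, student$weights, m_data)
  solo_trace <- rnn_policy_trace(sspec, solo$weights, m_data)
  t_trace_m <- teacher_forward(teacher$spec, teacher$weights, m_data)
  list(
    student_nll = negative_log_likelihood(s_trace, m_data,
                                          s_test0)$nll_per_trial,
    solo_nll = negative_log_likelihood(solo_trace, m_data,
                                       s_test0)$nll_per_trial,
    teacher_nll = negative_log_likelihood(t_trace_m, m_data,
                                          s_test0)$nll_per_trial,
    student = list(spec = sspec, weights = student$weights),
    solo = list(spec = sspec, weights = solo$weights),
    teacher = teacher[c("spec", "weights")],
    idx = list(m_train = m_train, m_val = m_val, m_test = m_test)
  )
}
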