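#' Softmax choice rule
#'
#' Converts a vector of action scores into choice probabilities,
#' `p_i = exp(beta * s_i) / sum_j exp(beta * s_j)`, computed with
#' max-subtraction for numerical stability.
#'
#' @param scores numeric vector of finite action scores.
#' @param beta inverse temperature, `beta >= 0`. `beta = 0` gives the uniform
#'   policy.
#' @return probability vector of the same length as `scores`.
#' @export
#' @examples
#' softmax_policy(c(1, 0), beta = log(3)) # c(0.75, 0.25)
softmax_policy <- function(scores, beta = 1) {
  if (!all(is.finite(scores))) stop("softmax_policy: non-finite score")
  if (beta < 0) stop("softmax_policy: beta must be >= 0")
  z <- beta * scores
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

logistic <- function(x) 1 / (1 + exp(-x))
logit <- function(p) log(p) - log1p(-p)

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
inv_softplus <- function(y) ifelse(y > 30, y, log(expm1(y)))

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package internals do not
#' perturb the caller's RNG stream.
#' @noRd
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## row index bookkeeping: first trial row of every session in a session table
session_starts <- function(df) {
  key <- paste(df$subject, df$session)
  which(key != c("", key[-length(key)]))
}
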