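#' @importFrom stats rexp rnorm runif rpois rbinom median sd var cor qlogis
#' @importFrom stats plogis pnorm pt qt ptukey t.test cor.test glm binomial
#' @importFrom stats coef lm anova quantile uniroot dnorm fft mvfft nextn
#' @importFrom stats aggregate predict qbeta complete.cases optim
#' @importFrom utils head tail
#' @import data.table
NULL

.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Saves the current `.Random.seed`, seeds the generator, evaluates `code`,
#' and restores the previous RNG state on exit. Used throughout so that
#' stimulus streams keyed by (seed_id, side) are bitwise reproducible without
#' disturbing the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  code
}

#' Derive a reproducible child seed from integer components
#'
#' Mixes the components with a multiplicative hash modulo 2^31 - 1 so that
#' distinct (session, stream, id) tuples map to distinct, valid integer seeds.
#'
#' @param ... integer components.
#' @return A single integer in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(...) {
  ids <- as.numeric(c(...))
  m <- 2147483647
  s <- 11
  for (k in ids) s <- (s * 7919 + (k %% m) + 1) %% m
  as.integer(s)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

gaussian_kernel <- function(sd, radius = ceiling(3 * sd)) {
  if (sd <= 0) return(1)
  k <- dnorm(seq(-radius, radius), sd = sd)
  k / sum(k)
}

# 1-d convolution with edge replication, same length as x
smooth_replicate <- function(x, kernel) {
  if (length(kernel) == 1L) return(x)
  r <- (length(kernel) - 1L) / 2L
  xp <- c(rep(x[1L], r), x, rep(x[length(x)], r))
  as.numeric(stats::filter(xp, kernel, sides = 2L))[(r + 1L):(r + length(x))]
}
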