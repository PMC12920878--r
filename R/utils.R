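# Internal helpers shared across modules.

#' @importFrom stats rnorm runif rbinom qnorm pnorm sd var cov predict
#' @importFrom utils head write.csv read.csv
NULL

# Deterministic child seed for stream `i` under tag `tag`; stays below 2^31.
child_seed <- function(seed, i, tag = 0L) {
  s <- (as.double(seed) * 1009 + as.double(i) * 7919 + as.double(tag) * 104729) %% 2147483587
  as.integer(s) + 1L
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_binary <- function(x) all(x %in% c(0, 1))

# Stable hash of an R object (used to fingerprint run configurations).
config_hash <- function(x) rlang::hash(x)

clip01 <- function(x) pmin(pmax(x, 0), 1)
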