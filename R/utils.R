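#' @importFrom methods new validObject is slot
#' @importFrom stats prcomp rnorm runif rnbinom sd var predict coef
#'   wilcox.test ks.test quantile dnorm setNames lm
#' @importFrom utils read.table write.table read.csv write.csv packageVersion
#'   head tail
NULL

# Deterministic per-stage seed derivation from a master seed. Keeps results
# below 2^31 so the value is a valid R integer seed.
deriveSeed <- function(seed, offset = 0L) {
  s <- (as.double(seed) %% 2147483647) + 1
  s <- (s * 48271 + as.double(offset) * 65537 + 12345) %% 2147483647
  as.integer(s)
}

# Evaluate `expr` under a temporary RNG state; global .Random.seed restored.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with a class so callers can distinguish schema vs integrity problems
polyenStop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(class = c(class, "polyenError", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
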