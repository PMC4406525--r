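#' @include AllClasses.R
NULL

## Run `expr` under a temporary RNG state seeded with `seed`, restoring the
## caller's .Random.seed afterwards.  Every stochastic operation in the
## package routes through this so that one seed argument fully determines
## its output without disturbing the session RNG.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

## clamp a scalar into [lo, hi]
.clamp <- function(x, lo, hi) min(max(x, lo), hi)
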