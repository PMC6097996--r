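## Isolated RNG streams.
##
## Seeded package functions must not disturb the caller's global RNG state,
## and independent streams (e.g. one per virtual participant) must be
## derivable from one master seed. local_rng() wraps a private .Random.seed
## that is swapped in around each draw.

local_rng <- function(seed) {
  state <- NULL
  with_state <- function(expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      state <<- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    if (is.null(state)) set.seed(seed)
    else assign(".Random.seed", state, globalenv())
    expr
  }
  list(
    permutation = function(n) with_state(sample.int(n)),
    choose = function(n, k) with_state(sample.int(n, k)),
    pick = function(x) with_state(x[sample.int(length(x), 1L)]),
    unif = function(n) with_state(stats::runif(n)),
    norm = function(n) with_state(stats::rnorm(n)),
    bern = function(p) with_state(as.integer(stats::runif(length(p)) < p)),
    sub_seeds = function(n) with_state(
      sample.int(.Machine$integer.max - 1L, n))
  )
}

## Derive n child seeds from one master seed (for per-participant streams).
derive_seeds <- function(seed, n) {
  local_rng(seed)$sub_seeds(n)
}
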