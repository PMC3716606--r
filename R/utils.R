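# Isolated RNG stream: draws are reproducible from `seed` and never disturb
# the caller's .Random.seed.
local_rng <- function(seed) {
  state <- NULL
  draw <- function(fn, ...) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    if (is.null(state)) set.seed(seed) else {
      assign(".Random.seed", state, envir = globalenv())
    }
    out <- fn(...)
    state <<- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    out
  }
  list(
    runif = function(n, min = 0, max = 1) draw(stats::runif, n, min, max),
    rnorm = function(n, mean = 0, sd = 1) draw(stats::rnorm, n, mean, sd),
    rlnorm = function(n, meanlog = 0, sdlog = 1) {
      draw(stats::rlnorm, n, meanlog, sdlog)
    },
    rpois = function(n, lambda) draw(stats::rpois, n, lambda),
    sample = function(x, size, replace = FALSE) {
      draw(base::sample, x, size, replace)
    }
  )
}
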