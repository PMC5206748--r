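## Seeded-RNG helpers: generators take an explicit seed and never disturb
## the caller's global RNG state.

#' Evaluate with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# a private RNG stream: each draw resumes this stream's state and leaves the
# global stream untouched
localRng <- function(seed) {
  state <- NULL
  draw <- function(fn, ...) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    if (is.null(state)) set.seed(seed)
    else assign(".Random.seed", state, envir = globalenv())
    out <- fn(...)
    state <<- get(".Random.seed", envir = globalenv())
    out
  }
  list(rnorm = function(...) draw(stats::rnorm, ...),
       runif = function(...) draw(stats::runif, ...),
       sample = function(...) draw(base::sample, ...))
}
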