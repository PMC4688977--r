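# Internal helpers: deterministic seed substreams and small utilities.

#' Derive a deterministic substream seed
#'
#' All stochastic operations take one user-facing seed; internally each
#' operation draws from its own substream derived from that seed and a short
#' tag, so adding a step never perturbs the randomness of another.
#'
#' @param seed integer master seed.
#' @param tag character tag naming the substream.
#' @return An integer seed in [0, 2^31 - 2].
#' @keywords internal
substream_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)) * 2654435761) %% 2147483647
  as.integer((abs(seed) %% 2147483647 + h) %% 2147483646) + 1L
}

# Evaluate expr with a local RNG state seeded from (seed, tag).
with_substream <- function(seed, tag, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(substream_seed(seed, tag))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Pearson correlation that returns NA (not an error/NaN) for constant input.
safe_cor <- function(x, y) {
  if (length(x) < 2L || sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

stop_ovimp <- function(...) stop(sprintf(...), call. = FALSE)
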