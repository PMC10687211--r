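# Internal helpers: seeded evaluation, seed derivation, content hashing.

# Evaluate expr under a temporary RNG state; restores the caller's stream.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage-specific seed from a global seed
#'
#' Every stochastic stage of a pipeline run draws its seed deterministically
#' from the global seed and a short stage tag, so that one integer reproduces
#' the whole run while stages remain decorrelated.
#'
#' @param seed integer global seed.
#' @param tag character stage tag (e.g. `"pretrain"`, `"split"`).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
deriveSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% (2^31 - 1))
}

# FNV-1a style 32-bit hash of a character vector; stable across sessions.
contentHash <- function(x) {
  s <- paste(x, collapse = "")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (as.numeric(h) * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

# Truncated-normal init (clipped resampling at 2 sd), standard for transformers.
rtruncnorm <- function(n, sd = 0.02) {
  x <- rnorm(n, 0, sd)
  bad <- abs(x) > 2 * sd
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), 0, sd)
    bad <- abs(x) > 2 * sd
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
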