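#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded internals do
#' not disturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Deterministic per-sample stream: fold (seed, index) into one 31-bit seed.
derive_seed <- function(seed, index) {
  s <- (abs(as.double(seed)) %% 1e6) * 1009 + abs(as.double(index)) * 9176 + 1
  as.integer(s %% 2147483629)
}

# round-half-up, elementwise
round_half_up <- function(x) floor(x + 0.5)

stopifnot_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("inputs must share the same raster shape", call. = FALSE)
}
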