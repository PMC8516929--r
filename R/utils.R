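# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state so callers never perturb the session stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# Private RNG streams for iterators/loops: an environment carries its own
# .Random.seed so interleaved consumers stay deterministic.
rng_env <- function(seed) {
  e <- new.env(parent = emptyenv())
  e$rng <- with_seed(seed, get(".Random.seed", envir = globalenv()))
  e
}

rng_eval <- function(env, fn) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", env$rng, envir = globalenv())
  tryCatch(fn(), finally = {
    env$rng <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
}

#' Derive a per-item seed from a parent seed
#'
#' Fixed integer hash `(seed * 48271 + index * 104729) mod (2^31 - 1)` mapped
#' into `[1, 2^31 - 2]`, so cohorts are stable under reordering and every
#' derived seed is a valid 32-bit R seed. Arithmetic stays below 2^53 and is
#' therefore exact in doubles.
#'
#' @param seed parent integer seed.
#' @param index 1-based item index.
#' @return integer seed.
#' @export
derive_seed <- function(seed, index) {
  m <- 2147483647
  h <- ((as.double(seed) %% m) * 48271 + as.double(index) * 104729) %% m
  as.integer(h %% (m - 1) + 1)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# 8-bit quantisation rule used everywhere a fractional gray value becomes a
# stored pixel: round half up, clip to [0, 255].
quantize8 <- function(x) clamp(floor(x + 0.5), 0, 255)

is_count <- function(x, min = 0) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x == floor(x) && x >= min
}

wsi_log <- function(fmt, ..., file = NULL) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  sprintf(fmt, ...))
  message(line)
  if (!is.null(file)) cat(line, "\n", file = file, append = TRUE, sep = "")
  invisible(line)
}
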