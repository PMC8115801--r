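#' Derive a child seed from a master seed
#'
#' One global seed fans out deterministically to per-stage / per-subject
#' child seeds so that stages can be rerun in isolation and cohorts are
#' reproducible subject by subject.
#'
#' @param seed integer master seed.
#' @param salt integer distinguishing the consumer (stage index, subject
#'   index, ...).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, salt) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(salt))
  m <- 2147483647
  # multiplicative congruential step; all intermediates stay below 2^53
  as.integer(((seed %% m) * 48271 + salt * 8191 + 1) %% m)
}

# Run `expr` under a local RNG state seeded with `seed`; if seed is NULL the
# current global RNG stream is used (and advanced).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mw <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}

assert_that <- function(cond, stage, msg) {
  if (!isTRUE(cond)) stop_mw(stage, msg)
  invisible(TRUE)
}
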