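# Internal helpers: classed errors, seed derivation, RNG scoping.

ms_error <- function(class, msg, ..., call = sys.call(-1)) {
  stop(structure(
    class = c(class, "mpnnscreen_error", "error", "condition"),
    list(message = msg, call = call, ...)
  ))
}

config_error     <- function(msg, ...) ms_error("ms_config_error", msg, ...)
format_error     <- function(msg, ...) ms_error("ms_format_error", msg, ...)
parse_error      <- function(msg, ...) ms_error("ms_parse_error", msg, ...)
conflict_error   <- function(msg, ...) ms_error("ms_conflict_error", msg, ...)
generation_error <- function(msg, ...) ms_error("ms_generation_error", msg, ...)
split_error      <- function(msg, ...) ms_error("ms_split_error", msg, ...)
training_error   <- function(msg, ...) ms_error("ms_training_error", msg, ...)
incompat_error   <- function(msg, ...) ms_error("ms_incompat_error", msg, ...)
io_error         <- function(msg, ...) ms_error("ms_io_error", msg, ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed and a tag
#'
#' Distinct pipeline stages (generation, splitting, weight initialisation,
#' shuffling, resampling) draw from independent streams derived
#' deterministically from one master seed, so that rerunning a single stage
#' never perturbs another. The result is always a valid 32-bit R seed.
#'
#' @param seed integer master seed.
#' @param tag character stream label.
#' @return a single integer in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopifnot_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    config_error(sprintf("'%s' must be TRUE or FALSE", name))
}
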