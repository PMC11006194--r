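# Condition helpers. Every user-facing error carries a subclass so that
# callers (and the command-line wrapper) can map failures to exit codes:
# validation -> 2, capacity -> 3.

abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "moranamp_error")))
}
abort_validation <- function(msg) abort(msg, "moranamp_validation_error")
abort_lookup     <- function(msg) abort(msg, c("moranamp_lookup_error", "moranamp_validation_error"))
abort_capacity   <- function(msg) abort(msg, "moranamp_capacity_error")
abort_absorbing  <- function(msg) abort(msg, c("moranamp_absorbing_error", "moranamp_validation_error"))
abort_invariant  <- function(msg) abort(msg, "moranamp_invariant_error")
abort_family     <- function(msg) abort(msg, c("moranamp_family_error", "moranamp_validation_error"))

# Evaluate `code` under a fixed seed without disturbing the caller's RNG
# stream. With seed = NULL the expression runs on the ambient stream.
with_preserved_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

check_scalar_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    abort_validation(sprintf("`%s` must be a single integer >= %s", name, min))
  }
  as.integer(x)
}

check_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort_validation(sprintf("`%s` must be a single positive number", name))
  }
  as.numeric(x)
}
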