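# Condition helpers. Every error raised by the package carries a specific
# class under the common "derephits_error" class so callers can distinguish
# parse, schema, integrity, contract, ... failures programmatically.

derep_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "derephits_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run an expression under a fixed RNG seed, restoring the caller's RNG state.
with_preserved_seed <- function(seed, expr) {
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

# Re-raise any error from a pipeline stage with the stage name prepended.
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(
      sprintf("[stage: %s] %s", stage, conditionMessage(e)),
      class = unique(c(class(e), "derephits_stage_error"))))
  })
}
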