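# Internal helpers shared across modules.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, restoring the caller's
#' RNG state afterwards so library code never perturbs user randomness.
#' @keywords internal
#' @noRd
withSeed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# stop() with a classed condition so callers can distinguish format errors
# (malformed files) from validation errors (well-formed but inconsistent).
formatError <- function(...) {
  stop(errorCondition(paste0(...), class = c("primenet_format_error", "error")))
}
validationError <- function(...) {
  stop(errorCondition(paste0(...), class = c("primenet_validation_error", "error")))
}

isDnaString <- function(x) {
  nzchar(x) & !grepl("[^ACGT]", x)
}

logMsg <- function(...) message("[primenet] ", ...)
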