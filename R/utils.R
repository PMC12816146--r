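#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stage-scoped timestamped logging to standard error
#' @noRd
ds_log <- function(stage, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste0(..., collapse = "")))
}

#' Deterministic child seed derivation; stays below 2^31
#' @noRd
derive_seed <- function(base_seed, offset) {
  as.integer((as.numeric(base_seed) * 7919 + offset) %% 2147483647)
}

#' Run an expression under a locally scoped RNG seed, restoring the caller's
#' RNG state afterwards so package internals never perturb user randomness.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
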