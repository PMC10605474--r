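# Internal helpers: structured conditions and reproducible RNG scoping.

#' @keywords internal
"_PACKAGE"

# All package errors carry class c("ogmstr_<what>", "ogmstr_error", "error").
# Tests and the CLI dispatch on the subclass.
stop_ogmstr <- function(what, msg, ..., call = sys.call(-1)) {
  cond <- errorCondition(
    sprintf(msg, ...),
    class = c(paste0("ogmstr_", what), "ogmstr_error"),
    call = call
  )
  stop(cond)
}

warn_ogmstr <- function(what, msg, ...) {
  cond <- warningCondition(
    sprintf(msg, ...),
    class = c(paste0("ogmstr_", what), "ogmstr_warning")
  )
  warning(cond)
}

# Evaluate `expr` under set.seed(seed) without disturbing the caller's RNG
# stream.  Every stochastic routine in the package funnels through this, so
# results are a pure function of (inputs, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == as.integer(x) && x > 0
}

`%||%` <- function(a, b) if (is.null(a)) b else a
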