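#' Evaluate an expression under a temporary RNG state
#'
#' Runs \code{expr} with the random-number generator seeded to \code{seed}
#' and restores the caller's RNG state afterwards, so seeded operations do
#' not perturb the global random stream.
#'
#' @param seed Integer seed, or \code{NULL} to use the current stream.
#' @param expr Expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Derive a child seed from a master seed
#'
#' Deterministic mixing used to hand independent substreams to pipeline
#' stages; keeps results below 2^31 so they remain valid R integers.
#'
#' @param seed Master integer seed.
#' @param offset Stage offset (small integer).
#' @return An integer seed.
#' @keywords internal
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 65537) %% 2147483629)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop2 <- function(...) stop(..., call. = FALSE)
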