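#' @keywords internal
"_PACKAGE"

#' @importFrom stats quantile sd cor optimize phyper runif setNames aggregate
#' @importFrom utils read.delim write.table combn head
NULL

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so package functions never clobber the session stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Derive a replicate seed from a base seed; kept below 2^31 - 1.
derive_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 48271 + index * 8191) %% 2147483587
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_kpnet <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "kpnet_error")))
}
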