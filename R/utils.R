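#' @importFrom stats cor qnorm pnorm pt pchisq pbinom dbinom rbinom rnbinom
#'   rnorm runif rhyper prcomp lm glm binomial coef p.adjust complete.cases
#'   smooth.spline predict quantile median sd var setNames ks.test rbeta
#' @importFrom utils head read.delim write.table packageVersion
#' @importFrom data.table data.table as.data.table setDF fread fwrite .N
NULL

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library calls never perturb user-level randomness.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stopf(fmt, ...)
  invisible(TRUE)
}

# Derive a stream-specific 31-bit seed from a base seed, so independent
# simulator stages draw from decoupled streams.
derive_seed <- function(seed, stream) {
  x <- (as.double(seed) * 48271 + stream * 2654435761) %% 2147483647
  as.integer(max(1, x))
}
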