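#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef lm median predict rbinom rnorm runif sd var
#' @importFrom utils read.csv write.csv packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so package functions never clobber the global stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a master seed; kept strictly below 2^31.
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(k)) %% 2147483647)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_if_not_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
}

bp_log <- function(...) {
  if (isTRUE(getOption("pinholebp.verbose", FALSE))) {
    message(sprintf(...))
  }
  invisible(NULL)
}
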