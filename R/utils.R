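#' Signal a classed sricp error
#'
#' All user-facing failures in the package raise conditions with class
#' `c(class, "sricp_error", "error")` so callers (and tests) can distinguish
#' e.g. a malformed PLY header from a degenerate-geometry failure.
#'
#' @param msg message
#' @param class condition subclass, e.g. "sricp_degenerate"
#' @noRd
sricp_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "sricp_error"), call = call))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-stage RNG seed from a global seed
#'
#' A single pipeline seed fans out deterministically to stage seeds by hashing
#' the stage name (Knuth multiplicative hash), so each stage is individually
#' reproducible. Results stay within the 32-bit signed integer range.
#'
#' @param seed integer global seed
#' @param stage character stage name
#' @return integer seed
#' @export
#' @examples
#' fan_out_seed(7, "ransac")
fan_out_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% 2147483647
  as.integer((h + as.numeric(seed) * 2654435761) %% 2147483647)
}

# Evaluate expr with a local RNG state: seeds with `seed` if non-NULL and
# restores the caller's .Random.seed afterwards.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
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

# row-wise euclidean norms of an N x 3 matrix
row_norms <- function(m) sqrt(rowSums(m * m))
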