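#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global random-number generator seeded at `seed`,
#' restoring the caller's RNG state afterwards so library functions do not
#' clobber user-level reproducibility. A `NULL` seed evaluates `code` under
#' the current RNG state.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# upper-triangular (i < j) pair indices of an N x N matrix
upper_pairs <- function(n) {
  which(upper.tri(matrix(0L, n, n)), arr.ind = TRUE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
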