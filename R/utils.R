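#' @importFrom stats cor sd rnorm qnorm qt runif var coef predict
#' @importFrom utils head read.delim write.table
NULL

# Evaluate expr under a locally scoped RNG seed; the caller's RNG stream is untouched.
local_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Derive a child seed from a parent seed and an offset, staying inside 32-bit range.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647L)
}

is_square_matrix <- function(x) {
  is.matrix(x) && is.numeric(x) && nrow(x) == ncol(x)
}

check_symmetric <- function(x, tol = 1e-8, arg = "matrix") {
  if (!is_square_matrix(x)) {
    stop(sprintf("'%s' must be a square numeric matrix", arg), call. = FALSE)
  }
  if (max(abs(x - t(x))) > tol) {
    stop(sprintf("'%s' must be symmetric", arg), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
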