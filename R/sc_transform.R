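#' Rank-based Gaussian resampling of a streamline-count matrix
#'
#' Raw tractography streamline counts span orders of magnitude. This transform
#' replaces them, rank for rank, by standard-normal draws: one draw per
#' upper-triangle edge, draws sorted and assigned so the smallest draw replaces
#' the smallest count and so on. Tied counts (ubiquitously, the zeros) receive
#' the mean of the Gaussian order statistics their tie group spans, so equal
#' inputs stay equal. The result is mirrored to the lower triangle and finally
#' rescaled affinely so the off-diagonal mean and standard deviation equal
#' `target_mean` and `target_sd` exactly; the diagonal is left at 0 and
#' excluded from the moments. Rank order is preserved (Spearman correlation 1
#' with the input on tie-free matrices).
#'
#' @param sc Symmetric nonnegative matrix of streamline counts with at least
#'   two distinct off-diagonal values.
#' @param target_mean,target_sd Off-diagonal moments of the output
#'   (defaults 0.5 and 0.1, the conventional normalization).
#' @param seed Integer seed for the normal draws.
#' @return Symmetric matrix of resampled weights, zero diagonal.
#' @examples
#' sc <- matrix(c(0, 3, 10, 3, 0, 70, 10, 70, 0), 3)
#' r <- gaussian_resample(sc, seed = 1)
#' mean(r[upper.tri(r)])  # 0.5
#' @export
gaussian_resample <- function(sc, target_mean = 0.5, target_sd = 0.1,
                              seed = 1L) {
  check_symmetric(sc, arg = "sc")
  if (any(sc < 0)) stop("streamline counts must be nonnegative", call. = FALSE)
  if (target_sd <= 0) stop("'target_sd' must be positive", call. = FALSE)
  v <- vectorize(sc)
  if (length(unique(v)) < 2) {
    stop("all off-diagonal entries are equal; the sd rescale is undefined",
         call. = FALSE)
  }
  draws <- local_seed(seed, sort(rnorm(length(v))))
  # each edge gets the draw at its rank; ties averaged over their span
  assigned <- draws[rank(v, ties.method = "first")]
  assigned <- stats::ave(assigned, v, FUN = mean)
  z <- (assigned - mean(assigned)) / sd(assigned)
  out <- devectorize(target_mean + target_sd * z, nrow(sc), diag = 0)
  dimnames(out) <- dimnames(sc)
  out
}
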