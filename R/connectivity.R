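#' Empirical functional connectivity from regional time series
#'
#' Computes the eFC matrix as the pairwise Pearson correlation between each
#' region's activity time series, the standard construction for parcellated
#' resting-state data.
#'
#' @param time_series Numeric matrix, rows = time points, columns = parcels.
#'   Needs at least 3 time points and no constant column.
#' @return Symmetric p x p correlation matrix with unit diagonal. The matrix is
#'   positive semidefinite by construction.
#' @examples
#' ts <- matrix(rnorm(300), 100, 3)
#' compute_efc(ts)
#' @export
compute_efc <- function(time_series) {
  if (!is.matrix(time_series) || !is.numeric(time_series)) {
    stop("'time_series' must be a numeric matrix (time x parcels)", call. = FALSE)
  }
  if (nrow(time_series) < 3) {
    stop("need at least 3 time points to estimate correlations", call. = FALSE)
  }
  v <- apply(time_series, 2, stats::var)
  if (any(v == 0 | !is.finite(v))) {
    bad <- which(v == 0 | !is.finite(v))
    labs <- colnames(time_series)[bad] %||% as.character(bad)
    stop("zero-variance region(s): parcel ", paste(labs, collapse = ", "),
         "; correlation is undefined there", call. = FALSE)
  }
  fc <- stats::cor(time_series)
  # enforce exact symmetry / unit diagonal against floating-point asymmetry
  fc <- (fc + t(fc)) / 2
  diag(fc) <- 1
  fc
}

#' Edge vectorization of a symmetric connectivity matrix
#'
#' `vectorize` extracts the upper triangle (excluding the diagonal) in
#' row-major order — the canonical edge ordering used throughout the package;
#' all edge-level correlations are computed on these vectors so that each edge
#' is counted once. `devectorize` inverts the operation.
#'
#' @param m Symmetric numeric matrix.
#' @param v Edge vector of length p(p-1)/2.
#' @param p Parcel count.
#' @param diag Value to place on the diagonal of the reconstructed matrix
#'   (1 for FC, 0 for SC).
#' @return `vectorize`: numeric vector of length p(p-1)/2; `devectorize`:
#'   symmetric p x p matrix.
#' @examples
#' m <- matrix(c(1, .2, .3, .2, 1, .4, .3, .4, 1), 3)
#' vectorize(m)              # 0.2 0.3 0.4
#' devectorize(vectorize(m), 3)
#' @export
vectorize <- function(m) {
  check_symmetric(m, arg = "m")
  t(m)[lower.tri(m)]  # row-major upper triangle
}

#' @rdname vectorize
#' @export
devectorize <- function(v, p, diag = 1) {
  if (length(v) != p * (p - 1) / 2) {
    stop(sprintf("edge vector has length %d, expected p(p-1)/2 = %d",
                 length(v), p * (p - 1) / 2), call. = FALSE)
  }
  m <- matrix(0, p, p)
  m[lower.tri(m)] <- v   # fill lower triangle column-wise = row-major upper
  m <- m + t(m)
  m <- t(m)
  diag(m) <- diag
  m
}

#' Group-average connectivity
#'
#' Elementwise mean of a list of FC matrices — the group-average predictor's
#' fitted object.
#'
#' @param fcs Nonempty list of symmetric matrices of matching dimension.
#' @return Symmetric matrix of the same dimension; unit diagonal when the
#'   inputs have unit diagonals.
#' @export
group_average <- function(fcs) {
  if (!is.list(fcs) || length(fcs) == 0) {
    stop("'fcs' must be a nonempty list of matrices", call. = FALSE)
  }
  dims <- vapply(fcs, function(x) dim(x)[1], numeric(1))
  if (length(unique(dims)) != 1 ||
      any(vapply(fcs, function(x) nrow(x) != ncol(x), logical(1)))) {
    stop("all matrices must be square with matching dimensions", call. = FALSE)
  }
  Reduce(`+`, fcs) / length(fcs)
}

#' Read / write a connectivity matrix as TSV
#'
#' Tab-separated parcel x parcel table whose header row carries the parcel
#' labels, so the atlas ordering travels with the file.
#'
#' @param m Symmetric matrix.
#' @param path File path.
#' @param labels Optional parcel labels for the header (defaults to existing
#'   column names or `V1..Vp`).
#' @return `read_conn_tsv` returns the matrix with labels as dimnames.
#' @export
write_conn_tsv <- function(m, path, labels = NULL) {
  check_symmetric(m, arg = "m")
  labels <- labels %||% colnames(m) %||% paste0("V", seq_len(ncol(m)))
  colnames(m) <- labels
  write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_conn_tsv
#' @export
read_conn_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df)
  rownames(m) <- colnames(m)
  m
}
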