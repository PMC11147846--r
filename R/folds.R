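#' Cross-validation fold assignment
#'
#' Deterministic seeded k-fold split: subjects are shuffled once, then cut into
#' contiguous blocks; any remainder is distributed one subject per fold, so fold
#' sizes never differ by more than 1. With n = 1000 and k = 10 this yields the
#' usual 10 folds of 100 (train on 900, validate on 100).
#'
#' @param n Number of subjects.
#' @param k Number of folds (2 <= k <= n).
#' @param seed Integer seed; the same (n, k, seed) always gives the same split.
#' @return An object of class `fc_folds`: list with `k`, `seed` and
#'   `assignment`, an integer vector mapping subject index to fold 1..k.
#' @examples
#' f <- make_folds(10, 5, seed = 1)
#' table(f$assignment)
#' @export
make_folds <- function(n, k, seed = 1L) {
  n <- as.integer(n); k <- as.integer(k)
  if (k < 2) stop("need at least 2 folds", call. = FALSE)
  if (k > n) stop("more folds than subjects (k > n)", call. = FALSE)
  sizes <- rep(n %/% k, k)
  rem <- n %% k
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  perm <- local_seed(seed, sample.int(n))
  assignment <- integer(n)
  assignment[perm] <- rep(seq_len(k), times = sizes)
  structure(list(k = k, seed = as.integer(seed), assignment = assignment),
            class = "fc_folds")
}

#' @export
print.fc_folds <- function(x, ...) {
  cat(sprintf("<fc_folds> %d subjects in %d folds (seed %d)\n",
              length(x$assignment), x$k, x$seed))
  invisible(x)
}

fold_train_idx <- function(folds, fold) which(folds$assignment != fold)
fold_test_idx  <- function(folds, fold) which(folds$assignment == fold)
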