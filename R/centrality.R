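#' Significance-threshold an FC matrix
#'
#' Keeps only edges whose Pearson correlation is individually significant for
#' the given scan length: the critical r is obtained by inverting the
#' two-sided t-test for a correlation coefficient with `t_len - 2` degrees of
#' freedom at level `alpha`; edges with |r| below the critical value are
#' zeroed, and surviving negative edges are removed as well (their
#' interpretability is disputed). With `t_len = 1200` and the conventional
#' `alpha = 1e-4`, the critical r is about 0.112.
#'
#' @param fc Symmetric FC matrix.
#' @param t_len Effective number of time points behind the correlations
#'   (>= 4).
#' @param alpha Significance level on each edge (default 1e-4).
#' @param two_sided Use the two-sided test (default). One-sided keeps the
#'   positive tail only.
#' @return Thresholded matrix (zero diagonal); attribute `"r_crit"` carries
#'   the critical correlation. Warns if no edge survives.
#' @export
threshold_fc <- function(fc, t_len, alpha = 1e-4, two_sided = TRUE) {
  check_symmetric(fc, arg = "fc")
  if (t_len < 4) stop("'t_len' must be at least 4", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)", call. = FALSE)
  df <- t_len - 2
  tcrit <- stats::qt(1 - alpha / (if (two_sided) 2 else 1), df)
  r_crit <- tcrit / sqrt(df + tcrit^2)
  out <- fc
  diag(out) <- 0
  out[abs(out) < r_crit] <- 0
  out[out < 0] <- 0
  if (all(out == 0)) {
    warning("no edge survives the threshold (r_crit = ",
            signif(r_crit, 4), "); graph is empty", call. = FALSE)
  }
  attr(out, "r_crit") <- r_crit
  out
}

#' Node centralities of a thresholded FC graph
#'
#' Degree centrality on the binarized graph; eigenvector and PageRank
#' centrality on the weighted graph of surviving positive edges. PageRank uses
#' damping 0.85 and sums to 1. On a disconnected graph, eigenvector centrality
#' is computed on the largest connected component with zeros elsewhere (the
#' result carries a `"disconnected"` attribute flag).
#'
#' @param thresholded Output of [threshold_fc()] (nonnegative, zero diagonal).
#' @param binarize_degree Compute degree on the binarized graph (default) or
#'   as weighted strength.
#' @param pagerank_damping PageRank damping factor.
#' @return A data.frame with columns `degree`, `eigenvector`, `pagerank`, one
#'   row per node.
#' @export
fc_centralities <- function(thresholded, binarize_degree = TRUE,
                            pagerank_damping = 0.85) {
  check_symmetric(thresholded, arg = "thresholded")
  if (any(thresholded < 0)) {
    stop("thresholded matrix must be nonnegative (negative edges removed)",
         call. = FALSE)
  }
  p <- nrow(thresholded)
  adj <- thresholded
  diag(adj) <- 0
  degree <- if (binarize_degree) rowSums(adj > 0) else rowSums(adj)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE)
  eig <- numeric(p)
  disconnected <- FALSE
  comp <- igraph::components(g)
  if (comp$no > 1) {
    disconnected <- TRUE
    big <- which.max(comp$csize)
    sub_nodes <- which(comp$membership == big)
    if (length(sub_nodes) >= 2) {
      sub <- igraph::induced_subgraph(g, sub_nodes)
      eig[sub_nodes] <- igraph::eigen_centrality(sub)$vector
    }
  } else {
    eig <- igraph::eigen_centrality(g)$vector
  }
  pr <- igraph::page_rank(g, damping = pagerank_damping)$vector
  out <- data.frame(degree = as.numeric(degree),
                    eigenvector = as.numeric(eig),
                    pagerank = as.numeric(pr))
  attr(out, "disconnected") <- disconnected
  out
}

#' Standardize centrality values across a cohort
#'
#' Per measure: z-scores the concatenation of all subjects' node values, then
#' maps the result linearly onto \[-1, 1\] (min to -1, max to 1). The
#' composition is strictly order-preserving.
#'
#' @param values Numeric matrix or vector of centrality values (subjects x
#'   nodes concatenated, or any shape); must contain at least 2 distinct
#'   values.
#' @return Rescaled values of the same shape, spanning exactly \[-1, 1\].
#' @export
standardize_centralities <- function(values) {
  v <- as.numeric(values)
  if (length(unique(v)) < 2) {
    stop("centrality values are constant; standardization undefined",
         call. = FALSE)
  }
  z <- (v - mean(v)) / stats::sd(v)
  out <- 2 * (z - min(z)) / (max(z) - min(z)) - 1
  if (is.matrix(values)) out <- matrix(out, nrow(values), ncol(values))
  out
}

#' Variance in individual centralities explained by the training average
#'
#' For each fold, averages the training subjects' per-node centralities and
#' uses those averages to predict each validation subject's node centralities;
#' concatenating all subjects and nodes, reports the squared Pearson
#' correlation per measure. This is the group-average analogue of judging a
#' model by how much centrality variance its predictions explain.
#'
#' @param cohort An `fc_cohort`.
#' @param folds An `fc_folds`.
#' @param t_len Effective time points for the significance threshold
#'   (default: the generator's `t_len` if recorded, else 1200).
#' @param alpha Edge significance level.
#' @param binarize_degree,pagerank_damping Passed to [fc_centralities()].
#' @return Named vector of R-squared per measure (degree, eigenvector,
#'   pagerank), with attribute `"centralities"` holding the standardized
#'   subject x node matrices.
#' @export
centrality_variance_explained <- function(cohort,
                                          folds = make_folds(cohort$n, 10L,
                                                             seed = 1L),
                                          t_len = NULL, alpha = 1e-4,
                                          binarize_degree = TRUE,
                                          pagerank_damping = 0.85) {
  t_len <- t_len %||% cohort$meta$t_len %||% 1200
  p <- cohort$atlas$p
  measures <- c("degree", "eigenvector", "pagerank")
  raw <- lapply(measures, function(m) matrix(NA_real_, cohort$n, p))
  names(raw) <- measures
  for (i in seq_len(cohort$n)) {
    th <- suppressWarnings(threshold_fc(cohort$efc[[i]], t_len, alpha))
    cent <- fc_centralities(th, binarize_degree, pagerank_damping)
    for (m in measures) raw[[m]][i, ] <- cent[[m]]
  }
  std <- lapply(raw, standardize_centralities)
  out <- vapply(measures, function(m) {
    emp <- std[[m]]
    pred <- matrix(NA_real_, cohort$n, p)
    for (fold in seq_len(folds$k)) {
      train <- fold_train_idx(folds, fold)
      test <- fold_test_idx(folds, fold)
      avg <- colMeans(emp[train, , drop = FALSE])
      pred[test, ] <- matrix(avg, length(test), p, byrow = TRUE)
    }
    stats::cor(as.numeric(emp), as.numeric(pred))^2
  }, numeric(1))
  attr(out, "centralities") <- std
  out
}
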