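test_that("the significance threshold matches numerical inversion of the t test", {
  # independent oracle: find r whose cor.test p-value equals alpha
  oracle_rcrit <- function(t_len, alpha) {
    stats::uniroot(function(r) {
      tval <- r * sqrt((t_len - 2) / (1 - r^2))
      2 * stats::pt(-abs(tval), t_len - 2) - alpha
    }, c(1e-6, 1 - 1e-6), tol = 1e-12)$root
  }
  for (case in list(c(1200, 1e-4), c(300, 0.01), c(50, 0.05))) {
    th <- suppressWarnings(threshold_fc(diag(3), t_len = case[1],
                                        alpha = case[2]))
    expect_equal(attr(th, "r_crit"), oracle_rcrit(case[1], case[2]),
                 tolerance = 1e-10)
  }
  r_crit_ref <- attr(suppressWarnings(threshold_fc(diag(3), 1200, 1e-4)),
                     "r_crit")
  expect_equal(r_crit_ref, 0.112, tolerance = 0.005)
})

test_that("thresholding keeps significant positive edges only and is nested", {
  fc <- devectorize(c(0.5, -0.5, 0.05), 3, diag = 1)
  th <- threshold_fc(fc, t_len = 500, alpha = 1e-4)
  expect_equal(th[1, 2], 0.5)   # strong positive survives
  expect_equal(th[1, 3], 0)     # strong negative removed
  expect_equal(th[2, 3], 0)     # sub-threshold removed
  expect_equal(diag(th), rep(0, 3))

  # alpha -> 1: everything except negatives survives
  th_all <- threshold_fc(fc, t_len = 500, alpha = 0.9999)
  expect_equal(th_all[1, 2], 0.5)
  expect_equal(th_all[1, 3], 0)

  expect_warning(threshold_fc(diag(3) * 0 + diag(3), 500, 1e-4), "empty")
  all_zero <- matrix(0, 4, 4)
  expect_warning(out <- threshold_fc(all_zero, 500, 1e-4))
  expect_true(all(out == 0))

  # nestedness: smaller alpha yields a subgraph
  fc2 <- withr::with_seed(61, compute_efc(matrix(rnorm(120 * 12), 120, 12)))
  a <- suppressWarnings(threshold_fc(fc2, 120, alpha = 0.001))
  b <- suppressWarnings(threshold_fc(fc2, 120, alpha = 0.05))
  expect_true(all(which(a != 0) %in% which(b != 0)))
  expect_gt(sum(b != 0), 0)
})

test_that("centralities match graph-theoretic closed forms and oracles", {
  # star on 5 nodes: hub degree 4, leaves 1
  star <- matrix(0, 5, 5); star[1, 2:5] <- 0.5; star <- star + t(star)
  cent <- fc_centralities(star)
  expect_equal(cent$degree, c(4, 1, 1, 1, 1))

  # complete graph with equal weights: uniform eigenvector centrality
  comp <- matrix(0.4, 4, 4); diag(comp) <- 0
  ec <- fc_centralities(comp)$eigenvector
  expect_equal(ec, rep(1, 4), tolerance = 1e-10)

  # 3-node chain PageRank vs brute-force power iteration
  chain <- matrix(0, 3, 3); chain[1, 2] <- chain[2, 3] <- 0.8
  chain <- chain + t(chain)
  pr <- fc_centralities(chain, pagerank_damping = 0.85)$pagerank
  # oracle: power iteration on the weighted google matrix
  W <- chain / rowSums(chain)
  G <- 0.85 * t(W) + 0.15 / 3
  v <- rep(1 / 3, 3)
  for (i in 1:500) v <- as.numeric(G %*% v)
  expect_equal(pr, v / sum(v), tolerance = 1e-8)
  expect_equal(sum(pr), 1, tolerance = 1e-10)

  # disconnected graph: eigenvector on the largest component, flagged
  two_comp <- matrix(0, 5, 5)
  two_comp[1, 2] <- two_comp[2, 3] <- two_comp[4, 5] <- 0.5
  two_comp <- two_comp + t(two_comp)
  cc <- fc_centralities(two_comp)
  expect_true(attr(cc, "disconnected"))
  expect_equal(cc$eigenvector[4:5], c(0, 0))
  expect_gt(max(cc$eigenvector[1:3]), 0)
})

test_that("standardization maps onto [-1, 1] and preserves order", {
  expect_equal(standardize_centralities(c(0, 5, 10)), c(-1, 0, 1))
  withr::with_seed(23, {
    v <- rnorm(50)
    out <- standardize_centralities(v)
    expect_equal(range(out), c(-1, 1))
    expect_equal(order(out), order(v))
    expect_equal(cor(out, v, method = "spearman"), 1)
  })
  expect_error(standardize_centralities(rep(3, 5)), "constant")
})

test_that("PageRank sums to 1 for every subject in a cohort", {
  coh <- tiny_cohort()
  for (i in seq_len(coh$n)) {
    th <- suppressWarnings(threshold_fc(coh$efc[[i]], t_len = 150))
    pr <- fc_centralities(th)$pagerank
    expect_equal(sum(pr), 1, tolerance = 1e-10)
  }
})

test_that("identical subjects give R^2 = 1; uncoupled cohorts sit at chance", {
  atl <- tiny_atlas()
  # structured FC so a nonempty graph survives the threshold
  fc <- withr::with_seed(71, {
    L <- matrix(rnorm(14 * 3), 14, 3)
    C <- stats::cov2cor(tcrossprod(L) + diag(0.5, 14))
    compute_efc(matrix(rnorm(200 * 14), 200, 14) %*% chol(C))
  })
  coh_same <- fc_cohort(atl, efc = replicate(10, fc, simplify = FALSE),
                        meta = list(t_len = 200))
  r2 <- centrality_variance_explained(coh_same, make_folds(10, 5, seed = 1))
  expect_equal(as.numeric(r2), rep(1, 3), tolerance = 1e-10)

  # independent subjects (no shared template): R^2 within the permutation null
  coh0 <- memo("rho0_cohort", function() {
    generate_cohort(tiny_config(mixing_weight = 0, seed = 601),
                    components = character(0))
  })
  folds <- make_folds(coh0$n, 4, seed = 2)
  r2_0 <- centrality_variance_explained(coh0, folds, t_len = 150)
  std <- attr(r2_0, "centralities")
  # permutation oracle on degree centrality: reassigning whole centrality
  # vectors across subjects must not lower the explained variance beyond
  # chance fluctuation, because the training-average predictor carries no
  # subject-specific information at rho = 0
  emp <- std$degree
  pred <- matrix(NA_real_, nrow(emp), ncol(emp))
  for (f in seq_len(folds$k)) {
    tr <- which(folds$assignment != f); te <- which(folds$assignment == f)
    pred[te, ] <- matrix(colMeans(emp[tr, , drop = FALSE]),
                         length(te), ncol(emp), byrow = TRUE)
  }
  null_dist <- withr::with_seed(31, {
    vapply(1:200, function(b) {
      perm <- sample(nrow(emp))
      cor(as.numeric(emp[perm, ]), as.numeric(pred))^2
    }, numeric(1))
  })
  expect_lt(r2_0["degree"], quantile(null_dist, 0.995) + 0.02)
  expect_gt(r2_0["degree"], quantile(null_dist, 0.005) - 0.02)
})
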