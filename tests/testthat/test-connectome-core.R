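test_that("compute_efc matches the textbook Pearson formula", {
  # hand-checkable cases
  ts <- cbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(3, 2, 1))
  fc <- compute_efc(ts)
  expect_equal(fc["a", "b"], 1)
  expect_equal(fc["a", "c"], -1)

  ts2 <- cbind(x = c(1, 2, 4), y = c(1, 3, 3))
  # oracle: explicit sums, frozen hand value 24/sqrt(1008)
  expect_equal(compute_efc(ts2)["x", "y"], pearson_oracle(ts2[, 1], ts2[, 2]))
  expect_equal(compute_efc(ts2)["x", "y"], 0.7559289, tolerance = 1e-7)

  # property: equals covariance-then-normalize on random inputs, PSD, unit diag
  withr::with_seed(9, {
    for (rep in 1:5) {
      ts <- matrix(rnorm(60 * 8), 60, 8)
      fc <- compute_efc(ts)
      xc <- scale(ts, center = TRUE, scale = FALSE)
      oracle <- crossprod(xc) / sqrt(outer(colSums(xc^2), colSums(xc^2)))
      expect_lt(max(abs(fc - oracle)), 1e-12)
      expect_equal(diag(fc), rep(1, 8))
      expect_gte(min(eigen(fc, symmetric = TRUE, only.values = TRUE)$values),
                 -1e-10)
    }
  })
})

test_that("compute_efc rejects degenerate input and names the parcel", {
  ts <- cbind(a = rnorm(10), flatline = rep(2, 10))
  expect_error(compute_efc(ts), "flatline")
  expect_error(compute_efc(matrix(rnorm(4), 2, 2)), "3 time points")
})

test_that("vectorize/devectorize round-trip is exact and canonically ordered", {
  m <- matrix(c(1, .2, .3, .2, 1, .4, .3, .4, 1), 3)
  expect_equal(vectorize(m), c(0.2, 0.3, 0.4))  # row-major upper triangle
  expect_length(vectorize(diag(68)), 68 * 67 / 2)     # DK-like size: 2278
  expect_length(vectorize(diag(200)), 200 * 199 / 2)  # Schaefer-like: 19900

  withr::with_seed(4, {
    for (p in c(3, 7, 20)) {
      v <- rnorm(p * (p - 1) / 2)
      m <- devectorize(v, p, diag = 1)
      expect_identical(vectorize(m), v)
      m2 <- devectorize(vectorize(m), p, diag = 1)
      expect_identical(m2, m)
    }
  })
  asym <- matrix(rnorm(9), 3)
  expect_error(vectorize(asym), "symmetric")
})

test_that("group_average is the elementwise mean and preserves PSD", {
  m <- compute_efc(matrix(rnorm(50 * 4), 50, 4))
  expect_equal(group_average(list(m, m, m)), m)

  a <- devectorize(c(0.2, 0, 0), 3); b <- devectorize(c(0.4, 0, 0), 3)
  expect_equal(group_average(list(a, b))[1, 2], 0.3)
  expect_error(group_average(list()), "nonempty")

  # convexity: the average of PSD correlation matrices is PSD
  withr::with_seed(11, {
    mats <- lapply(1:6, function(i) compute_efc(matrix(rnorm(40 * 6), 40, 6)))
    avg <- group_average(mats)
    expect_gte(min(eigen(avg, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
    expect_equal(diag(avg), rep(1, 6))
    # commutes with vectorization
    expect_equal(vectorize(avg),
                 colMeans(t(vapply(mats, vectorize, numeric(15)))))
  })
})

test_that("make_folds partitions evenly and deterministically", {
  f <- make_folds(1000, 10, seed = 3)
  expect_equal(as.integer(table(f$assignment)), rep(100L, 10))

  f2 <- make_folds(10, 10, seed = 1)
  expect_equal(sort(f2$assignment), 1:10)  # singleton folds

  expect_identical(make_folds(57, 7, seed = 5), make_folds(57, 7, seed = 5))
  expect_false(identical(make_folds(57, 7, seed = 5)$assignment,
                         make_folds(57, 7, seed = 6)$assignment))

  # uneven n: sizes differ by at most 1, folds partition the cohort
  f3 <- make_folds(23, 5, seed = 2)
  sizes <- table(f3$assignment)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_equal(sum(sizes), 23)
  expect_error(make_folds(5, 6), "k > n")
})

test_that("atlas invariants and preset proportions hold", {
  expect_equal(atlas_dk_like()$p, 68)
  expect_equal(atlas_schaefer_like()$p, 200)
  expect_setequal(unique(atlas_dk_like()$networks), yeo7_networks)
  expect_setequal(unique(atlas_schaefer_like()$networks), yeo7_networks)
  expect_error(fc_atlas(c("a", "a"), c("VN", "VN")), "unique")
  expect_error(fc_atlas(c("a", "b"), c("VN", "XXX")), "unknown network")
  expect_error(fc_atlas("solo", "VN"), "at least 2")
})

test_that("matrix, atlas and cohort round-trip through their text formats", {
  dir <- withr::local_tempdir()
  atl <- tiny_atlas()
  write_atlas(atl, file.path(dir, "atlas.tsv"))
  atl2 <- read_atlas(file.path(dir, "atlas.tsv"))
  expect_equal(atl2$labels, atl$labels)
  expect_equal(atl2$networks, atl$networks)

  m <- compute_efc(matrix(rnorm(60 * 14), 60, 14))
  write_conn_tsv(m, file.path(dir, "m.tsv"), labels = atl$labels)
  m2 <- read_conn_tsv(file.path(dir, "m.tsv"))
  expect_equal(unname(m2), unname(m), tolerance = 1e-12)

  coh <- tiny_cohort()
  write_cohort(coh, file.path(dir, "cohort"))
  coh2 <- read_cohort(file.path(dir, "cohort"))
  expect_equal(coh2$n, coh$n)
  expect_equal(coh2$efc[[3]], coh$efc[[3]], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(coh2$sc[[2]], coh$sc[[2]], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(coh2$cognition, coh$cognition, tolerance = 1e-12)
})
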