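test_that("the variance-preserving loss evaluates its closed-form cases", {
  withr::with_seed(8, {
    T <- matrix(rnorm(4 * 30), 4, 30)
  })
  # perfect prediction, gamma = 0, lambda = 0 -> loss 0
  expect_equal(as.numeric(mlp_loss(T, T, gamma = 0)), 0, tolerance = 1e-12)

  # gamma = 0: loss reduces to the accuracy term, between term has no weight
  P <- T + matrix(rnorm(120, 0, 0.5), 4, 30)
  l1 <- mlp_loss(P, T, gamma = 0)
  expect_equal(as.numeric(l1), 1 - attr(l1, "within"), tolerance = 1e-12)

  # all predictions identical, gamma = 1, lambda = 0 -> between term is 1
  same <- matrix(rep(rnorm(30), each = 4), 4, 30)
  expect_equal(as.numeric(mlp_loss(same, T, gamma = 1)), 1, tolerance = 1e-12)

  # direct-evaluation oracle on a random batch
  l <- mlp_loss(P, T, gamma = 0.4)
  within <- mean(sapply(1:4, function(i) pearson_oracle(P[i, ], T[i, ])))
  pairs <- combn(4, 2)
  between <- mean(apply(pairs, 2, function(ij)
    pearson_oracle(P[ij[1], ], P[ij[2], ])))
  expect_equal(as.numeric(l), 0.6 * (1 - within) + 0.4 * between,
               tolerance = 1e-12)

  expect_error(mlp_loss(T[1, , drop = FALSE], T[1, , drop = FALSE],
                        gamma = 0.4), "at least 2")
})

test_that("the analytic loss gradient matches finite differences", {
  withr::with_seed(13, {
    P <- matrix(rnorm(5 * 12), 5, 12)
    T <- matrix(rnorm(5 * 12), 5, 12)
  })
  for (g in c(0, 0.4, 1)) {
    an <- fcnull:::mlp_loss_grad_pred(P, T, g)
    num <- matrix(0, 5, 12)
    h <- 1e-6
    for (i in 1:5) for (j in 1:12) {
      Pp <- P; Pp[i, j] <- Pp[i, j] + h
      Pm <- P; Pm[i, j] <- Pm[i, j] - h
      num[i, j] <- (as.numeric(mlp_loss(Pp, T, g)) -
                      as.numeric(mlp_loss(Pm, T, g))) / (2 * h)
    }
    expect_lt(max(abs(an - num)), 1e-7)
  }
})

test_that("training recovers a linear SC-to-FC map and its loss decreases", {
  withr::with_seed(17, {
    X <- matrix(rnorm(30 * 21), 30, 21)
    A <- matrix(rnorm(21 * 21), 21, 21)
    Y <- X %*% A
  })
  cfg <- mlp_config(n_layers = 2, width = 32, gamma = 0, lambda_reg = 0,
                    epochs = 400)
  model <- mlp_train(X, Y, cfg, seed = 1)
  pred <- mlp_predict(model, X)
  r_within <- mean(sapply(1:30, function(i) cor(pred[i, ], Y[i, ])))
  expect_gt(r_within, 0.95)

  # monotone trend on the smoothed loss curve
  h <- model$history
  smooth <- stats::filter(h, rep(1 / 25, 25), sides = 1)
  smooth <- smooth[!is.na(smooth)]
  expect_lt(smooth[length(smooth)], 0.1 * smooth[1])
  expect_gt(mean(diff(smooth) <= 1e-8), 0.9)
})

test_that("training and inference are deterministic and guarded against leakage", {
  withr::with_seed(19, {
    X <- matrix(rnorm(12 * 15), 12, 15)
    Y <- matrix(rnorm(12 * 15), 12, 15)
  })
  cfg <- mlp_config(n_layers = 1, width = 8, epochs = 30)
  m1 <- mlp_train(X, Y, cfg, seed = 4, train_ids = sprintf("s%02d", 1:12))
  m2 <- mlp_train(X, Y, cfg, seed = 4, train_ids = sprintf("s%02d", 1:12))
  expect_identical(m1$par, m2$par)

  # identical inputs give identical predictions
  p1 <- mlp_predict(m1, X[c(1, 1), ])
  expect_identical(p1[1, ], p1[2, ])

  # predicting a training subject raises a leakage error
  expect_error(mlp_predict(m1, X[1, , drop = FALSE], ids = "s01"), "leakage")
  expect_error(mlp_predict(m1, X[, 1:10]), "expects")
})

test_that("an SC-decoupled cohort cannot beat the group-average baseline", {
  # eFC independent of SC: the MLP has nothing individual to learn
  coh <- memo("null_coupling_cohort", function() {
    generate_cohort(tiny_config(sc_coupling = 1, seed = 404))
  })
  folds <- make_folds(coh$n, 4, seed = 2)
  avg_perf <- mean(per_subject_correlation(
    fit_fc_predictor(coh, "avg", folds), coh))
  mfit <- fit_fc_predictor(coh, "mlp", folds,
                           mlp = mlp_config(n_layers = 2, width = 16,
                                            epochs = 150), seed = 3)
  mlp_perf <- mean(per_subject_correlation(mfit, coh))
  expect_lte(mlp_perf, avg_perf + 0.02)
})

test_that("fit_fc_predictor('mlp') predicts every subject out of fold", {
  coh <- tiny_cohort()
  folds <- make_folds(coh$n, 4, seed = 2)
  fit <- fit_fc_predictor(coh, "mlp", folds,
                          mlp = mlp_config(n_layers = 2, width = 16,
                                           epochs = 100), seed = 1)
  expect_length(fit$predictions, coh$n)
  for (pred in fit$predictions) {
    expect_equal(pred, t(pred))
    expect_equal(diag(pred), rep(1, 14))
  }
  # per-fold training histories recorded
  expect_length(fit$history, 4)
  expect_true(all(vapply(fit$history, length, numeric(1)) == 100))
})
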