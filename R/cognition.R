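#' Regress structural connectivity out of an FC edge vector
#'
#' Per subject, residualizes the FC (or predicted FC) edge vector on the same
#' subject's SC edge vector by ordinary least squares across edges, removing
#' the linear FC~SC dependence. Residuals are mean-zero and exactly orthogonal
#' to the centered SC vector. This is the "\\SC" operation applied before
#' cognition prediction.
#'
#' @param fc_edges,sc_edges Numeric vectors of equal length (one subject's
#'   edges).
#' @return Residual vector of the same length.
#' @export
regress_out_sc <- function(fc_edges, sc_edges) {
  if (length(fc_edges) != length(sc_edges)) {
    stop("edge vectors must have equal length", call. = FALSE)
  }
  if (stats::sd(sc_edges) == 0) {
    stop("SC edge vector is constant; regression undefined", call. = FALSE)
  }
  sc_c <- sc_edges - mean(sc_edges)
  beta <- sum(sc_c * fc_edges) / sum(sc_c^2)
  fc_edges - mean(fc_edges) - beta * sc_c
}

#' Shuffle predicted FC between subjects (rpFC)
#'
#' Reassigns predicted FC matrices across subjects by a seeded fixed-point-free
#' permutation (derangement): every subject receives some *other* subject's
#' prediction, and the multiset of matrices is preserved. Control for whether
#' the individual identity of a prediction matters.
#'
#' @param predictions An `fc_predictor` or list of predicted matrices
#'   (>= 2 subjects).
#' @param seed Integer seed.
#' @return List of matrices in the shuffled order, with attribute
#'   `"permutation"`.
#' @export
shuffle_pfc <- function(predictions, seed = 1L) {
  preds <- prediction_list(predictions)
  n <- length(preds)
  if (n < 2) stop("need at least 2 subjects to shuffle", call. = FALSE)
  perm <- local_seed(seed, {
    repeat {
      cand <- sample.int(n)
      if (!any(cand == seq_len(n))) break
    }
    cand
  })
  out <- preds[perm]
  attr(out, "permutation") <- perm
  out
}

#' Cross-validated lasso prediction of cognition
#'
#' Predicts a scalar cognition score from per-subject edge features with lasso
#' regression in `k_inner`-fold cross-validation, repeated over `n_outer`
#' outer loops with re-randomized folds so results do not hinge on one
#' subdivision. The penalty is chosen per training set by nested
#' cross-validation (`cv.glmnet`, training folds only). Per outer loop, the
#' out-of-fold predictions are concatenated and correlated with the actual
#' scores; the Pearson r and its test p-value are reported per loop, with
#' their mean/variance and the median p as summary.
#'
#' Two p-values are reported per loop: the two-sided Pearson test (`p`) and
#' the one-sided test for a *positive* association (`p_pos`). The one-sided
#' version is what "significantly predicts cognition" means downstream:
#' concatenated out-of-fold predictions carry a systematic negative
#' correlation bias under the null (each fold's prediction leans on the
#' training folds' mean, which is anticorrelated with the held-out scores, on
#' the order of -1/(k-1)), so the two-sided test flags that artefact rather
#' than predictive skill. The one-sided test is close to nominal, slightly
#' conservative, under the null.
#'
#' @param features Numeric matrix, subjects x features.
#' @param y Cognition scores (nonconstant).
#' @param k_inner Inner CV folds (default 10).
#' @param n_outer Outer repetitions (default 10).
#' @param seed Integer seed.
#' @param nfolds_lambda Folds for the nested penalty selection.
#' @return Object of class `fc_cognition_result` with fields `r`, `p`,
#'   `p_pos` (per outer loop), `mean_r`, `var_r`, `median_p`, `median_p_pos`.
#'   Loops whose concatenated prediction is constant (intercept-only lasso)
#'   yield `NA` r/p and are flagged in `n_degenerate`.
#' @export
predict_cognition <- function(features, y, k_inner = 10L, n_outer = 10L,
                              seed = 1L, nfolds_lambda = 5L) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 20) stop("need at least 20 subjects", call. = FALSE)
  if (length(y) != n) stop("'y' must have one score per subject", call. = FALSE)
  if (stats::sd(y) == 0) stop("'y' has zero variance", call. = FALSE)
  r <- p <- p_pos <- rep(NA_real_, n_outer)
  for (loop in seq_len(n_outer)) {
    folds <- make_folds(n, k_inner, seed = child_seed(seed, loop))
    pred <- rep(NA_real_, n)
    for (fold in seq_len(folds$k)) {
      train <- fold_train_idx(folds, fold)
      test <- fold_test_idx(folds, fold)
      # constant training designs (e.g. the avgFC variant within one fold)
      # cannot be fitted; fall back to the intercept-only prediction
      cvfit <- local_seed(child_seed(seed, 100 * loop + fold), {
        tryCatch(
          glmnet::cv.glmnet(features[train, , drop = FALSE], y[train],
                            alpha = 1, nfolds = nfolds_lambda,
                            standardize = TRUE),
          error = function(e) NULL
        )
      })
      pred[test] <- if (is.null(cvfit)) mean(y[train]) else {
        as.numeric(predict(cvfit, features[test, , drop = FALSE],
                           s = "lambda.min"))
      }
    }
    if (stats::sd(pred) > 0) {
      ct <- stats::cor.test(pred, y)
      r[loop] <- unname(ct$estimate)
      p[loop] <- ct$p.value
      p_pos[loop] <- stats::cor.test(pred, y,
                                     alternative = "greater")$p.value
    }
  }
  structure(
    list(r = r, p = p, p_pos = p_pos, mean_r = mean(r, na.rm = TRUE),
         var_r = if (sum(!is.na(r)) > 1) stats::var(r[!is.na(r)]) else NA_real_,
         median_p = stats::median(p, na.rm = TRUE),
         median_p_pos = stats::median(p_pos, na.rm = TRUE),
         n_degenerate = sum(is.na(r)), n_outer = n_outer),
    class = "fc_cognition_result"
  )
}

#' @export
print.fc_cognition_result <- function(x, ...) {
  cat(sprintf(paste0("<fc_cognition_result> mean r = %.3f (var %.4f) over %d",
                     " outer loops; median p = %.3g (one-sided %.3g)%s\n"),
              x$mean_r, x$var_r, x$n_outer, x$median_p, x$median_p_pos,
              if (x$n_degenerate > 0)
                sprintf(" [%d degenerate loop(s)]", x$n_degenerate) else ""))
  invisible(x)
}

#' The cognition-prediction control battery
#'
#' Runs [predict_cognition()] on the ten predictor variants used to probe
#' whether predicted FC carries individual information: eFC, SC, pFC, rpFC,
#' navgFC, avgFC, and the "\\SC" residual variants of the last four (each
#' subject's feature vector residualized on their own SC edges). The
#' diagnostic pattern on SC-driven cognition is that SC and every \\SC variant
#' predict significantly while pFC, rpFC, navgFC and avgFC alone do not —
#' i.e. the predictive power enters through the regressed-out SC, not through
#' the predictions themselves.
#'
#' @param cohort An `fc_cohort` with eFC, resampled SC and cognition.
#' @param pfc Optional `fc_predictor` (or list of matrices) supplying pFC;
#'   without it the pFC/rpFC variants are skipped with a warning.
#' @param folds Fold assignment used for the avg/navg predictors.
#' @param sigma Noise sd for the navgFC variant.
#' @param k_inner,n_outer,seed Passed to [predict_cognition()].
#' @param alpha_sig Significance level applied to the median one-sided p
#'   (default 0.05; the ten tests form one family — no correction is applied,
#'   mirroring the side-by-side reporting convention, but the family size is
#'   annotated).
#' @return Object of class `fc_cognition_battery`: `table` (data.frame with
#'   predictor, mean_r, var_r, median_p, median_p_pos, significant) and
#'   `results` (named list of `fc_cognition_result`). `significant` means a
#'   positive predictive association (median one-sided p below `alpha_sig`).
#' @export
run_cognition_battery <- function(cohort, pfc = NULL,
                                  folds = make_folds(cohort$n, 10L, seed = 1L),
                                  sigma = 0.1, k_inner = 10L, n_outer = 10L,
                                  seed = 1L, alpha_sig = 0.05) {
  if (is.null(cohort$cognition)) stop("cohort has no cognition scores", call. = FALSE)
  sc_comp <- if (!is.null(cohort$sc_resampled)) "sc_resampled" else "sc"
  SC <- cohort_edges(cohort, sc_comp)
  feats <- list(eFC = cohort_edges(cohort, "efc"), SC = SC)
  if (!is.null(pfc)) {
    P <- t(vapply(prediction_list(pfc), vectorize, numeric(ncol(SC))))
    feats$pFC <- P
    feats$rpFC <- t(vapply(shuffle_pfc(pfc, seed = child_seed(seed, 99)),
                           vectorize, numeric(ncol(SC))))
  } else {
    warning("no pFC supplied; battery runs without the pFC/rpFC variants",
            call. = FALSE)
  }
  navg <- fit_fc_predictor(cohort, "navg", folds, sigma = sigma,
                           seed = child_seed(seed, 7))
  avg <- fit_fc_predictor(cohort, "avg", folds)
  feats$navgFC <- t(vapply(navg$predictions, vectorize, numeric(ncol(SC))))
  feats$avgFC <- t(vapply(avg$predictions, vectorize, numeric(ncol(SC))))

  resid_variant <- function(X) {
    t(vapply(seq_len(nrow(X)),
             function(i) regress_out_sc(X[i, ], SC[i, ]), numeric(ncol(X))))
  }
  for (nm in intersect(c("pFC", "rpFC", "navgFC", "avgFC"), names(feats))) {
    feats[[paste0(nm, "\\SC")]] <- resid_variant(feats[[nm]])
  }

  results <- lapply(seq_along(feats), function(i) {
    predict_cognition(feats[[i]], cohort$cognition, k_inner = k_inner,
                      n_outer = n_outer, seed = child_seed(seed, 1000 + i))
  })
  names(results) <- names(feats)
  tab <- data.frame(
    predictor = names(results),
    mean_r = vapply(results, function(x) x$mean_r, numeric(1)),
    var_r = vapply(results, function(x) x$var_r, numeric(1)),
    median_p = vapply(results, function(x) x$median_p, numeric(1)),
    median_p_pos = vapply(results, function(x) x$median_p_pos, numeric(1)),
    row.names = NULL
  )
  tab$significant <- !is.na(tab$median_p_pos) & tab$median_p_pos < alpha_sig
  structure(list(table = tab, results = results, alpha = alpha_sig,
                 family_size = nrow(tab)),
            class = "fc_cognition_battery")
}

#' @export
print.fc_cognition_battery <- function(x, ...) {
  cat(sprintf(paste0("<fc_cognition_battery> %d predictors (uncorrected",
                     " alpha = %g; one family of %d tests)\n"),
              nrow(x$table), x$alpha, x$family_size))
  print(transform(x$table, mean_r = round(mean_r, 3),
                  var_r = signif(var_r, 3), median_p = signif(median_p, 3),
                  median_p_pos = signif(median_p_pos, 3)),
        row.names = FALSE)
  invisible(x)
}
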