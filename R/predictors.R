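#' Fit a cross-validated FC predictor
#'
#' Central fitting function of the package. Under a k-fold assignment, each
#' validation subject receives a predicted FC built only from the training
#' folds:
#'
#' * `"avg"` — the training group-average eFC (the "glass ceiling" null
#'   predictor);
#' * `"navg"` — the training average plus subject-independent symmetric
#'   Gaussian edge noise of standard deviation `sigma` (a null predictor that
#'   mimics inter-individual variation while carrying no individual
#'   information);
#' * `"mlp"` — a feed-forward network mapping Gaussian-resampled SC edge
#'   vectors to eFC edge vectors, trained per fold with a variance-preserving
#'   loss (see [mlp_config()]).
#'
#' @param cohort An `fc_cohort` with eFC for all subjects (and resampled SC
#'   for `method = "mlp"`).
#' @param method Predictor type.
#' @param folds An `fc_folds` assignment (default: 10-fold, seed 1).
#' @param sigma Noise sd for `"navg"` in FC correlation units (default 0.1,
#'   the value that matches the reported individual-level prediction
#'   performance regime on HCP-calibrated data).
#' @param clip Clip predicted edges into \[-1, 1\]? Off by default: clipping
#'   would distort the tuned noise distribution.
#' @param mlp An `fc_mlp_config` for `method = "mlp"`.
#' @param seed Seed for the navg noise / MLP initialization.
#' @return An object of class `fc_predictor`: fields `method`, `folds`,
#'   `predictions` (list of p x p matrices, one per subject, each produced
#'   without that subject's data), `sigma`, and for the MLP the per-fold
#'   models and training histories. Use [summary()] (= [evaluate_predictor()])
#'   for the evaluation statistics.
#' @examples
#' \donttest{
#' coh <- generate_cohort(cohort_config(n_subjects = 20, t_len = 200),
#'                        components = character(0))
#' fit <- fit_fc_predictor(coh, "avg", make_folds(20, 5))
#' summary(fit)
#' }
#' @export
fit_fc_predictor <- function(cohort, method = c("avg", "navg", "mlp"),
                             folds = make_folds(cohort$n, 10L, seed = 1L),
                             sigma = 0.1, clip = FALSE, mlp = mlp_config(),
                             seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(cohort, "fc_cohort"), inherits(folds, "fc_folds"))
  if (length(folds$assignment) != cohort$n) {
    stop("fold assignment does not match cohort size", call. = FALSE)
  }
  if (folds$k < 2) stop("need at least 2 folds", call. = FALSE)
  if (method == "navg" && sigma < 0) stop("'sigma' must be >= 0", call. = FALSE)

  p <- cohort$atlas$p
  predictions <- vector("list", cohort$n)
  models <- NULL
  history <- NULL

  if (method %in% c("avg", "navg")) {
    for (fold in seq_len(folds$k)) {
      train <- fold_train_idx(folds, fold)
      test <- fold_test_idx(folds, fold)
      avg <- group_average(cohort$efc[train])
      for (i in test) {
        pred <- avg
        if (method == "navg" && sigma > 0) {
          noise <- local_seed(child_seed(seed, i), {
            devectorize(rnorm(p * (p - 1) / 2, 0, sigma), p, diag = 0)
          })
          pred <- pred + noise
        }
        if (clip) {
          v <- pmin(pmax(vectorize(pred), -1), 1)
          pred <- devectorize(v, p, diag = 1)
        }
        predictions[[i]] <- pred
      }
    }
  } else {
    if (is.null(cohort$sc_resampled)) {
      stop("method 'mlp' needs Gaussian-resampled SC (cohort$sc_resampled)",
           call. = FALSE)
    }
    X <- cohort_edges(cohort, "sc_resampled")
    Y <- cohort_edges(cohort, "efc")
    models <- vector("list", folds$k)
    history <- vector("list", folds$k)
    for (fold in seq_len(folds$k)) {
      train <- fold_train_idx(folds, fold)
      test <- fold_test_idx(folds, fold)
      model <- mlp_train(X[train, , drop = FALSE], Y[train, , drop = FALSE],
                         mlp, seed = child_seed(seed, fold),
                         train_ids = cohort$ids[train])
      models[[fold]] <- model
      history[[fold]] <- model$history
      pred_edges <- mlp_predict(model, X[test, , drop = FALSE],
                                ids = cohort$ids[test])
      for (j in seq_along(test)) {
        predictions[[test[j]]] <- devectorize(pred_edges[j, ], p, diag = 1)
      }
    }
  }

  structure(
    list(method = method, folds = folds, predictions = predictions,
         sigma = if (method == "navg") sigma, clip = clip,
         models = models, history = history, ids = cohort$ids,
         atlas = cohort$atlas, seed = as.integer(seed)),
    class = "fc_predictor"
  )
}

#' @export
print.fc_predictor <- function(x, ...) {
  cat(sprintf("<fc_predictor> method '%s', %d subjects, %d folds%s\n",
              x$method, length(x$predictions), x$folds$k,
              if (!is.null(x$sigma)) sprintf(", sigma = %g", x$sigma) else ""))
  invisible(x)
}

#' @export
predict.fc_predictor <- function(object, subjects = NULL, ...) {
  idx <- if (is.null(subjects)) seq_along(object$predictions)
         else match(subjects, object$ids)
  if (anyNA(idx)) stop("unknown subject id(s)", call. = FALSE)
  out <- object$predictions[idx]
  names(out) <- object$ids[idx]
  out
}

#' @export
summary.fc_predictor <- function(object, cohort, ...) {
  evaluate_predictor(object, cohort, ...)
}

#' @export
plot.fc_predictor <- function(x, cohort, ...) {
  r <- per_subject_correlation(x, cohort)
  graphics::hist(r, breaks = 20, col = "grey80",
                 main = sprintf("Per-subject prediction correlation (%s)",
                                x$method),
                 xlab = "Pearson r (predicted vs empirical FC edges)")
  graphics::abline(v = mean(r, na.rm = TRUE), lwd = 2)
  invisible(r)
}

#' Tune the navgFC noise level to a target performance
#'
#' Bisection on `sigma` until the mean per-subject prediction correlation of
#' the noisy group-average predictor is within `tol` of `target`. Performance
#' is monotonically nonincreasing in `sigma`; targets above the zero-noise
#' group-average ceiling are rejected (the "glass ceiling").
#'
#' @param cohort,folds As in [fit_fc_predictor()].
#' @param target Desired mean per-subject correlation.
#' @param tol Tolerance on the match (default 0.01).
#' @param seed Seed for the noise draws (held fixed across bisection steps).
#' @param max_iter Bisection iteration cap.
#' @return The tuned `sigma`, with attribute `"performance"`.
#' @export
tune_sigma <- function(cohort, folds = make_folds(cohort$n, 10L, seed = 1L),
                       target, tol = 0.01, seed = 1L, max_iter = 40L) {
  perf <- function(sigma) {
    fit <- fit_fc_predictor(cohort, "navg", folds, sigma = sigma, seed = seed)
    mean(per_subject_correlation(fit, cohort), na.rm = TRUE)
  }
  ceiling_perf <- perf(0)
  if (target > ceiling_perf - tol) {
    if (abs(target - ceiling_perf) <= tol) {
      out <- 0
      attr(out, "performance") <- ceiling_perf
      return(out)
    }
    stop(sprintf(paste("target %.3f exceeds the zero-noise group-average",
                       "ceiling %.3f; no noise level can reach it"),
                 target, ceiling_perf), call. = FALSE)
  }
  lo <- 0; hi <- 0.2
  while (perf(hi) > target && hi < 100) hi <- hi * 2
  sigma <- hi
  for (it in seq_len(max_iter)) {
    sigma <- (lo + hi) / 2
    v <- perf(sigma)
    if (abs(v - target) < tol) break
    if (v > target) lo <- sigma else hi <- sigma
  }
  out <- sigma
  attr(out, "performance") <- perf(sigma)
  out
}
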