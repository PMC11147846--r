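# Resolve a predictor argument to a list of predicted matrices.
prediction_list <- function(predictions) {
  if (inherits(predictions, "fc_predictor")) predictions$predictions
  else predictions
}

#' Per-subject prediction correlation
#'
#' Pearson correlation between each subject's empirical FC edge vector and the
#' predicted FC edge vector (upper triangle, diagonal excluded). The
#' distribution of these values over subjects is the standard individual-level
#' performance report; its mean is about 0.84 for the group-average predictor
#' in the DK-atlas HCP regime.
#'
#' @param predictions An `fc_predictor` or list of p x p predicted matrices.
#' @param cohort The `fc_cohort` holding empirical FC.
#' @return Numeric vector over subjects; `NA` (with a warning) where the
#'   predicted edge vector is constant and the correlation undefined.
#' @export
per_subject_correlation <- function(predictions, cohort) {
  preds <- prediction_list(predictions)
  if (length(preds) != cohort$n) {
    stop("number of predictions does not match cohort size", call. = FALSE)
  }
  out <- vapply(seq_len(cohort$n), function(i) {
    pv <- vectorize(preds[[i]])
    ev <- vectorize(cohort$efc[[i]])
    if (stats::sd(pv) == 0 || stats::sd(ev) == 0) return(NA_real_)
    stats::cor(pv, ev)
  }, numeric(1))
  if (anyNA(out)) {
    warning("constant prediction for subject(s) ",
            paste(which(is.na(out)), collapse = ", "),
            "; correlation undefined there", call. = FALSE)
  }
  out
}

#' Concatenated variance explained
#'
#' Squared Pearson correlation between the concatenation over all subjects of
#' predicted and empirical FC edge vectors — the "variance explained on the
#' full data set" convention. Note this statistic is sign-blind: a perfectly
#' anticorrelated prediction also yields R-squared 1.
#'
#' @inheritParams per_subject_correlation
#' @return Scalar in \[0, 1\].
#' @export
concatenated_r2 <- function(predictions, cohort) {
  preds <- prediction_list(predictions)
  pv <- unlist(lapply(preds, vectorize))
  ev <- unlist(lapply(cohort$efc, vectorize))
  if (stats::sd(pv) == 0) {
    warning("concatenated prediction is constant; R^2 undefined",
            call. = FALSE)
    return(NA_real_)
  }
  stats::cor(pv, ev)^2
}

#' Convert variance explained to correlation
#'
#' For a univariate regression, `R = sqrt(R^2)`; e.g. an R-squared of 0.56
#' corresponds to a correlation magnitude of 0.75. Useful when comparing
#' studies that report one or the other.
#'
#' @param r2 Variance explained in \[0, 1\].
#' @return `sqrt(r2)`.
#' @export
r2_to_r <- function(r2) {
  stopifnot(all(r2 >= 0 & r2 <= 1))
  sqrt(r2)
}

#' Preservation of inter-individual differences
#'
#' For every subject pair i < j, computes `x = cor(eFC_i, eFC_j)` (inter-eFC)
#' and `y = cor(pred_i, pred_j)` (inter-prediction similarity), then returns
#' the Pearson correlation of x with y across pairs. A predictor that
#' preserves the geometry of individual differences scores near 1; the noisy
#' group average scores 0 on average because its noise is independent across
#' subjects.
#'
#' @inheritParams per_subject_correlation
#' @return Scalar correlation; `NA` with attribute `reason` when the
#'   inter-prediction similarities are constant (e.g. identical predictions
#'   for all subjects, as with the zero-noise group average within one fold).
#' @export
preservation_correlation <- function(predictions, cohort) {
  preds <- prediction_list(predictions)
  n <- cohort$n
  if (n < 3) stop("need at least 3 subjects", call. = FALSE)
  E <- t(vapply(cohort$efc, vectorize,
                numeric(cohort$atlas$p * (cohort$atlas$p - 1) / 2)))
  P <- t(vapply(preds, vectorize, numeric(ncol(E))))
  ce <- stats::cor(t(E))
  cp <- suppressWarnings(stats::cor(t(P)))
  x <- ce[upper.tri(ce)]
  y <- cp[upper.tri(cp)]
  if (!all(is.finite(y)) || stats::sd(y) == 0) {
    out <- NA_real_
    attr(out, "reason") <- "inter-prediction similarities are constant or undefined"
    return(out)
  }
  stats::cor(x, y)
}

#' Per-parcel and per-network prediction error map
#'
#' For each subject and parcel, correlates that parcel's row of the predicted
#' matrix with the same row of the empirical FC (diagonal entry excluded) and
#' converts to the error measure `ln(1 - r)` (r clipped at 1 - 1e-9); lower is
#' better. Errors are averaged over the parcels of each Yeo-7 network, then
#' over subjects. In the HCP Schaefer-atlas regime the group-average predictor
#' scores best (most negative) in visual/somatomotor cortex and worst in the
#' limbic network.
#'
#' @inheritParams per_subject_correlation
#' @param atlas Atlas carrying the network labels (default: the cohort's).
#' @return Named numeric vector, one mean error per Yeo-7 network, plus
#'   attribute `"parcel_errors"` with the per-parcel means.
#' @export
network_error_map <- function(predictions, cohort, atlas = cohort$atlas) {
  preds <- prediction_list(predictions)
  p <- atlas$p
  err <- matrix(NA_real_, cohort$n, p)
  for (i in seq_len(cohort$n)) {
    pm <- preds[[i]]; em <- cohort$efc[[i]]
    for (q in seq_len(p)) {
      pr <- pm[q, -q]; er <- em[q, -q]
      if (stats::sd(pr) == 0 || stats::sd(er) == 0) next  # flagged as NA
      r <- min(stats::cor(pr, er), 1 - 1e-9)
      err[i, q] <- log(1 - r)
    }
  }
  parcel_means <- colMeans(err, na.rm = TRUE)
  nets <- factor(atlas$networks, levels = yeo7_networks)
  out <- tapply(parcel_means, nets, mean)
  out <- stats::setNames(as.numeric(out), levels(nets))
  attr(out, "parcel_errors") <- parcel_means
  out
}

#' Full evaluation report for a predictor
#'
#' Bundles the per-subject correlation distribution, concatenated variance
#' explained, preservation correlation and network error map into one object.
#' Also available as `summary()` on an `fc_predictor`.
#'
#' @param predictor An `fc_predictor` (or list of predicted matrices).
#' @param cohort The `fc_cohort`.
#' @return Object of class `fc_evaluation`.
#' @export
evaluate_predictor <- function(predictor, cohort) {
  r <- suppressWarnings(per_subject_correlation(predictor, cohort))
  structure(
    list(
      predictor_name = if (inherits(predictor, "fc_predictor"))
        predictor$method else "custom",
      per_subject_r = r,
      mean_r = mean(r, na.rm = TRUE),
      sd_r = stats::sd(r[!is.na(r)]),
      quartiles_r = stats::quantile(r, c(0.25, 0.5, 0.75), na.rm = TRUE),
      concatenated_r2 = suppressWarnings(concatenated_r2(predictor, cohort)),
      preservation_r = preservation_correlation(predictor, cohort),
      network_errors = network_error_map(predictor, cohort)
    ),
    class = "fc_evaluation"
  )
}

#' @export
print.fc_evaluation <- function(x, digits = 3, ...) {
  cat(sprintf("<fc_evaluation> predictor '%s'\n", x$predictor_name))
  cat(sprintf("  per-subject r: mean %.3f (sd %.3f), quartiles %.3f / %.3f / %.3f\n",
              x$mean_r, x$sd_r, x$quartiles_r[1], x$quartiles_r[2],
              x$quartiles_r[3]))
  cat(sprintf("  concatenated R^2: %.3f\n", x$concatenated_r2))
  pr <- x$preservation_r
  if (is.na(pr)) {
    cat("  preservation r: undefined (", attr(pr, "reason"), ")\n", sep = "")
  } else {
    cat(sprintf("  preservation r: %.3f\n", pr))
  }
  cat("  network errors ln(1-r):\n")
  ne <- x$network_errors
  print(round(stats::setNames(as.numeric(ne), names(ne)), digits))
  invisible(x)
}
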