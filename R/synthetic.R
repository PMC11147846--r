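#' Configuration for the synthetic connectome cohort generator
#'
#' The generator emulates the second-order statistics of a large resting-state
#' cohort: a shared group FC template, smooth subject-specific deviations,
#' extra deviation variance that differs by Yeo-7 network, heavy-tailed
#' streamline counts coupled to the same individual structure, and a cognition
#' score driven by SC edges. Each subject's FC arises from finite Gaussian
#' time series drawn from a valid per-subject latent correlation matrix, so
#' within-subject estimation noise is controlled by `t_len`.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param atlas An `fc_atlas` or one of `"dk_like"` (p = 68) /
#'   `"schaefer_like"` (p = 200).
#' @param t_len Time points per subject (controls FC estimation noise).
#' @param rho_target Target mean pairwise inter-subject eFC correlation in
#'   \[0, 1\]; the mixing weight between group template and individual
#'   deviation is auto-calibrated so the realized mean is within +-0.02 of this.
#' @param network_deviation_scale Named nonnegative multipliers (Yeo-7 codes)
#'   on the per-network individual deviation variance. The defaults order
#'   limbic > frontoparietal = default mode > attention > visual = somatomotor,
#'   the ordering reported for group-average prediction errors across networks.
#' @param deviation_strength Global weight of the network-structured deviation
#'   component (correlation units).
#' @param n_factors Number of latent factors in the random correlation
#'   templates.
#' @param sc_coupling Weight in \[0, 1\] of shared vs individual structure in
#'   SC (1 = identical SC for all subjects up to noise).
#' @param sc_log_scale,sc_log_base,sc_noise_sd Log-normal parameters of the
#'   streamline-count model; the default scale spans several orders of
#'   magnitude, as raw tractography counts do.
#' @param cognition_beta Effect sizes on the selected standardized SC edge
#'   features (default: equal weights summing in squares to 1). Use 0 for a
#'   null cognition score independent of connectivity.
#' @param cognition_noise_sd Residual sd of the cognition score.
#' @param n_cognition_features Number of SC edges carrying cognition signal.
#' @param seed Integer seed; the whole cohort is deterministic given the config.
#' @param mixing_weight Optional fixed group-template weight in \[0, 1\]
#'   bypassing calibration (mainly for degenerate test settings).
#' @return A list of class `fc_cohort_config`.
#' @export
cohort_config <- function(n_subjects = 100, atlas = "dk_like", t_len = 1000,
                          rho_target = 0.70,
                          network_deviation_scale = c(VN = 0.6, SMN = 0.6,
                                                      DAN = 1.0, VAN = 1.0,
                                                      LSN = 2.5, FPN = 1.5,
                                                      DMN = 1.5),
                          deviation_strength = 0.15, n_factors = 10,
                          sc_coupling = 0.5, sc_log_scale = 1.5,
                          sc_log_base = 3, sc_noise_sd = 0.2,
                          cognition_beta = NULL, cognition_noise_sd = 0.5,
                          n_cognition_features = 3, seed = 1L,
                          mixing_weight = NULL) {
  if (is.character(atlas)) {
    atlas <- switch(match.arg(atlas, c("dk_like", "schaefer_like")),
                    dk_like = atlas_dk_like(),
                    schaefer_like = atlas_schaefer_like())
  }
  stopifnot(inherits(atlas, "fc_atlas"))
  if (n_subjects < 2) stop("need at least 2 subjects", call. = FALSE)
  if (rho_target < 0 || rho_target > 1) {
    stop("'rho_target' must be in [0, 1]", call. = FALSE)
  }
  if (any(network_deviation_scale < 0) || deviation_strength < 0) {
    stop("deviation scales must be nonnegative", call. = FALSE)
  }
  if (!all(yeo7_networks %in% names(network_deviation_scale))) {
    stop("'network_deviation_scale' must name all 7 Yeo networks", call. = FALSE)
  }
  if (sc_coupling < 0 || sc_coupling > 1) {
    stop("'sc_coupling' must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(n_subjects = as.integer(n_subjects), atlas = atlas,
         t_len = as.integer(t_len), rho_target = rho_target,
         network_deviation_scale = network_deviation_scale,
         deviation_strength = deviation_strength, n_factors = n_factors,
         sc_coupling = sc_coupling, sc_log_scale = sc_log_scale,
         sc_log_base = sc_log_base, sc_noise_sd = sc_noise_sd,
         cognition_beta = cognition_beta,
         cognition_noise_sd = cognition_noise_sd,
         n_cognition_features = as.integer(n_cognition_features),
         seed = as.integer(seed), mixing_weight = mixing_weight),
    class = "fc_cohort_config"
  )
}

# Random p x p correlation matrix from a k-factor model with ridge.
random_corr <- function(p, k, ridge = 1) {
  L <- matrix(rnorm(p * k), p, k)
  stats::cov2cor(tcrossprod(L) + diag(ridge, p))
}

# Project a symmetric unit-diagonal matrix onto the correlation matrices.
# Fast eigenvalue clip first; Higham projection (Matrix::nearPD) only if the
# clipped matrix is still meaningfully indefinite.
make_correlation <- function(m, tol = 1e-8) {
  ev <- eigen(m, symmetric = TRUE)
  if (min(ev$values) >= tol) {
    diag(m) <- 1
    return(m)
  }
  vals <- pmax(ev$values, tol)
  out <- ev$vectors %*% (vals * t(ev$vectors))
  out <- stats::cov2cor((out + t(out)) / 2)
  diag(out) <- 1
  out
}

# Latent correlation target for one subject given the mixing weight w.
subject_latent_corr <- function(w, G, D_i, E_i) {
  make_correlation(w * G + (1 - w) * D_i + E_i)
}

# Gaussian time series with covariance C, using pre-drawn standard normals Z.
ts_from_corr <- function(C, Z) {
  Z %*% chol(C)
}

#' Generate a synthetic cohort of coupled FC / SC / cognition
#'
#' Each subject's latent correlation target is the correlation-matrix
#' projection of `w*G + (1-w)*D_i + E_i`, where `G` is a shared group
#' template, `D_i` a subject-specific smooth deviation (both random factor
#' correlation matrices) and `E_i` an extra zero-diagonal deviation whose
#' variance is scaled per Yeo network by `network_deviation_scale`. Gaussian
#' time series of length `t_len` are drawn from each target and eFC computed
#' as pairwise Pearson correlation. The weight `w` is calibrated by bisection
#' on a pilot batch of 10 subjects so the realized mean pairwise inter-subject
#' eFC correlation lands within +-0.02 of `rho_target`; with the default
#' target of 0.70 this reproduces the regime in which individual FC correlates
#' about sqrt(0.70) ~ 0.84 with the group average. SC and cognition are then
#' filled in by [generate_sc()] and [generate_cognition()].
#'
#' @param config An `fc_cohort_config` from [cohort_config()].
#' @param components Which derived components to generate alongside eFC.
#' @return An `fc_cohort`; `$meta` records the seed and calibrated weight, and
#'   the latent edge structure is kept (in memory only) for SC generation.
#' @examples
#' \donttest{
#' cfg <- cohort_config(n_subjects = 20, t_len = 300, seed = 7)
#' coh <- generate_cohort(cfg)
#' }
#' @export
generate_cohort <- function(config,
                            components = c("sc", "sc_resampled", "cognition")) {
  stopifnot(inherits(config, "fc_cohort_config"))
  atlas <- config$atlas
  p <- atlas$p
  n <- config$n_subjects
  scale_vec <- config$network_deviation_scale[atlas$networks]
  s_half <- sqrt(scale_vec)

  state <- local_seed(config$seed, {
    G <- random_corr(p, config$n_factors)
    subj <- lapply(seq_len(n), function(i) {
      D <- random_corr(p, config$n_factors)
      N <- random_corr(p, max(3, config$n_factors %/% 2))
      E <- config$deviation_strength * (s_half * t(s_half * (N - diag(p))))
      Z <- matrix(rnorm(config$t_len * p), config$t_len, p)
      list(D = D, E = E, Z = Z)
    })
    list(G = G, subj = subj)
  })

  efc_at <- function(w, idx) {
    lapply(idx, function(i) {
      s <- state$subj[[i]]
      C <- subject_latent_corr(w, state$G, s$D, s$E)
      compute_efc(ts_from_corr(C, s$Z))
    })
  }
  mean_inter <- function(efcs) {
    edges <- vapply(efcs, vectorize, numeric(p * (p - 1) / 2))
    cc <- cor(edges)
    mean(cc[upper.tri(cc)])
  }

  w <- config$mixing_weight
  if (is.null(w)) {
    pilot <- seq_len(min(10L, n))
    f <- function(w) mean_inter(efc_at(w, pilot))
    f1 <- f(1)
    f0 <- f(0)
    if (f1 + 0.02 < config$rho_target) {
      stop(sprintf(paste("calibration infeasible: even with full weight on the",
                         "group template the realized inter-eFC is %.3f < %.3f;",
                         "reduce deviation_strength, network scales, or",
                         "rho_target"), f1, config$rho_target), call. = FALSE)
    }
    if (f0 > config$rho_target + 0.02) {
      stop(sprintf(paste("calibration infeasible: with no group template the",
                         "realized inter-eFC is already %.3f > %.3f; raise",
                         "rho_target or the deviation scales"),
                   f0, config$rho_target), call. = FALSE)
    }
    lo <- 0; hi <- 1
    w <- 0.5
    for (it in seq_len(30)) {
      w <- (lo + hi) / 2
      fv <- f(w)
      if (abs(fv - config$rho_target) < 0.005) break
      if (fv < config$rho_target) lo <- w else hi <- w
    }
  } else if (w < 0 || w > 1) {
    stop("'mixing_weight' must be in [0, 1]", call. = FALSE)
  }

  efcs <- efc_at(w, seq_len(n))
  m_edges <- p * (p - 1) / 2
  cohort <- fc_cohort(atlas, efc = efcs,
                      meta = list(generator = "fcnull", seed = config$seed,
                                  mixing_weight = w,
                                  rho_target = config$rho_target,
                                  t_len = config$t_len))
  cohort$latent <- list(
    g_edges = vectorize(state$G),
    d_edges = t(vapply(state$subj, function(s) vectorize(s$D),
                       numeric(m_edges)))
  )
  cohort$config <- config
  if ("sc" %in% components) {
    cohort <- generate_sc(cohort, config)
    if ("sc_resampled" %in% components) {
      cohort$sc_resampled <- lapply(seq_len(n), function(i) {
        gaussian_resample(cohort$sc[[i]], seed = child_seed(config$seed, 7000 + i))
      })
    }
    if ("cognition" %in% components) {
      cohort <- generate_cognition(cohort, config)
    }
  }
  cohort
}

#' Generate heavy-tailed streamline-count SC for a synthetic cohort
#'
#' Per subject, blends the shared template edges with the subject's own latent
#' deviation edges (weight `sc_coupling`), converts the blend to normal scores,
#' and exponentiates: `SC = round(exp(a * rankscore + b + noise))`. This yields
#' symmetric nonnegative integer counts spanning orders of magnitude, coupled
#' to the subject's FC through the shared deviation component.
#'
#' @param cohort An `fc_cohort` produced by [generate_cohort()] (needs the
#'   latent templates).
#' @param config The cohort's `fc_cohort_config`.
#' @return The cohort with `$sc` filled in.
#' @export
generate_sc <- function(cohort, config = cohort$config) {
  if (is.null(cohort$latent)) {
    stop("cohort has no latent templates; generate it with generate_cohort()",
         call. = FALSE)
  }
  p <- cohort$atlas$p
  m <- p * (p - 1) / 2
  cohort$sc <- local_seed(child_seed(config$seed, 1234), {
    lapply(seq_len(cohort$n), function(i) {
      blend <- config$sc_coupling * cohort$latent$g_edges +
        (1 - config$sc_coupling) * cohort$latent$d_edges[i, ]
      z <- qnorm((rank(blend, ties.method = "average") - 0.5) / m)
      counts <- round(exp(config$sc_log_scale * z + config$sc_log_base +
                            rnorm(m, 0, config$sc_noise_sd)))
      devectorize(pmax(counts, 0), p, diag = 0)
    })
  })
  cohort
}

#' Generate an SC-linked cognition score
#'
#' `y_i = beta . x_i + noise`, where `x_i` are the subject's standardized
#' values on a seeded selection of SC edges (restricted to edges with
#' between-subject variance). The Gaussian-resampled SC weights are used when
#' present — the SC representation the downstream analyses consume — falling
#' back to raw counts otherwise. With `cognition_beta = 0` the score is
#' independent of all connectivity — the global null used by the
#' type-I-error checks.
#'
#' @inheritParams generate_sc
#' @return The cohort with `$cognition` filled in; the selected edge indices
#'   and effect sizes are recorded in `$meta$cognition`.
#' @export
generate_cognition <- function(cohort, config = cohort$config) {
  if (is.null(cohort$sc)) stop("generate SC first", call. = FALSE)
  X <- cohort_edges(cohort,
                    if (!is.null(cohort$sc_resampled)) "sc_resampled" else "sc")
  usable <- which(apply(X, 2, stats::sd) > 0)
  k <- config$n_cognition_features
  if (length(usable) < k) {
    stop("fewer than ", k, " SC edges vary between subjects", call. = FALSE)
  }
  beta <- config$cognition_beta %||% rep(1 / sqrt(k), k)
  if (length(beta) == 1) beta <- rep(beta, k)
  if (length(beta) != k) {
    stop("'cognition_beta' must have length 1 or n_cognition_features",
         call. = FALSE)
  }
  cohort$cognition <- local_seed(child_seed(config$seed, 4321), {
    sel <- sample(usable, k)
    Xs <- scale(X[, sel, drop = FALSE])
    y <- as.numeric(Xs %*% beta) + rnorm(cohort$n, 0, config$cognition_noise_sd)
    attr(y, "features") <- sel
    y
  })
  cohort$meta$cognition <- list(features = attr(cohort$cognition, "features"),
                                beta = beta)
  attr(cohort$cognition, "features") <- NULL
  cohort
}
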