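#' Configuration for the feed-forward FC predictor
#'
#' A fully connected network mapping Gaussian-resampled SC edge vectors to eFC
#' edge vectors, trained with a loss that trades prediction accuracy against
#' preservation of inter-individual variation:
#' \deqn{L = (1-\gamma)\,(1 - \overline{r_{within}}) +
#'       \gamma\,\overline{r_{between}} + \lambda\,\overline{W^2}}
#' where the within term is the mean Pearson correlation between each
#' subject's predicted and target edge vector, the between term the mean
#' correlation between different subjects' predictions, and the last term the
#' mean squared network weight. The reference architecture is 10 hidden layers
#' of 1024 units with gamma = 0.4, lambda = 0.01 over 20000 epochs; the
#' defaults here are desk-scale (width 256, 2000 epochs) so a fold trains in
#' minutes on one CPU — pass the reference values explicitly to reproduce the
#' full model. Optimizer is Adam with ReLU activations and He initialization.
#'
#' @param n_layers Hidden layers (default 10).
#' @param width Hidden units per layer (desk-scale default 256; reference 1024).
#' @param gamma Accuracy / variation trade-off in \[0, 1\] (default 0.4).
#' @param lambda_reg Weight-decay coefficient (default 0.01).
#' @param epochs Training epochs (desk-scale default 2000; reference 20000).
#' @param batch_size Minibatch size; `NULL` = full batch.
#' @param learning_rate Adam step size.
#' @return A list of class `fc_mlp_config`.
#' @export
mlp_config <- function(n_layers = 10, width = 256, gamma = 0.4,
                       lambda_reg = 0.01, epochs = 2000, batch_size = NULL,
                       learning_rate = 1e-3) {
  if (gamma < 0 || gamma > 1) stop("'gamma' must be in [0, 1]", call. = FALSE)
  if (lambda_reg < 0) stop("'lambda_reg' must be >= 0", call. = FALSE)
  structure(
    list(n_layers = as.integer(n_layers), width = as.integer(width),
         gamma = gamma, lambda_reg = lambda_reg, epochs = as.integer(epochs),
         batch_size = batch_size, learning_rate = learning_rate),
    class = "fc_mlp_config"
  )
}

# Row-center a matrix and return centered rows plus their norms.
row_center <- function(m) {
  mc <- m - rowMeans(m)
  list(c = mc, norm = sqrt(rowSums(mc^2)))
}

#' Variance-preserving training loss
#'
#' Evaluates the loss described in [mlp_config()] on a batch of predicted and
#' target edge vectors (rows = subjects). Exposed so the loss is a pluggable,
#' separately testable component.
#'
#' @param pred,target Numeric matrices, rows = subjects, columns = edges.
#' @param gamma,lambda_reg Trade-off and regularization weights.
#' @param weights Optional list of weight matrices entering the penalty term.
#' @return Scalar loss (lower is better), with attributes `within` (mean
#'   within-subject correlation) and `between` (mean between-subject
#'   prediction correlation).
#' @export
mlp_loss <- function(pred, target, gamma = 0.4, lambda_reg = 0,
                     weights = NULL) {
  stopifnot(is.matrix(pred), is.matrix(target), all(dim(pred) == dim(target)))
  B <- nrow(pred)
  if (B < 2 && gamma > 0) {
    stop("the between-subject term needs a batch of at least 2 subjects",
         call. = FALSE)
  }
  pc <- row_center(pred); tc <- row_center(target)
  r_within <- rowSums(pc$c * tc$c) / (pc$norm * tc$norm)
  between <- 0
  if (B >= 2) {
    Z <- pc$c / pc$norm
    R <- tcrossprod(Z)
    between <- mean(R[upper.tri(R)])
  }
  penalty <- 0
  if (!is.null(weights) && lambda_reg > 0) {
    penalty <- lambda_reg * mean(unlist(lapply(weights, function(w) w^2)))
  }
  out <- (1 - gamma) * (1 - mean(r_within)) + gamma * between + penalty
  attr(out, "within") <- mean(r_within)
  attr(out, "between") <- between
  out
}

# Gradient of the correlation terms of mlp_loss with respect to `pred`.
mlp_loss_grad_pred <- function(pred, target, gamma) {
  B <- nrow(pred)
  pc <- row_center(pred); tc <- row_center(target)
  sp <- pc$norm; st <- tc$norm
  r_w <- rowSums(pc$c * tc$c) / (sp * st)
  # d mean(r_within)/d pred_i = (t_c/(sp st) - r pc/sp^2)/B ; centered already
  g_within <- (tc$c / (sp * st) - (r_w / sp^2) * pc$c) / B
  grad <- -(1 - gamma) * g_within
  if (gamma > 0 && B >= 2) {
    Z <- pc$c / sp
    R <- tcrossprod(Z)
    S <- colSums(Z)
    rs <- rowSums(R) - 1   # sum_{j != i} r_ij
    # d mean_{i<j} r_ij / d pred_i, mean over B(B-1)/2 unordered pairs
    g_between <- (rep(1, B) %o% S - Z - rs * Z) / sp
    g_between <- g_between / (B * (B - 1) / 2)
    grad <- grad + gamma * g_between
  }
  grad
}

# He-initialized parameter set for an MLP with given layer sizes.
mlp_init <- function(sizes) {
  L <- length(sizes) - 1
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1], 0, sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  list(W = W, b = b)
}

mlp_forward <- function(par, X, keep = FALSE) {
  L <- length(par$W)
  A <- X
  acts <- if (keep) vector("list", L + 1)
  if (keep) acts[[1]] <- A
  for (l in seq_len(L)) {
    A <- sweep(A %*% par$W[[l]], 2, par$b[[l]], `+`)
    if (l < L) A[A < 0] <- 0   # ReLU on hidden layers, linear output
    if (keep) acts[[l + 1]] <- A
  }
  if (keep) list(out = A, acts = acts) else A
}

#' Train the feed-forward FC predictor on one training set
#'
#' Full-batch (or minibatch) Adam on the variance-preserving loss. Training is
#' deterministic given `seed` up to floating-point reordering. Usually called
#' through `fit_fc_predictor(method = "mlp")`, which handles the fold loop and
#' leakage guard.
#'
#' @param X Training SC edge matrix (subjects x edges).
#' @param Y Training eFC edge matrix (same shape).
#' @param config An `fc_mlp_config`.
#' @param seed Seed for initialization and batch shuffling.
#' @param train_ids Subject identifiers recorded for the leakage guard.
#' @return A model object of class `fc_mlp` with the fitted parameters, the
#'   config, the per-epoch loss `history`, and `train_ids`.
#' @export
mlp_train <- function(X, Y, config = mlp_config(), seed = 1L,
                      train_ids = NULL) {
  stopifnot(inherits(config, "fc_mlp_config"))
  if (is.null(X) || nrow(X) < 2) {
    stop("MLP training needs SC and eFC for at least 2 subjects", call. = FALSE)
  }
  if (nrow(X) != nrow(Y) || ncol(X) != ncol(Y)) {
    stop("X and Y must have matching dimensions", call. = FALSE)
  }
  n <- nrow(X); m <- ncol(X)
  sizes <- c(m, rep(config$width, config$n_layers), m)
  local_seed(seed, {
    par <- mlp_init(sizes)
    L <- length(par$W)
    n_w <- sum(vapply(par$W, length, numeric(1)))
    adam <- list(mW = lapply(par$W, function(w) w * 0),
                 vW = lapply(par$W, function(w) w * 0),
                 mb = lapply(par$b, function(b) b * 0),
                 vb = lapply(par$b, function(b) b * 0))
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    lr <- config$learning_rate
    history <- numeric(config$epochs)
    step <- 0
    bs <- config$batch_size %||% n
    for (epoch in seq_len(config$epochs)) {
      idx <- if (bs < n) sample.int(n) else seq_len(n)
      starts <- seq(1, n, by = bs)
      ep_loss <- 0
      for (s in starts) {
        rows <- idx[s:min(s + bs - 1, n)]
        if (length(rows) < 2) next  # between-subject term needs >= 2
        fw <- mlp_forward(par, X[rows, , drop = FALSE], keep = TRUE)
        loss <- mlp_loss(fw$out, Y[rows, , drop = FALSE],
                         gamma = config$gamma,
                         lambda_reg = config$lambda_reg, weights = par$W)
        ep_loss <- ep_loss + as.numeric(loss) * length(rows)
        delta <- mlp_loss_grad_pred(fw$out, Y[rows, , drop = FALSE],
                                    config$gamma)
        step <- step + 1
        for (l in rev(seq_len(L))) {
          gW <- crossprod(fw$acts[[l]], delta) +
            (2 * config$lambda_reg / n_w) * par$W[[l]]
          gb <- colSums(delta)
          if (l > 1) {
            delta <- (delta %*% t(par$W[[l]])) * (fw$acts[[l]] > 0)
          }
          adam$mW[[l]] <- beta1 * adam$mW[[l]] + (1 - beta1) * gW
          adam$vW[[l]] <- beta2 * adam$vW[[l]] + (1 - beta2) * gW^2
          adam$mb[[l]] <- beta1 * adam$mb[[l]] + (1 - beta1) * gb
          adam$vb[[l]] <- beta2 * adam$vb[[l]] + (1 - beta2) * gb^2
          mhW <- adam$mW[[l]] / (1 - beta1^step)
          vhW <- adam$vW[[l]] / (1 - beta2^step)
          mhb <- adam$mb[[l]] / (1 - beta1^step)
          vhb <- adam$vb[[l]] / (1 - beta2^step)
          par$W[[l]] <- par$W[[l]] - lr * mhW / (sqrt(vhW) + eps)
          par$b[[l]] <- par$b[[l]] - lr * mhb / (sqrt(vhb) + eps)
        }
      }
      history[epoch] <- ep_loss / n
    }
    structure(list(par = par, config = config, history = history,
                   train_ids = train_ids, n_edges = m, seed = as.integer(seed)),
              class = "fc_mlp")
  })
}

#' @export
print.fc_mlp <- function(x, ...) {
  cat(sprintf(paste0("<fc_mlp> %d hidden layers x %d units, gamma %.2f, ",
                     "lambda %.3g; final loss %.4f\n"),
              x$config$n_layers, x$config$width, x$config$gamma,
              x$config$lambda_reg, utils::tail(x$history, 1)))
  invisible(x)
}

#' Predict FC edge vectors from SC edge vectors
#'
#' Deterministic inference. If subject `ids` are supplied, predicting any
#' subject the model was trained on raises a leakage error.
#'
#' @param model An `fc_mlp`.
#' @param X SC edge matrix (subjects x edges).
#' @param ids Optional subject identifiers of the rows of `X`.
#' @return Predicted eFC edge matrix.
#' @export
mlp_predict <- function(model, X, ids = NULL) {
  stopifnot(inherits(model, "fc_mlp"))
  if (ncol(X) != model$n_edges) {
    stop(sprintf("input has %d edges, model expects %d", ncol(X),
                 model$n_edges), call. = FALSE)
  }
  if (!is.null(ids) && !is.null(model$train_ids)) {
    leak <- intersect(ids, model$train_ids)
    if (length(leak)) {
      stop("leakage: subject(s) ", paste(leak, collapse = ", "),
           " were in this model's training folds", call. = FALSE)
    }
  }
  mlp_forward(model$par, X)
}
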