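# Character n-gram TF-IDF + RBF-kernel maximum-margin classifier.
#
# No kernel-SVM solver ships with the base stack, so the soft-margin problem
# is solved in its kernelized primal form with the Pegasos subgradient
# scheme: deterministic given the seed, and adequate at the corpus sizes
# this pipeline targets (hundreds to a few thousand candidates).

#' Margin-classifier configuration
#'
#' @param c Margin penalty (soft-margin cost) used when no grid search runs.
#' @param gamma RBF kernel width.
#' @param ngram Character n-gram range, an [ngram_config()].
#' @param c_grid,gamma_grid Candidate values for the (c, gamma) grid search;
#'   non-empty. Selection criterion is positive-class F1 on a 30% internal
#'   validation split of the training data.
#' @param class_weight `"none"` (default) or `"balanced"`
#'   (inverse-prevalence weighting of the hinge updates).
#' @return An `svm_config`.
#' @export
svm_config <- function(c = 10, gamma = 1, ngram = ngram_config(2L, 5L),
                       c_grid = c(1, 10), gamma_grid = c(0.5, 1),
                       class_weight = c("none", "balanced")) {
  if (!length(c_grid) || !length(gamma_grid)) {
    stop_ade("ade_config_error", "c_grid and gamma_grid must be non-empty")
  }
  if (c <= 0 || gamma <= 0 || any(c_grid <= 0) || any(gamma_grid <= 0)) {
    stop_ade("ade_config_error", "c and gamma values must be positive")
  }
  structure(list(c = c, gamma = gamma, ngram = ngram, c_grid = c_grid,
                 gamma_grid = gamma_grid,
                 class_weight = match.arg(class_weight)),
            class = "svm_config")
}

rbf_kernel <- function(S, gamma, self_a = NULL, self_b = NULL) {
  # S = <a_i, b_j> inner products; squared distances from self inner
  # products (1 for L2-unit rows, which TF-IDF rows are unless all-zero)
  if (is.null(self_a)) self_a <- rep(1, nrow(S))
  if (is.null(self_b)) self_b <- rep(1, ncol(S))
  d2 <- outer(self_a, self_b, "+") - 2 * as.matrix(S)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

row_self <- function(X) Matrix::rowSums(X^2)

# Kernelized Pegasos: minimizes lambda/2 ||w||^2 + mean hinge, with
# lambda = 1 / (C * n). `weights` scales each example's update.
pegasos_fit <- function(K, y, cost, epochs = 30L, weights = NULL, seed = 1L) {
  n <- length(y)
  lambda <- 1 / (cost * n)
  if (is.null(weights)) weights <- rep(1, n)
  av <- numeric(n)   # alpha_i * y_i * weight_i accumulated
  t <- 0L
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      for (i in sample.int(n)) {
        t <- t + 1L
        f <- sum(K[i, ] * av) / (lambda * t)
        if (y[i] * f < 1) av[i] <- av[i] + y[i] * weights[i]
      }
    }
  })
  list(av = av, scale = 1 / (lambda * t), lambda = lambda, t = t)
}

svm_fit_core <- function(X, y, cost, gamma, weights, epochs, seed) {
  S <- as.matrix(Matrix::tcrossprod(X))
  K <- rbf_kernel(S, gamma, row_self(X), row_self(X))
  fit <- pegasos_fit(K, y, cost, epochs = epochs, weights = weights, seed = seed)
  fit
}

svm_decision <- function(model, X_new) {
  S <- as.matrix(Matrix::tcrossprod(X_new, model$X_train))
  K <- rbf_kernel(S, model$gamma, row_self(X_new), row_self(model$X_train))
  as.numeric(K %*% model$fit$av) * model$fit$scale
}

#' Train the RBF margin classifier on character n-gram TF-IDF features
#'
#' Grid-searches (c, gamma) by positive-class F1 on a seeded stratified 30%
#' internal validation split, then refits the selected pair on the full
#' training portion. The TF-IDF vocabulary is always rebuilt from the rows
#' actually fitted, so validation/test text never shapes the representation.
#'
#' @param dataset A `relation_dataset` with both classes.
#' @param train_cfg A [train_config()] (only `epochs` and `seed` are used by
#'   this model).
#' @param config An [svm_config()].
#' @param search Run the grid search (default `TRUE`); `FALSE` fits
#'   `config$c`/`config$gamma` directly.
#' @return An `ade_svm` model.
#' @export
train_svm <- function(dataset, train_cfg = train_config(),
                      config = svm_config(), search = TRUE) {
  df <- training_frame(dataset)
  assert_two_classes(df$y)
  weights <- if (config$class_weight == "balanced") {
    w <- length(df$y) / (2 * table(factor(df$y, levels = c(-1, 1))))
    as.numeric(w[as.character(df$y)])
  } else NULL

  chosen <- c(config$c, config$gamma)
  selection <- NULL
  if (search && (length(config$c_grid) > 1 || length(config$gamma_grid) > 1)) {
    sp <- stratified_holdout(df$label, 0.3, seed = train_cfg$seed)
    tr <- df[sp$train, ]; va <- df[sp$holdout, ]
    vec <- char_ngram_tfidf_fit(tr$input_span, config$ngram)
    Xtr <- tfidf_transform(vec, tr$input_span)
    Xva <- tfidf_transform(vec, va$input_span)
    wtr <- if (is.null(weights)) NULL else weights[sp$train]
    grid <- expand.grid(c = config$c_grid, gamma = config$gamma_grid)
    grid$f1 <- NA_real_
    for (gidx in seq_len(nrow(grid))) {
      fit <- svm_fit_core(Xtr, tr$y, grid$c[gidx], grid$gamma[gidx], wtr,
                          epochs = train_cfg$epochs, seed = train_cfg$seed)
      m <- list(X_train = Xtr, gamma = grid$gamma[gidx], fit = fit)
      pred <- as.integer(svm_decision(m, Xva) >= 0)
      grid$f1[gidx] <- f1_binary(pred, as.integer(va$y == 1))
    }
    best <- which.max(grid$f1)  # ties: first (smallest c, then gamma)
    chosen <- c(grid$c[best], grid$gamma[best])
    selection <- grid
  }

  vec <- char_ngram_tfidf_fit(df$input_span, config$ngram)
  X <- tfidf_transform(vec, df$input_span)
  fit <- svm_fit_core(X, df$y, chosen[1], chosen[2], weights,
                      epochs = train_cfg$epochs, seed = train_cfg$seed)
  structure(list(vectorizer = vec, X_train = X, fit = fit,
                 c = chosen[1], gamma = chosen[2], selection = selection,
                 config = config, seed = train_cfg$seed, n_train = nrow(df)),
            class = c("ade_svm", "ade_model"))
}

#' @export
predict_candidates.ade_svm <- function(model, dataset) {
  df <- as.data.frame(dataset)
  if (!nrow(df)) return(prediction_frame(character(), numeric()))
  X <- tfidf_transform(model$vectorizer, df$input_span)
  score <- sigmoid(svm_decision(model, X))
  prediction_frame(df$candidate_id, score)
}

# positive-class F1 from 0/1 vectors (internal; full scoring lives in
# evaluation.R)
f1_binary <- function(pred, truth) {
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  if (tp == 0) return(0)
  p <- tp / (tp + fp); r <- tp / (tp + fn)
  2 * p * r / (p + r)
}
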