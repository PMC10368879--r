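# Model registry and shared training plumbing. The three in-tree models
# (svm, cnn, bilstm) classify the entity-bounded input span of a candidate;
# external adapters (e.g. transformer fine-tuners) may be registered at run
# time through the same train/predict contract.

#' Training configuration
#'
#' The hyperparameter value sets mirror the studied search space: dropout in
#' \[0.1, 0.8\], learning rate one of 0.1/0.01/0.001/0.0001, batch size one
#' of 16/32/64.
#'
#' @param dropout Dropout rate in `[0.1, 0.8]` (neural models only).
#' @param learning_rate One of `0.1, 0.01, 0.001, 0.0001`.
#' @param batch_size One of `16, 32, 64`.
#' @param epochs Positive integer (default 20; early stopping on validation
#'   F1 with patience 3 when a validation split is available).
#' @param seed Integer seed; together with the dataset order it makes
#'   training bit-reproducible.
#' @return A `train_config`.
#' @export
train_config <- function(dropout = 0.3, learning_rate = 0.01,
                         batch_size = 32L, epochs = 20L, seed = 42L) {
  if (dropout < 0.1 || dropout > 0.8) {
    stop_ade("ade_config_error", "dropout must lie in [0.1, 0.8]")
  }
  if (!learning_rate %in% c(0.1, 0.01, 0.001, 0.0001)) {
    stop_ade("ade_config_error",
             "learning_rate must be one of 0.1, 0.01, 0.001, 0.0001")
  }
  if (!batch_size %in% c(16L, 32L, 64L)) {
    stop_ade("ade_config_error", "batch_size must be one of 16, 32, 64")
  }
  if (epochs < 1) stop_ade("ade_config_error", "epochs must be >= 1")
  structure(list(dropout = dropout, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "train_config")
}

# ---- registry ---------------------------------------------------------

model_registry <- new.env(parent = emptyenv())

#' Register a model adapter
#'
#' @param name Registry key (e.g. `"svm"`).
#' @param train_fn `function(dataset, train_cfg, ...) -> model`.
#' @param predict_fn `function(model, dataset) -> prediction data frame`
#'   with columns `candidate_id`, `y`, `score`.
#' @return Invisibly, `name`.
#' @export
register_model <- function(name, train_fn, predict_fn) {
  assign(name, list(train = train_fn, predict = predict_fn),
         envir = model_registry)
  invisible(name)
}

#' List registered model names
#' @return Character vector.
#' @export
registered_models <- function() sort(ls(model_registry))

#' Train a registered model on a relation dataset
#'
#' @param dataset A `relation_dataset`.
#' @param model_name Registry key; built-ins are `"svm"`, `"cnn"`,
#'   `"bilstm"`.
#' @param train_cfg A [train_config()].
#' @param ... Model-specific configuration (e.g. `config = svm_config()`).
#' @return A fitted model (class `ade_model`).
#' @export
train_relation_model <- function(dataset, model_name,
                                 train_cfg = train_config(), ...) {
  if (!exists(model_name, envir = model_registry)) {
    stop_ade("ade_config_error", "unknown model '%s'; registered: %s",
             model_name, paste(registered_models(), collapse = ", "))
  }
  get(model_name, envir = model_registry)$train(dataset, train_cfg, ...)
}

# Training rows: positives vs negatives as +-1, degenerate candidates
# (overlapping drug/ADE spans) excluded by default.
training_frame <- function(dataset, include_degenerate = FALSE) {
  df <- as.data.frame(dataset)
  if (!include_degenerate && "degenerate" %in% names(df)) {
    df <- df[!df$degenerate, , drop = FALSE]
  }
  if (!nrow(df)) stop_ade("ade_degenerate_error", "no usable candidates")
  df$y <- ifelse(df$label == "positive", 1L, -1L)
  df
}

assert_two_classes <- function(y) {
  if (length(unique(y)) < 2L) {
    stop_ade("ade_degenerate_error",
             "training data contain a single class; cannot fit a discriminative model")
  }
}

#' Predict candidate labels with a fitted model
#'
#' One prediction per candidate, deterministic at inference time. The
#' predicted label is 1 (positive) iff the calibrated score is at least 0.5.
#'
#' @param model An `ade_model`.
#' @param dataset A `relation_dataset` (or data frame with `candidate_id`
#'   and `input_span`).
#' @return Data frame with `candidate_id`, `y` (0/1), `score` in `[0, 1]`.
#' @export
predict_candidates <- function(model, dataset) {
  UseMethod("predict_candidates")
}

#' @export
predict_candidates.default <- function(model, dataset) {
  stop_ade("ade_state_error", "not a fitted aderelex model")
}

#' @export
print.ade_model <- function(x, ...) {
  cat(sprintf("<ade_model:%s> trained on %d candidates (seed %d)\n",
              class(x)[1], x$n_train, x$seed))
  invisible(x)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

prediction_frame <- function(candidate_id, score) {
  data.frame(candidate_id = candidate_id,
             y = as.integer(score >= 0.5),
             score = score, stringsAsFactors = FALSE)
}
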