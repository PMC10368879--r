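# Token-level convolutional classifier: embedding -> parallel convolutions
# over kernel sizes W_h -> ReLU -> max-over-time pooling -> concatenation ->
# dropout -> dense sigmoid head. Implemented directly on base-R matrices
# (no deep-learning runtime ships with the environment); sizes stay small
# enough that this is fast at corpus scale.

#' CNN specification
#'
#' @param s_n Maximum tokens per input (inputs are padded/truncated to this
#'   length); must be at least the largest kernel size and >= 2.
#' @param s_d Embedding dimension per token. 300 is the convention when a
#'   pretrained 300-d table is supplied; the trained-from-scratch default is
#'   32.
#' @param w_h Integer vector of kernel (filter window) sizes; default
#'   `c(2, 3, 4)`.
#' @param n_filters Filters per kernel size (default 8; pooled feature
#'   length is `length(w_h) * n_filters`).
#' @param embedding Optional `embedding_table` for pretrained vectors
#'   (`s_d` must match its dimension).
#' @param freeze_embedding Keep embedding weights fixed during training.
#' @return A `cnn_spec`.
#' @export
cnn_spec <- function(s_n = 30L, s_d = 32L, w_h = c(2L, 3L, 4L),
                     n_filters = 8L, embedding = NULL,
                     freeze_embedding = FALSE) {
  if (s_n < 2L) stop_ade("ade_config_error", "s_n must be at least 2")
  if (any(w_h < 1L) || max(w_h) > s_n) {
    stop_ade("ade_config_error", "kernel sizes must lie in [1, s_n]")
  }
  if (!is.null(embedding) && embedding$dim != s_d) {
    stop_ade("ade_config_error",
             "s_d %d does not match pretrained embedding dimension %d",
             s_d, embedding$dim)
  }
  structure(list(s_n = as.integer(s_n), s_d = as.integer(s_d),
                 w_h = as.integer(w_h), n_filters = as.integer(n_filters),
                 embedding = embedding,
                 freeze_embedding = isTRUE(freeze_embedding)),
            class = "cnn_spec")
}

cnn_init_params <- function(spec, vocab) {
  params <- list(
    E = init_embedding(length(vocab), spec$s_d, spec$embedding, vocab)
  )
  for (h in spec$w_h) {
    lim <- sqrt(6 / (h * spec$s_d + spec$n_filters))
    params[[paste0("W", h)]] <- matrix(
      stats::runif(h * spec$s_d * spec$n_filters, -lim, lim),
      nrow = h * spec$s_d)
    params[[paste0("b", h)]] <- numeric(spec$n_filters)
  }
  ftot <- length(spec$w_h) * spec$n_filters
  params$w_out <- stats::rnorm(ftot, sd = 0.1)
  params$b_out <- 0
  params
}

# Stacked convolution windows: rows = (sample, position) pairs, columns =
# the h concatenated token embeddings.
cnn_windows <- function(X3, h) {
  b <- dim(X3)[1]; s <- dim(X3)[2]; d <- dim(X3)[3]
  p <- s - h + 1L
  Xw <- matrix(0, nrow = b * p, ncol = h * d)
  for (o in seq_len(h)) {
    # slice positions o..o+p-1 -> (b, p, d), flattened row-major over (b, p)
    sl <- X3[, o:(o + p - 1L), , drop = FALSE]
    Xw[, ((o - 1L) * d + 1L):(o * d)] <- matrix(sl, nrow = b * p)
  }
  Xw
}

cnn_forward <- function(params, spec, ids, drop_mask = NULL) {
  b <- nrow(ids); s <- ncol(ids); d <- spec$s_d
  X3 <- array(params$E[t(ids) + 1L, ], dim = c(s, b, d))
  X3 <- aperm(X3, c(2, 1, 3))   # (b, s, d)
  pooled <- NULL
  cache <- list(X3 = X3, per_h = list())
  for (h in spec$w_h) {
    p <- s - h + 1L
    Xw <- cnn_windows(X3, h)
    Z <- sweep(Xw %*% params[[paste0("W", h)]], 2, params[[paste0("b", h)]], "+")
    A <- pmax(Z, 0)
    A3 <- array(A, dim = c(b, p, spec$n_filters))
    am <- apply(A3, c(1, 3), which.max)        # (b, f) argmax position
    mx <- apply(A3, c(1, 3), max)              # (b, f) pooled value
    pooled <- cbind(pooled, mx)
    cache$per_h[[as.character(h)]] <- list(Xw = Xw, Z = Z, am = am, p = p)
  }
  dropped <- if (is.null(drop_mask)) pooled else pooled * drop_mask
  logit <- as.numeric(dropped %*% params$w_out) + params$b_out
  cache$pooled <- pooled; cache$dropped <- dropped
  list(prob = sigmoid(logit), cache = cache)
}

cnn_backward <- function(params, spec, ids, y01, drop_mask) {
  fw <- cnn_forward(params, spec, ids, drop_mask)
  cache <- fw$cache
  b <- nrow(ids); s <- ncol(ids); d <- spec$s_d
  dlogit <- bce_grad(fw$prob, y01)
  grads <- list()
  grads$w_out <- as.numeric(crossprod(cache$dropped, dlogit))
  grads$b_out <- sum(dlogit)
  dpooled <- (dlogit %o% params$w_out) *
    (if (is.null(drop_mask)) 1 else drop_mask)
  dX3 <- array(0, dim = dim(cache$X3))
  col0 <- 0L
  for (h in spec$w_h) {
    ch <- cache$per_h[[as.character(h)]]
    p <- ch$p
    f <- spec$n_filters
    dZ <- matrix(0, nrow = b * p, ncol = f)
    dp_h <- dpooled[, (col0 + 1L):(col0 + f), drop = FALSE]
    # gradient reaches only the argmax window of each (sample, filter)
    rows <- as.vector((ch$am - 1L) * b + row(ch$am))  # (pos-1)*b + sample
    idx <- cbind(rows, as.vector(col(ch$am)))
    relu_on <- ch$Z[idx] > 0
    dZ[idx[relu_on, , drop = FALSE]] <- as.vector(dp_h)[relu_on]
    grads[[paste0("W", h)]] <- crossprod(ch$Xw, dZ)
    grads[[paste0("b", h)]] <- colSums(dZ)
    dXw <- dZ %*% t(params[[paste0("W", h)]])
    for (o in seq_len(h)) {
      dslice <- array(dXw[, ((o - 1L) * d + 1L):(o * d)], dim = c(b, p, d))
      dX3[, o:(o + p - 1L), ] <- dX3[, o:(o + p - 1L), , drop = FALSE] + dslice
    }
    col0 <- col0 + f
  }
  if (spec$freeze_embedding) {
    grads$E <- params$E * 0
  } else {
    flat_ids <- as.vector(ids) + 1L
    dE_rows <- matrix(dX3, nrow = b * s)  # column-major (b, s) matches as.vector(ids)
    grads$E <- rowsum(dE_rows, group = flat_ids, reorder = FALSE)
    full <- matrix(0, nrow = nrow(params$E), ncol = d)
    full[as.integer(rownames(grads$E)), ] <- grads$E
    full[PAD_ID + 1L, ] <- 0   # padding stays a zero vector
    grads$E <- full
  }
  list(loss = -mean(y01 * log(fw$prob + 1e-12) +
                      (1 - y01) * log(1 - fw$prob + 1e-12)),
       grads = grads)
}

#' Train the convolutional relation classifier
#'
#' @param dataset A `relation_dataset` with both classes.
#' @param train_cfg A [train_config()].
#' @param spec A [cnn_spec()].
#' @param validation Optional `relation_dataset` monitored for early
#'   stopping; by default a 15% stratified slice of `dataset` is carved out.
#' @return An `ade_cnn` model.
#' @export
train_cnn <- function(dataset, train_cfg = train_config(), spec = cnn_spec(),
                      validation = NULL) {
  df <- training_frame(dataset)
  assert_two_classes(df$y)
  if (is.null(validation)) {
    sp <- stratified_holdout(df$label, 0.15, seed = train_cfg$seed)
    va <- df[sp$holdout, ]; df_tr <- df[sp$train, ]
  } else {
    va <- training_frame(validation); df_tr <- df
  }
  vocab <- build_vocab(df_tr$input_span)
  enc <- encode_spans(df_tr$input_span, vocab, spec$s_n)
  enc_va <- encode_spans(va$input_span, vocab, spec$s_n)
  y01 <- as.integer(df_tr$y == 1)

  res <- with_seed(train_cfg$seed, {
    params <- cnn_init_params(spec, vocab)
    nn_train_loop(
      params, nrow(df_tr), y01,
      forward_backward = function(p, rows) {
        dm <- dropout_mask(length(rows), length(spec$w_h) * spec$n_filters,
                           train_cfg$dropout)
        cnn_backward(p, spec, enc$ids[rows, , drop = FALSE], y01[rows], dm)
      },
      predict_scores = function(p, rows) {
        cnn_forward(p, spec, enc_va$ids[rows, , drop = FALSE])$prob
      },
      train_cfg = train_cfg,
      val_rows = seq_len(nrow(va)), val_y01 = as.integer(va$y == 1)
    )
  })
  structure(list(params = res$params, spec = spec, vocab = vocab,
                 val_f1 = res$val_f1, best_epoch = res$best_epoch,
                 seed = train_cfg$seed, n_train = nrow(df_tr)),
            class = c("ade_cnn", "ade_model"))
}

#' @export
predict_candidates.ade_cnn <- function(model, dataset) {
  df <- as.data.frame(dataset)
  if (!nrow(df)) return(prediction_frame(character(), numeric()))
  enc <- encode_spans(df$input_span, model$vocab, model$spec$s_n)
  score <- cnn_forward(model$params, model$spec, enc$ids)$prob
  prediction_frame(df$candidate_id, score)
}
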