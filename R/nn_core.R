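# Shared plumbing for the token-level neural models: vocabulary indexing,
# padding, Adam updates, and the training loop scaffold (mini-batches,
# binary cross-entropy, early stopping on validation F1).

PAD_ID <- 0L
UNK_ID <- 1L

build_vocab <- function(spans) {
  toks <- sort(unique(unlist(lapply(spans, tokenize_text))))
  stats::setNames(seq_along(toks) + 1L, toks)   # ids start at 2 after PAD/UNK
}

# n x S_n integer matrix (PAD_ID-padded/truncated) plus true lengths
encode_spans <- function(spans, vocab, s_n) {
  n <- length(spans)
  ids <- matrix(PAD_ID, nrow = n, ncol = s_n)
  lens <- integer(n)
  for (r in seq_len(n)) {
    toks <- tokenize_text(spans[r])
    if (length(toks) > s_n) toks <- toks[seq_len(s_n)]
    lens[r] <- length(toks)
    if (length(toks)) {
      m <- vocab[toks]
      m[is.na(m)] <- UNK_ID
      ids[r, seq_along(toks)] <- m
    }
  }
  list(ids = ids, lengths = lens)
}

# Embedding matrix rows are indexed by id + 1 (PAD row first, then UNK).
init_embedding <- function(vocab_size, dim, pretrained = NULL, vocab = NULL) {
  E <- matrix(stats::rnorm((vocab_size + 2L) * dim, sd = 0.1),
              nrow = vocab_size + 2L)
  if (!is.null(pretrained)) {
    if (pretrained$dim != dim) {
      stop_ade("ade_config_error",
               "embedding table dimension %d does not match configured S_d %d",
               pretrained$dim, dim)
    }
    E[UNK_ID + 1L, ] <- 0
    toks <- names(vocab)
    E[vocab + 1L, ] <- lookup_embeddings(pretrained, toks)
  }
  E[PAD_ID + 1L, ] <- 0
  E
}

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Generic mini-batch loop with early stopping (patience 3 on validation F1,
# counted only after `min_epochs` so the model can escape the all-negative
# regime on imbalanced data). `forward_backward(params, batch_rows)` returns
# list(loss, grads); `predict_scores(params, rows)` returns probabilities.
nn_train_loop <- function(params, n_rows, y01, forward_backward,
                          predict_scores, train_cfg, val_rows = NULL,
                          val_y01 = NULL, patience = 3L, min_epochs = 5L) {
  opt <- adam_new(params)
  best <- list(f1 = -Inf, params = params, epoch = 0L)
  stale <- 0L
  history <- numeric()
  for (ep in seq_len(train_cfg$epochs)) {
    order <- sample.int(n_rows)
    batches <- split(order, ceiling(seq_along(order) / train_cfg$batch_size))
    for (b in batches) {
      fb <- forward_backward(params, b)
      upd <- adam_step(params, fb$grads, opt, train_cfg$learning_rate)
      params <- upd$params; opt <- upd$state
    }
    if (!is.null(val_rows)) {
      pv <- as.integer(predict_scores(params, val_rows) >= 0.5)
      f1 <- f1_binary(pv, val_y01)
      history <- c(history, f1)
      if (f1 > best$f1 + 1e-9) {
        best <- list(f1 = f1, params = params, epoch = ep)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (ep >= min_epochs && stale >= patience) break
      }
    } else {
      best <- list(f1 = NA_real_, params = params, epoch = ep)
    }
  }
  if (!is.null(val_rows) && best$f1 <= 0) {
    # validation F1 never rose above zero: the checkpoint carries no
    # information, so prefer the most-trained weights
    best <- list(f1 = best$f1, params = params, epoch = train_cfg$epochs)
  }
  list(params = best$params, best_epoch = best$epoch, val_f1 = best$f1,
       history = history)
}

bce_grad <- function(p, y01) {
  # d(mean BCE)/dlogit for sigmoid output
  (p - y01) / length(y01)
}

# dropout mask applied at train time with inverted scaling
dropout_mask <- function(dim1, dim2, rate) {
  if (rate <= 0) return(matrix(1, dim1, dim2))
  matrix(stats::rbinom(dim1 * dim2, 1L, 1 - rate) / (1 - rate), dim1, dim2)
}
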