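# Bidirectional LSTM classifier: embedding -> forward and backward LSTM
# passes -> concatenated terminal states -> dropout -> dense sigmoid head.
# The backward direction is a second LSTM run over each sequence physically
# reversed, so swapping the two directions' weights and reversing every
# input yields mirrored (identical, once the head halves are swapped)
# outputs — an architectural symmetry the tests exercise.

#' BiLSTM specification
#'
#' @param hidden_units Hidden state size per direction (default 16; the
#'   dense head sees `2 * hidden_units` features).
#' @param s_n Maximum tokens per input.
#' @param s_d Embedding dimension (300 with a pretrained table, 32 trained
#'   from scratch).
#' @param embedding Optional `embedding_table`.
#' @param freeze_embedding Keep embedding weights fixed.
#' @return A `bilstm_spec`.
#' @export
bilstm_spec <- function(hidden_units = 16L, s_n = 30L, s_d = 32L,
                        embedding = NULL, freeze_embedding = FALSE) {
  if (s_n < 2L) stop_ade("ade_config_error", "s_n must be at least 2")
  if (hidden_units < 1L) stop_ade("ade_config_error", "hidden_units must be >= 1")
  if (!is.null(embedding) && embedding$dim != s_d) {
    stop_ade("ade_config_error",
             "s_d %d does not match pretrained embedding dimension %d",
             s_d, embedding$dim)
  }
  structure(list(hidden_units = as.integer(hidden_units),
                 s_n = as.integer(s_n), s_d = as.integer(s_d),
                 embedding = embedding,
                 freeze_embedding = isTRUE(freeze_embedding)),
            class = "bilstm_spec")
}

bilstm_init_params <- function(spec, vocab) {
  h <- spec$hidden_units; d <- spec$s_d
  glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  mk_dir <- function() {
    b <- numeric(4 * h)
    b[(h + 1):(2 * h)] <- 1   # forget-gate bias init
    list(W = glorot(d, 4 * h), U = glorot(h, 4 * h), b = b)
  }
  fwd <- mk_dir(); bwd <- mk_dir()
  list(
    E = init_embedding(length(vocab), d, spec$embedding, vocab),
    Wf = fwd$W, Uf = fwd$U, bf = fwd$b,
    Wb = bwd$W, Ub = bwd$U, bb = bwd$b,
    w_out = stats::rnorm(2 * h, sd = 0.1), b_out = 0
  )
}

# reverse each row's first `len` tokens in place (padding stays at the end)
reverse_ids <- function(ids, lengths) {
  out <- ids
  for (r in seq_len(nrow(ids))) {
    l <- lengths[r]
    if (l > 1L) out[r, 1:l] <- ids[r, l:1]
  }
  out
}

# One directional LSTM pass over (b, s, d) embeddings with per-row lengths.
# Gate layout within the 4h columns: input, forget, candidate, output.
lstm_forward_dir <- function(X3, lengths, W, U, b, keep_cache = FALSE) {
  bsz <- dim(X3)[1]; s <- dim(X3)[2]; h <- nrow(U)
  hh <- matrix(0, bsz, h); cc <- matrix(0, bsz, h)
  cache <- if (keep_cache) vector("list", s) else NULL
  for (t in seq_len(s)) {
    x <- matrix(X3[, t, ], nrow = bsz)
    a <- x %*% W + hh %*% U
    a <- sweep(a, 2, b, "+")
    i <- sigmoid(a[, 1:h, drop = FALSE])
    f <- sigmoid(a[, (h + 1):(2 * h), drop = FALSE])
    g <- tanh(a[, (2 * h + 1):(3 * h), drop = FALSE])
    o <- sigmoid(a[, (3 * h + 1):(4 * h), drop = FALSE])
    c_raw <- f * cc + i * g
    h_raw <- o * tanh(c_raw)
    m <- as.numeric(t <= lengths)
    c_new <- m * c_raw + (1 - m) * cc
    h_new <- m * h_raw + (1 - m) * hh
    if (keep_cache) {
      cache[[t]] <- list(x = x, i = i, f = f, g = g, o = o, c_prev = cc,
                         h_prev = hh, c_raw = c_raw, m = m)
    }
    cc <- c_new; hh <- h_new
  }
  list(h = hh, cache = cache)
}

lstm_backward_dir <- function(dh_final, cache, lengths, W, U, X3_dims) {
  bsz <- X3_dims[1]; s <- X3_dims[2]; d <- X3_dims[3]; h <- nrow(U)
  dW <- W * 0; dU <- U * 0; db <- numeric(4 * h)
  dX3 <- array(0, dim = X3_dims)
  dh <- dh_final; dc <- matrix(0, bsz, h)
  for (t in rev(seq_len(s))) {
    ch <- cache[[t]]
    m <- ch$m
    dh_raw <- m * dh; dc_raw <- m * dc
    dh_carry <- (1 - m) * dh; dc_carry <- (1 - m) * dc
    tc <- tanh(ch$c_raw)
    do <- dh_raw * tc
    dc_raw <- dc_raw + dh_raw * ch$o * (1 - tc^2)
    di <- dc_raw * ch$g
    df <- dc_raw * ch$c_prev
    dg <- dc_raw * ch$i
    dc_prev <- dc_raw * ch$f
    da <- cbind(di * ch$i * (1 - ch$i),
                df * ch$f * (1 - ch$f),
                dg * (1 - ch$g^2),
                do * ch$o * (1 - ch$o))
    dW <- dW + crossprod(ch$x, da)
    dU <- dU + crossprod(ch$h_prev, da)
    db <- db + colSums(da)
    dX3[, t, ] <- da %*% t(W)
    dh <- dh_carry + da %*% t(U)
    dc <- dc_carry + dc_prev
  }
  list(dW = dW, dU = dU, db = db, dX3 = dX3)
}

bilstm_forward <- function(params, spec, ids, lengths, drop_mask = NULL,
                           keep_cache = FALSE) {
  bsz <- nrow(ids); s <- ncol(ids); d <- spec$s_d
  X3 <- array(params$E[t(ids) + 1L, ], dim = c(s, bsz, d))
  X3 <- aperm(X3, c(2, 1, 3))
  ids_rev <- reverse_ids(ids, lengths)
  X3r <- array(params$E[t(ids_rev) + 1L, ], dim = c(s, bsz, d))
  X3r <- aperm(X3r, c(2, 1, 3))
  fw <- lstm_forward_dir(X3, lengths, params$Wf, params$Uf, params$bf, keep_cache)
  bw <- lstm_forward_dir(X3r, lengths, params$Wb, params$Ub, params$bb, keep_cache)
  concat <- cbind(fw$h, bw$h)
  dropped <- if (is.null(drop_mask)) concat else concat * drop_mask
  logit <- as.numeric(dropped %*% params$w_out) + params$b_out
  list(prob = sigmoid(logit),
       cache = list(X3 = X3, X3r = X3r, ids = ids, ids_rev = ids_rev,
                    fw = fw, bw = bw, concat = concat, dropped = dropped))
}

bilstm_backward <- function(params, spec, ids, lengths, y01, drop_mask) {
  fwd <- bilstm_forward(params, spec, ids, lengths, drop_mask, keep_cache = TRUE)
  ca <- fwd$cache
  bsz <- nrow(ids); s <- ncol(ids); d <- spec$s_d; h <- spec$hidden_units
  dlogit <- bce_grad(fwd$prob, y01)
  grads <- list()
  grads$w_out <- as.numeric(crossprod(ca$dropped, dlogit))
  grads$b_out <- sum(dlogit)
  dconcat <- (dlogit %o% params$w_out) *
    (if (is.null(drop_mask)) 1 else drop_mask)
  bk_f <- lstm_backward_dir(dconcat[, 1:h, drop = FALSE], ca$fw$cache, lengths,
                            params$Wf, params$Uf, c(bsz, s, d))
  bk_b <- lstm_backward_dir(dconcat[, (h + 1):(2 * h), drop = FALSE],
                            ca$bw$cache, lengths, params$Wb, params$Ub,
                            c(bsz, s, d))
  grads$Wf <- bk_f$dW; grads$Uf <- bk_f$dU; grads$bf <- bk_f$db
  grads$Wb <- bk_b$dW; grads$Ub <- bk_b$dU; grads$bb <- bk_b$db
  if (spec$freeze_embedding) {
    grads$E <- params$E * 0
  } else {
    acc <- function(dX3, idmat) {
      rows <- matrix(dX3, nrow = bsz * s)
      g <- rowsum(rows, group = as.vector(idmat) + 1L, reorder = FALSE)
      full <- matrix(0, nrow = nrow(params$E), ncol = d)
      full[as.integer(rownames(g)), ] <- g
      full
    }
    grads$E <- acc(bk_f$dX3, ca$ids) + acc(bk_b$dX3, ca$ids_rev)
    grads$E[PAD_ID + 1L, ] <- 0
  }
  list(loss = -mean(y01 * log(fwd$prob + 1e-12) +
                      (1 - y01) * log(1 - fwd$prob + 1e-12)),
       grads = grads)
}

#' Train the BiLSTM relation classifier
#'
#' @inheritParams train_cnn
#' @param spec A [bilstm_spec()].
#' @return An `ade_bilstm` model.
#' @export
train_bilstm <- function(dataset, train_cfg = train_config(),
                         spec = bilstm_spec(), validation = NULL) {
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
    params <- bilstm_init_params(spec, vocab)
    nn_train_loop(
      params, nrow(df_tr), y01,
      forward_backward = function(p, rows) {
        dm <- dropout_mask(length(rows), 2L * spec$hidden_units,
                           train_cfg$dropout)
        bilstm_backward(p, spec, enc$ids[rows, , drop = FALSE],
                        enc$lengths[rows], y01[rows], dm)
      },
      predict_scores = function(p, rows) {
        bilstm_forward(p, spec, enc_va$ids[rows, , drop = FALSE],
                       enc_va$lengths[rows])$prob
      },
      train_cfg = train_cfg,
      val_rows = seq_len(nrow(va)), val_y01 = as.integer(va$y == 1)
    )
  })
  structure(list(params = res$params, spec = spec, vocab = vocab,
                 val_f1 = res$val_f1, best_epoch = res$best_epoch,
                 seed = train_cfg$seed, n_train = nrow(df_tr)),
            class = c("ade_bilstm", "ade_model"))
}

#' @export
predict_candidates.ade_bilstm <- function(model, dataset) {
  df <- as.data.frame(dataset)
  if (!nrow(df)) return(prediction_frame(character(), numeric()))
  enc <- encode_spans(df$input_span, model$vocab, model$spec$s_n)
  score <- bilstm_forward(model$params, model$spec, enc$ids, enc$lengths)$prob
  prediction_frame(df$candidate_id, score)
}
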