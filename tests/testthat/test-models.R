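# Model zoo: registry, margin classifier, CNN, BiLSTM, embeddings.

trivial_dataset <- function(n_pos = 30, n_neg = 60) {
  # positives always contain the token "attributed", negatives never do
  pos <- sprintf("colitis attributed to nivolumab v%d", seq_len(n_pos))
  neg <- sprintf("rash and ipilimumab mentioned together v%d", seq_len(n_neg))
  df <- data.frame(
    candidate_id = paste0("c", seq_len(n_pos + n_neg)),
    doc_id = "d", sent_index = 0L,
    drug_surface = "x", ade_surface = "y",
    label = c(rep("positive", n_pos), rep("negative", n_neg)),
    input_span = c(pos, neg),
    sentence_text = c(pos, neg), degenerate = FALSE,
    dedup_key = paste0("k", seq_len(n_pos + n_neg)),
    stringsAsFactors = FALSE
  )
  aderelex:::new_relation_dataset(df, "trivial")
}

test_that("train_config validates the hyperparameter value sets", {
  expect_error(train_config(dropout = 0.05), class = "ade_config_error")
  expect_error(train_config(learning_rate = 0.5), class = "ade_config_error")
  expect_error(train_config(batch_size = 10L), class = "ade_config_error")
  expect_error(train_config(epochs = 0L), class = "ade_config_error")
  expect_s3_class(train_config(), "train_config")
})

test_that("the registry exposes the three in-tree models and accepts adapters", {
  expect_true(all(c("svm", "cnn", "bilstm") %in% registered_models()))
  register_model("const", function(dataset, train_cfg, ...) {
    structure(list(n_train = nrow(dataset), seed = train_cfg$seed),
              class = c("ade_const", "ade_model"))
  }, function(model, dataset) {
    data.frame(candidate_id = dataset$candidate_id, y = 1L, score = 1)
  })
  expect_true("const" %in% registered_models())
  m <- train_relation_model(trivial_dataset(), "const")
  expect_s3_class(m, "ade_model")
  expect_error(train_relation_model(trivial_dataset(), "nope"),
               class = "ade_config_error")
})

test_that("svm separates the trivially separable set perfectly", {
  ds <- trivial_dataset()
  sp <- split_dataset(ds, seed = 3)
  m <- train_svm(sp$train, train_config(epochs = 15L, seed = 1L))
  pred <- predict_candidates(m, sp$test)
  expect_equal(f1_of(pred, as.data.frame(sp$test)), 1)
  expect_true(all(pred$score >= 0 & pred$score <= 1))
  expect_identical(pred$y, as.integer(pred$score >= 0.5))
})

test_that("single-class training data raise a degenerate-model error", {
  df <- as.data.frame(trivial_dataset())
  ds <- aderelex:::new_relation_dataset(df[df$label == "negative", ])
  expect_error(train_svm(ds, train_config(epochs = 2L)),
               class = "ade_degenerate_error")
  expect_error(train_cnn(ds, train_config(epochs = 2L)),
               class = "ade_degenerate_error")
  expect_error(train_bilstm(ds, train_config(epochs = 2L)),
               class = "ade_degenerate_error")
})

test_that("training is reproducible given (dataset order, seed)", {
  ds <- trivial_dataset(15, 30)
  cfg <- train_config(epochs = 5L, seed = 9L)
  m1 <- train_svm(ds, cfg, search = FALSE)
  m2 <- train_svm(ds, cfg, search = FALSE)
  expect_identical(m1$fit$av, m2$fit$av)
  p1 <- predict_candidates(m1, ds); p2 <- predict_candidates(m2, ds)
  expect_identical(p1$score, p2$score)
  mc1 <- train_cnn(ds, cfg, cnn_spec(s_n = 10, s_d = 8, n_filters = 4))
  mc2 <- train_cnn(ds, cfg, cnn_spec(s_n = 10, s_d = 8, n_filters = 4))
  expect_identical(predict_candidates(mc1, ds)$score,
                   predict_candidates(mc2, ds)$score)
  mb1 <- train_bilstm(ds, cfg, bilstm_spec(hidden_units = 4, s_n = 10, s_d = 8))
  mb2 <- train_bilstm(ds, cfg, bilstm_spec(hidden_units = 4, s_n = 10, s_d = 8))
  expect_identical(predict_candidates(mb1, ds)$score,
                   predict_candidates(mb2, ds)$score)
})

test_that("margin-classifier score does not drop when text matches a confident positive", {
  ds <- trivial_dataset()
  m <- train_svm(ds, train_config(epochs = 15L, seed = 1L), search = FALSE)
  tr_pred <- predict_candidates(m, ds)
  best_pos <- as.data.frame(ds)$input_span[which.max(tr_pred$score)]
  probe <- data.frame(candidate_id = c("far", "near"),
                      input_span = c("entirely unrelated text block", best_pos),
                      stringsAsFactors = FALSE)
  pr <- predict_candidates(m, probe)
  expect_gte(pr$score[pr$candidate_id == "near"],
             pr$score[pr$candidate_id == "far"])
})

test_that("cnn pooled feature length is |W_h| x n_filters and shapes hold", {
  spec <- cnn_spec(s_n = 5, s_d = 6, w_h = c(2, 3, 4), n_filters = 8)
  vocab <- stats::setNames(2:6, c("a", "b", "c", "d", "e"))
  params <- with_seed(1, aderelex:::cnn_init_params(spec, vocab))
  ids <- matrix(c(2L, 3L, 4L, 5L, 6L), nrow = 1)
  fw <- aderelex:::cnn_forward(params, spec, ids)
  expect_length(fw$cache$pooled, 24)      # 3 sizes x 8 filters
  expect_length(fw$prob, 1)
  expect_true(fw$prob > 0 && fw$prob < 1)
  expect_error(cnn_spec(s_n = 1), class = "ade_config_error")
})

test_that("an all-zero frozen embedding makes the cnn input-invariant", {
  tab <- embedding_table(matrix(0, nrow = 3, ncol = 6,
                                dimnames = list(c("colitis", "rash", "nivolumab"))))
  ds <- trivial_dataset(10, 20)
  spec <- cnn_spec(s_n = 8, s_d = 6, n_filters = 4, embedding = tab,
                   freeze_embedding = TRUE)
  m <- train_cnn(ds, train_config(epochs = 2L, seed = 2L), spec)
  pr <- predict_candidates(m, ds)
  expect_equal(length(unique(round(pr$score, 12))), 1)
})

test_that("bilstm single-token forward is deterministic and sane", {
  spec <- bilstm_spec(hidden_units = 3, s_n = 4, s_d = 5)
  vocab <- stats::setNames(2L, "rash")
  params <- with_seed(2, aderelex:::bilstm_init_params(spec, vocab))
  ids <- matrix(c(2L, 0L, 0L, 0L), nrow = 1)
  f1 <- aderelex:::bilstm_forward(params, spec, ids, 1L)
  f2 <- aderelex:::bilstm_forward(params, spec, ids, 1L)
  expect_identical(f1$prob, f2$prob)
  # both directions read the same single token: with tied direction weights
  # the two terminal states coincide
  tied <- params
  tied[c("Wb", "Ub", "bb")] <- params[c("Wf", "Uf", "bf")]
  f3 <- aderelex:::bilstm_forward(tied, spec, ids, 1L)
  expect_equal(f3$cache$fw$h, f3$cache$bw$h, tolerance = 1e-12)
})

test_that("reversing inputs and swapping direction weights mirrors the bilstm", {
  spec <- bilstm_spec(hidden_units = 2, s_n = 6, s_d = 4)
  vocab <- stats::setNames(2:7, letters[1:6])
  params <- with_seed(5, aderelex:::bilstm_init_params(spec, vocab))
  ids <- rbind(c(2L, 4L, 6L, 3L, 0L, 0L), c(7L, 5L, 2L, 0L, 0L, 0L))
  lens <- c(4L, 3L)
  base <- aderelex:::bilstm_forward(params, spec, ids, lens)
  swapped <- params
  swapped[c("Wf", "Uf", "bf")] <- params[c("Wb", "Ub", "bb")]
  swapped[c("Wb", "Ub", "bb")] <- params[c("Wf", "Uf", "bf")]
  h <- spec$hidden_units
  swapped$w_out <- c(params$w_out[(h + 1):(2 * h)], params$w_out[1:h])
  rev_ids <- aderelex:::reverse_ids(ids, lens)
  mirrored <- aderelex:::bilstm_forward(swapped, spec, rev_ids, lens)
  expect_equal(mirrored$prob, base$prob, tolerance = 1e-12)
})

test_that("load_embeddings reads the text format and applies OOV policy", {
  path <- withr::local_tempfile(fileext = ".vec")
  writeLines(c("rash 0.1 0.2 0.3 0.4",
               "Colitis 1 0 0 1",
               "nivolumab -1 2 0.5 0"), path)
  tab <- load_embeddings(path)
  expect_equal(tab$dim, 4)
  expect_equal(nrow(tab$vectors), 3)
  # case-folded lookup
  expect_equal(lookup_embeddings(tab, "colitis")[1, ], c(1, 0, 0, 1))
  expect_equal(lookup_embeddings(tab, "RASH")[1, 2], 0.2)
  # zero OOV policy
  expect_equal(lookup_embeddings(tab, "unknowntok")[1, ], rep(0, 4))
  # random OOV policy is deterministic per token
  tabr <- load_embeddings(path, oov_policy = "random", seed = 3L)
  v1 <- lookup_embeddings(tabr, "mystery")[1, ]
  v2 <- lookup_embeddings(tabr, "mystery")[1, ]
  expect_identical(v1, v2)
  expect_false(all(v1 == 0))
  # ragged file errors with the offending line
  writeLines(c("a 1 2", "b 1 2 3"), path)
  expect_error(load_embeddings(path), class = "ade_format_error")
})

test_that("prediction on an empty candidate list is empty", {
  ds <- trivial_dataset(10, 20)
  m <- train_svm(ds, train_config(epochs = 3L, seed = 1L), search = FALSE)
  empty <- as.data.frame(ds)[0, ]
  expect_equal(nrow(predict_candidates(m, empty)), 0)
})

test_that("pretrained embeddings can back the neural models", {
  ds <- trivial_dataset(12, 24)
  toks <- unique(unlist(lapply(as.data.frame(ds)$input_span, tokenize_text)))
  mat <- with_seed(8, matrix(stats::rnorm(length(toks) * 6), ncol = 6,
                             dimnames = list(toks)))
  tab <- embedding_table(mat)
  m <- train_cnn(ds, train_config(epochs = 4L, seed = 2L),
                 cnn_spec(s_n = 8, s_d = 6, n_filters = 4, embedding = tab))
  expect_s3_class(m, "ade_cnn")
  expect_error(cnn_spec(s_d = 10, embedding = tab), class = "ade_config_error")
})
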