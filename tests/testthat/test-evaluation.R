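test_that("score_predictions computes the closed-form identities", {
  gold <- data.frame(candidate_id = as.character(1:12),
                     label = c(rep("positive", 10), rep("negative", 2)))
  # tp=8, fp=2, fn=2: predict positives on 8 true + the 2 negatives
  pred <- data.frame(candidate_id = as.character(1:12),
                     y = c(rep(1, 8), 0, 0, 1, 1))
  r <- score_predictions(pred, gold)
  expect_equal(r$tp, 8); expect_equal(r$fp, 2); expect_equal(r$fn, 2)
  expect_equal(r$precision, 0.8)
  expect_equal(r$recall, 0.8)
  expect_equal(r$f1, 0.8)
  expect_equal(r$f1, 2 * r$precision * r$recall / (r$precision + r$recall))
})

test_that("undefined ratios are zero with a flag", {
  gold <- data.frame(candidate_id = as.character(1:4),
                     label = c("positive", "positive", "negative", "negative"))
  all_neg <- data.frame(candidate_id = as.character(1:4), y = 0)
  r <- score_predictions(all_neg, gold)
  expect_equal(r$recall, 0)
  expect_true("precision" %in% r$undefined)
  expect_equal(r$f1, 0)
})

test_that("missing predictions raise a coverage error naming ids", {
  gold <- data.frame(candidate_id = c("a", "b"), label = c("positive", "negative"))
  pred <- data.frame(candidate_id = "a", y = 1)
  expect_error(score_predictions(pred, gold), class = "ade_coverage_error")
})

test_that("a random predictor's precision approaches prevalence", {
  n <- 10000; prev <- 0.2
  labels <- with_seed(42, sample(c("positive", "negative"), n, TRUE,
                                 prob = c(prev, 1 - prev)))
  gold <- data.frame(candidate_id = as.character(seq_len(n)), label = labels)
  pred <- data.frame(candidate_id = as.character(seq_len(n)),
                     y = with_seed(43, stats::rbinom(n, 1, 0.5)))
  r <- score_predictions(pred, gold)
  se <- sqrt(prev * (1 - prev) / (r$tp + r$fp))
  expect_lt(abs(r$precision - prev), 3 * se)
})

test_that("stratified folds are disjoint, exhaustive, and class-balanced", {
  labels <- c(rep("positive", 23), rep("negative", 77))
  fold <- stratified_folds(labels, k = 5, seed = 11)
  expect_length(fold, 100)
  expect_setequal(unique(fold), 1:5)
  for (f in 1:5) {
    expect_true(any(labels[fold == f] == "positive"))
    expect_true(any(labels[fold == f] == "negative"))
  }
  expect_error(stratified_folds(c("a", rep("b", 50)), k = 5),
               class = "ade_stratification_error")
})

test_that("5-fold CV tests every candidate exactly once and pools counts", {
  ds <- signal_dataset()
  rep <- run_intra(ds, "svm", "intra_cv",
                   train_config(epochs = 10L, seed = 4L), search = FALSE)
  expect_equal(rep$tp + rep$fp + rep$fn + rep$tn,
               sum(!as.data.frame(ds)$degenerate))
  expect_equal(rep$protocol, "intra_cv")
  folds <- attr(rep, "fold_reports")
  expect_length(folds, 5)
  expect_equal(sum(vapply(folds, function(f) f$tp + f$fp + f$fn + f$tn, 0)),
               rep$tp + rep$fp + rep$fn + rep$tn)
  # perfect-signal corpus: pooled F1 >= 0.95
  expect_gte(rep$f1, 0.95)
})

test_that("intra_fixed honors the provided split", {
  ds <- signal_dataset()
  df <- as.data.frame(ds)
  split <- rep("train", nrow(df))
  split[with_seed(5, sample.int(nrow(df), floor(nrow(df) / 3)))] <- "test"
  rep <- run_intra(ds, "svm", "intra_fixed",
                   train_config(epochs = 10L, seed = 4L), split = split,
                   search = FALSE)
  expect_equal(rep$tp + rep$fp + rep$fn + rep$tn,
               sum(split == "test" & !df$degenerate))
})

test_that("run_inter trains on one corpus, tests fully on the other", {
  gen_b <- fixture("signal_b", function() {
    generate_corpus(synth_config(n_patients = 10, notes_per_patient = c(4, 6),
                                 p_positive_sentence = 0.4,
                                 signal_strength = 1.0,
                                 p_cross_sentence_relation = 0, seed = 303,
                                 corpus_id = "signal-b"))
  })
  ds_a <- signal_dataset()
  ds_b <- build_relation_dataset(gen_b$corpus)
  # same templated generator: a few verbatim candidate collisions across the
  # corpora are expected and must surface as a leakage warning
  expect_warning(
    rep <- run_inter(ds_a, ds_b, "svm", train_config(epochs = 10L, seed = 4L)),
    "leakage")
  expect_equal(rep$protocol, "inter")
  expect_equal(rep$train_corpus, "synthetic")
  expect_equal(rep$test_corpus, "signal-b")
  expect_equal(rep$tp + rep$fp + rep$fn + rep$tn, nrow(ds_b))
  # same generative signal: inter F1 within 0.1 of intra F1
  intra <- run_intra(ds_a, "svm", "intra_cv",
                     train_config(epochs = 10L, seed = 4L), search = FALSE)
  expect_lt(abs(rep$f1 - intra$f1), 0.1)
  expect_error(run_inter(ds_a, ds_b[0, ], "svm"), class = "ade_config_error")
})

test_that("cohen_kappa matches hand computations and is symmetric", {
  expect_equal(cohen_kappa(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  # p_o = 0.5, p_e = 0.5 -> kappa = 0
  expect_equal(cohen_kappa(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0)
  a <- with_seed(6, sample(0:2, 40, TRUE))
  b <- with_seed(7, sample(0:2, 40, TRUE))
  expect_equal(cohen_kappa(a, b), cohen_kappa(b, a))
  expect_gte(cohen_kappa(a, b), -1)
  expect_lte(cohen_kappa(a, b), 1)
  expect_error(cohen_kappa(1:3, 1:4), class = "ade_config_error")
  # degenerate marginals: both raters constant on the same category
  expect_equal(cohen_kappa(c("x", "x"), c("x", "x")), 1)
  # constant but fully disjoint raters: p_o = p_e = 0 -> kappa = 0
  expect_equal(cohen_kappa(c("x", "x"), c("y", "y")), 0)
})

test_that("pairwise F agreement handles identical, partial, disjoint sets", {
  txt <- paste(sprintf("drug%02d", 1:10), collapse = " ")
  mk <- function(ids) {
    ents <- do.call(rbind, lapply(ids, function(i) {
      start <- (i - 1L) * 7L
      data.frame(id = paste0("T", i), label = "DRUG", start = start,
                 end = start + 6L, surface = sprintf("drug%02d", i),
                 fragmented = FALSE, stringsAsFactors = FALSE)
    }))
    ade_document("doc1", txt, ents)
  }
  a <- list(mk(1:10))
  # B shares 8 spans, adds 2 different ones -> P = R = F = 0.8
  b <- list(ade_document("doc1", txt,
                         rbind(mk(1:8)$entities,
                               data.frame(id = c("T11", "T12"), label = "DRUG",
                                          start = c(60L, 65L), end = c(62L, 68L),
                                          surface = c(substring(txt, 61, 62),
                                                      substring(txt, 66, 68)),
                                          fragmented = FALSE))))
  agg <- pairwise_f_agreement(a, b)
  expect_equal(agg$precision[agg$type == "DRUG"], 0.8)
  expect_equal(agg$recall[agg$type == "DRUG"], 0.8)
  expect_equal(agg$f[agg$type == "DRUG"], 0.8)

  ident <- pairwise_f_agreement(a, a)
  expect_equal(ident$f, 1)

  disjoint <- pairwise_f_agreement(a, list(ade_document("doc1", txt)))
  expect_equal(disjoint$f[disjoint$type == "DRUG"], 0)

  expect_error(pairwise_f_agreement(a, list(ade_document("other", txt))),
               class = "ade_config_error")
})

test_that("pairwise F covers relation types via argument spans", {
  txt <- "rash from nivolumab"
  ents <- data.frame(id = c("T1", "T2"), label = c("ADE", "DRUG"),
                     start = c(0L, 10L), end = c(4L, 19L),
                     surface = c("rash", "nivolumab"), fragmented = FALSE)
  rels <- data.frame(id = "R1", type = "DRUG_ADE", arg1 = "T2", arg2 = "T1")
  a <- list(ade_document("d", txt, ents, rels))
  # same relation with different entity ids still matches (span-keyed)
  ents2 <- ents; ents2$id <- c("T9", "T8")
  rels2 <- data.frame(id = "R7", type = "DRUG_ADE", arg1 = "T8", arg2 = "T9")
  b <- list(ade_document("d", txt, ents2, rels2))
  agg <- pairwise_f_agreement(a, b)
  expect_equal(agg$f[agg$type == "DRUG_ADE"], 1)
})

test_that("agreement matrix and cluster map behave on planted structure", {
  gold <- aderelex:::new_relation_dataset(data.frame(
    candidate_id = paste0("c", 1:8),
    label = c(rep("positive", 4), rep("negative", 4)),
    input_span = "x", degenerate = FALSE, dedup_key = paste0("k", 1:8),
    stringsAsFactors = FALSE
  ))
  truth <- c(1, 1, 1, 1, 0, 0, 0, 0)
  mk_pred <- function(y) data.frame(candidate_id = paste0("c", 1:8), y = y,
                                    score = y)
  preds <- list(
    m1 = mk_pred(c(1, 1, 1, 1, 0, 0, 0, 1)),
    m2 = mk_pred(c(1, 1, 1, 1, 0, 0, 0, 1)),   # identical to m1
    m3 = mk_pred(c(0, 0, 0, 0, 1, 1, 1, 1))
  )
  m <- agreement_matrix(preds, gold)
  expect_equal(dim(m), c(3, 8))
  expect_true(all(m %in% 0:1))
  cm <- agreement_cluster_map(m)
  # identical rows merge at height 0 and sit adjacent
  expect_equal(cm$tree$height[1], 0)
  ord <- match(c("m1", "m2"), cm$order)
  expect_equal(abs(diff(ord)), 1)
  # positive-class map restricts columns
  mp <- agreement_matrix(preds, gold, class = "positive")
  expect_equal(ncol(mp), 4)
  expect_error(agreement_cluster_map(m[1, , drop = FALSE]),
               class = "ade_config_error")
})

test_that("cluster order is consistent with brute-force Hamming distances", {
  with_seed(9, {
    base <- stats::rbinom(40, 1, 0.8)
    flip <- function(v, k) { i <- sample.int(40, k); v[i] <- 1 - v[i]; v }
    m <- rbind(m1 = base, m2 = flip(base, 1), m3 = flip(base, 2),
               m4 = flip(base, 15), m5 = flip(base, 16))
  })
  cm <- agreement_cluster_map(m)
  # brute-force all-pairs Hamming: the closest pair must merge first
  d <- as.matrix(stats::dist(m, method = "manhattan")) / ncol(m)
  diag(d) <- Inf
  closest <- which(d == min(d), arr.ind = TRUE)[1, ]
  first_merge <- -cm$tree$merge[1, ]
  expect_setequal(sort(as.integer(first_merge)), sort(as.integer(closest)))
  # and the two cluster blocks {m1,m2,m3}, {m4,m5} are contiguous in order
  blockA <- match(c("m1", "m2", "m3"), cm$order)
  expect_equal(diff(range(blockA)), 2)
})

test_that("eval reports serialize to JSON with provenance", {
  gold <- data.frame(candidate_id = c("a", "b"), label = c("positive", "negative"))
  pred <- data.frame(candidate_id = c("a", "b"), y = c(1, 0))
  r <- score_predictions(pred, gold, model_id = "svm", train_corpus = "A",
                         test_corpus = "B", protocol = "inter")
  path <- withr::local_tempfile(fileext = ".json")
  write_eval_report(r, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$model_id, "svm")
  expect_equal(back$split_seed, 1218679)
  expect_equal(back$f1, 1)
})
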