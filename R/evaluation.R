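# Scoring, intra-/inter-corpus evaluation protocols, inter-annotator
# agreement, and model-agreement cluster maps.

#' Score predictions against gold labels
#'
#' Positive-class precision/recall/F1 from one prediction per gold
#' candidate. Undefined ratios (zero denominators) are reported as 0 with
#' the `undefined` flag naming which.
#'
#' @param predictions Data frame with `candidate_id` and `y` (0/1), as
#'   returned by [predict_candidates()].
#' @param gold A `relation_dataset` (or data frame with `candidate_id` and
#'   `label`).
#' @param model_id,train_corpus,test_corpus,protocol Provenance fields
#'   recorded on the report.
#' @return An `eval_report`: list with `tp`, `fp`, `fn`, `tn`, `precision`,
#'   `recall`, `f1`, `undefined`, and the provenance fields.
#' @export
score_predictions <- function(predictions, gold, model_id = NA_character_,
                              train_corpus = NA_character_,
                              test_corpus = NA_character_,
                              protocol = NA_character_) {
  gold_df <- as.data.frame(gold)
  missing <- setdiff(gold_df$candidate_id, predictions$candidate_id)
  if (length(missing)) {
    stop_ade("ade_coverage_error", "missing predictions for %d candidate(s): %s",
             length(missing), paste(utils::head(missing, 5), collapse = ", "))
  }
  pred <- predictions$y[match(gold_df$candidate_id, predictions$candidate_id)]
  truth <- as.integer(gold_df$label == "positive")
  tp <- sum(pred == 1 & truth == 1); fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1); tn <- sum(pred == 0 & truth == 0)
  undefined <- character()
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    undefined <- c(undefined, "precision"); 0
  }
  recall <- if (tp + fn > 0) tp / (tp + fn) else {
    undefined <- c(undefined, "recall"); 0
  }
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    undefined <- c(undefined, "f1"); 0
  }
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, precision = precision,
                 recall = recall, f1 = f1, undefined = undefined,
                 model_id = model_id, train_corpus = train_corpus,
                 test_corpus = test_corpus, protocol = protocol,
                 split_seed = DEFAULT_SPLIT_SEED),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s [%s] %s->%s | P %.3f R %.3f F1 %.3f (tp %d fp %d fn %d tn %d)\n",
              x$model_id, x$protocol, x$train_corpus, x$test_corpus,
              x$precision, x$recall, x$f1, x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#' @param report An `eval_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Intra-corpus evaluation
#'
#' `protocol = "intra_cv"`: stratified 5-fold cross-validation with pooled
#' (micro) confusion counts — every candidate is tested exactly once.
#' `protocol = "intra_fixed"`: honors a provided train/test assignment (the
#' `split` argument or a `split` column with values "train"/"test").
#'
#' @param dataset A `relation_dataset` containing both classes.
#' @param model_name Registry key ("svm", "cnn", "bilstm", ...).
#' @param protocol `"intra_cv"` or `"intra_fixed"`.
#' @param train_cfg A [train_config()].
#' @param k Folds for `intra_cv`.
#' @param split Character vector ("train"/"test", one per candidate) for
#'   `intra_fixed`.
#' @param pool Pool fold confusions (micro, default) or average per-fold F1
#'   (`FALSE`; the per-fold reports are attached as an attribute).
#' @param ... Passed to the model trainer.
#' @return An `eval_report`.
#' @export
run_intra <- function(dataset, model_name, protocol = c("intra_cv", "intra_fixed"),
                      train_cfg = train_config(), k = 5L, split = NULL,
                      pool = TRUE, ...) {
  protocol <- match.arg(protocol)
  df <- as.data.frame(dataset)
  corpus_id <- attr(dataset, "source_corpus")
  if (protocol == "intra_fixed") {
    split <- split %||% df$split
    if (is.null(split)) {
      stop_ade("ade_config_error",
               "intra_fixed requires a split column or argument")
    }
    tr <- new_relation_dataset(df[split == "train", , drop = FALSE], corpus_id)
    te <- df[split == "test", , drop = FALSE]
    model <- train_relation_model(tr, model_name, train_cfg, ...)
    pred <- predict_candidates(model, te)
    return(score_predictions(pred, new_relation_dataset(te, corpus_id),
                             model_id = model_name, train_corpus = corpus_id,
                             test_corpus = corpus_id, protocol = protocol))
  }
  fold <- stratified_folds(df$label, k = k, seed = train_cfg$seed)
  preds <- vector("list", k)
  fold_reports <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- new_relation_dataset(df[fold != f, , drop = FALSE], corpus_id)
    te <- df[fold == f, , drop = FALSE]
    model <- train_relation_model(tr, model_name, train_cfg, ...)
    preds[[f]] <- predict_candidates(model, te)
    fold_reports[[f]] <- score_predictions(preds[[f]],
                                           new_relation_dataset(te, corpus_id),
                                           model_id = model_name,
                                           train_corpus = corpus_id,
                                           test_corpus = corpus_id,
                                           protocol = "intra_cv_fold")
  }
  all_pred <- do.call(rbind, preds)
  report <- score_predictions(all_pred, dataset, model_id = model_name,
                              train_corpus = corpus_id,
                              test_corpus = corpus_id, protocol = protocol)
  if (!pool) {
    report$f1 <- mean(vapply(fold_reports, `[[`, 0, "f1"))
    report$protocol <- "intra_cv_foldmean"
  }
  attr(report, "fold_reports") <- fold_reports
  report
}

#' Inter-corpus evaluation
#'
#' Trains on one corpus and tests on the other: a seeded stratified 30% of
#' the training corpus serves as the internal validation split (model
#' selection / early stopping only), the model is then applied once to the
#' full external test corpus. Overlapping dedup keys between the two
#' corpora trigger a leakage warning with the overlap count.
#'
#' @param train_dataset,test_dataset `relation_dataset`s from distinct
#'   corpora.
#' @param model_name Registry key.
#' @param train_cfg A [train_config()].
#' @param p_internal Internal validation fraction (default 0.3).
#' @param ... Passed to the trainer.
#' @return An `eval_report` labeled with both corpus ids.
#' @export
run_inter <- function(train_dataset, test_dataset, model_name,
                      train_cfg = train_config(), p_internal = 0.3, ...) {
  if (!nrow(test_dataset)) {
    stop_ade("ade_config_error", "empty test dataset")
  }
  overlap <- intersect(train_dataset$dedup_key, test_dataset$dedup_key)
  if (length(overlap)) {
    warning(sprintf("%d candidate key(s) occur in both corpora (possible leakage)",
                    length(overlap)))
  }
  df <- as.data.frame(train_dataset)
  corpus_tr <- attr(train_dataset, "source_corpus")
  corpus_te <- attr(test_dataset, "source_corpus")
  sp <- stratified_holdout(df$label, p_internal, seed = train_cfg$seed)
  tr <- new_relation_dataset(df[sp$train, , drop = FALSE], corpus_tr)
  va <- new_relation_dataset(df[sp$holdout, , drop = FALSE], corpus_tr)
  model <- if (model_name %in% c("cnn", "bilstm")) {
    train_relation_model(tr, model_name, train_cfg, validation = va, ...)
  } else {
    # the margin classifier runs its own internal grid-search split
    train_relation_model(new_relation_dataset(df, corpus_tr), model_name,
                         train_cfg, ...)
  }
  pred <- predict_candidates(model, test_dataset)
  score_predictions(pred, test_dataset, model_id = model_name,
                    train_corpus = corpus_tr, test_corpus = corpus_te,
                    protocol = "inter")
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with
#' marginal-product expected agreement. When `p_e = 1` (both raters fully
#' concentrated on one category each) kappa is defined as 1 for identical
#' sequences and an error otherwise.
#'
#' @param labels_a,labels_b Equal-length categorical vectors.
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop_ade("ade_config_error", "label sequences differ in length (%d vs %d)",
             length(labels_a), length(labels_b))
  }
  if (!length(labels_a)) {
    stop_ade("ade_config_error", "empty label sequences")
  }
  a <- as.character(labels_a); b <- as.character(labels_b)
  p_o <- mean(a == b)
  cats <- union(a, b)
  p_e <- sum(vapply(cats, function(ct) mean(a == ct) * mean(b == ct), 0))
  if (p_e >= 1 - 1e-12) {
    if (all(a == b)) return(1)
    stop_ade("ade_degenerate_error",
             "expected agreement is 1 but sequences differ; kappa undefined")
  }
  (p_o - p_e) / (1 - p_e)
}

#' Pairwise F agreement between two annotation sets
#'
#' Inter-annotator agreement as an F-score, per annotation type: exact
#' span + label match for entities, exact (type, argument-pair) match for
#' relations. Set A is treated as reference; F is symmetric in the two sets
#' by construction.
#'
#' @param docs_a,docs_b Named lists of `ade_document`s over the same doc
#'   ids (two annotators' versions of the same notes).
#' @return Data frame with `type`, `n_a`, `n_b`, `n_match`, `precision`,
#'   `recall`, `f` (fractions in `[0, 1]`).
#' @export
pairwise_f_agreement <- function(docs_a, docs_b) {
  ids_a <- vapply(docs_a, `[[`, "", "doc_id")
  ids_b <- vapply(docs_b, `[[`, "", "doc_id")
  if (!setequal(ids_a, ids_b)) {
    stop_ade("ade_config_error",
             "annotation sets cover different documents")
  }
  names(docs_a) <- ids_a; names(docs_b) <- ids_b
  ent_keys <- function(doc) {
    e <- doc$entities
    if (!nrow(e)) return(data.frame(type = character(), key = character()))
    data.frame(type = e$label,
               key = paste(doc$doc_id, e$label, e$start, e$end),
               stringsAsFactors = FALSE)
  }
  rel_keys <- function(doc) {
    r <- doc$relations
    if (!nrow(r)) return(data.frame(type = character(), key = character()))
    e <- doc$entities
    span_of <- function(id) {
      i <- match(id, e$id)
      paste(e$start[i], e$end[i])
    }
    data.frame(type = r$type,
               key = paste(doc$doc_id, r$type,
                           vapply(r$arg1, span_of, ""),
                           vapply(r$arg2, span_of, "")),
               stringsAsFactors = FALSE)
  }
  collect <- function(docs) {
    do.call(rbind, c(lapply(docs, ent_keys), lapply(docs, rel_keys)))
  }
  ka <- collect(docs_a); kb <- collect(docs_b)
  types <- sort(union(ka$type, kb$type))
  out <- lapply(types, function(tp) {
    a <- unique(ka$key[ka$type == tp]); b <- unique(kb$key[kb$type == tp])
    n_match <- length(intersect(a, b))
    p <- if (length(b)) n_match / length(b) else 0
    r <- if (length(a)) n_match / length(a) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    data.frame(type = tp, n_a = length(a), n_b = length(b), n_match = n_match,
               precision = p, recall = r, f = f, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Build the model-agreement matrix
#'
#' Rows = models, columns = candidates, cell = 1 when the model's predicted
#' label equals the true label. The column order is the gold dataset order
#' and identical across models.
#'
#' @param predictions Named list of prediction data frames (one per model).
#' @param gold A `relation_dataset`.
#' @param class Restrict columns to `"positive"` or `"negative"` gold
#'   candidates, or `"all"`.
#' @return Binary matrix with model rownames and candidate_id colnames.
#' @export
agreement_matrix <- function(predictions, gold, class = c("all", "positive", "negative")) {
  class <- match.arg(class)
  gold_df <- as.data.frame(gold)
  if (class != "all") gold_df <- gold_df[gold_df$label == class, , drop = FALSE]
  truth <- as.integer(gold_df$label == "positive")
  rows <- lapply(predictions, function(pr) {
    y <- pr$y[match(gold_df$candidate_id, pr$candidate_id)]
    if (anyNA(y)) {
      stop_ade("ade_coverage_error", "prediction set missing candidates")
    }
    as.integer(y == truth)
  })
  m <- do.call(rbind, rows)
  rownames(m) <- names(predictions)
  colnames(m) <- gold_df$candidate_id
  m
}

#' Cluster models by their per-sample agreement pattern
#'
#' Hierarchical agglomerative clustering of the model rows of an agreement
#' matrix under Hamming distance with average linkage. Returns the row
#' order, the `hclust` tree, and the matrix reordered for rendering; use
#' separate matrices for positive- and negative-class maps.
#'
#' @param matrix Binary model-by-sample matrix from [agreement_matrix()].
#' @return List with `order` (model names), `tree` (`hclust`), `matrix`
#'   (rows reordered).
#' @export
agreement_cluster_map <- function(matrix) {
  if (nrow(matrix) < 2L) {
    stop_ade("ade_config_error", "need at least two models to cluster")
  }
  if (ncol(matrix) < 2L) {
    warning("single-sample agreement matrix; clustering is degenerate")
  }
  d <- stats::dist(matrix, method = "manhattan") / ncol(matrix)  # Hamming
  tree <- stats::hclust(d, method = "average")
  ord <- rownames(matrix)[tree$order]
  list(order = ord, tree = tree, matrix = matrix[ord, , drop = FALSE])
}

#' Render a cluster map to an image file
#'
#' Simple base-graphics rendering (yellow = model correct, blue = model
#' wrong) with rows in clustered order; the machine-readable row order is
#' written alongside as `<path>.order.txt`.
#'
#' @param cmap Result of [agreement_cluster_map()].
#' @param path PNG output path.
#' @return Invisibly, `path`.
#' @export
plot_cluster_map <- function(cmap, path) {
  grDevices::png(path, width = 900, height = 300)
  on.exit(grDevices::dev.off())
  m <- cmap$matrix
  graphics::image(t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  col = c("#27408B", "#FFD700"), axes = FALSE,
                  main = "model agreement (yellow = correct)")
  graphics::axis(2, at = seq(0, 1, length.out = nrow(m)),
                 labels = rev(rownames(m)), las = 1, tick = FALSE)
  writeLines(cmap$order, paste0(path, ".order.txt"))
  invisible(path)
}
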