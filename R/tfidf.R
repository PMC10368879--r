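# Character n-gram TF-IDF vectorization.
#
# Fixed variant (the common "smoothed idf" form):
#   idf(g) = ln((1 + N) / (1 + df(g))) + 1,  rows L2-normalized,
# with the vocabulary built from the training spans only; transforming
# unseen text uses the fitted vocabulary and idf, so no test information
# can leak into the representation.

#' n-gram configuration
#'
#' @param n_min,n_max Inclusive n-gram size range, `1 <= n_min <= n_max <= 8`.
#' @param level `"character"` (used by the margin classifier) or `"token"`.
#' @return An `ngram_config`.
#' @export
ngram_config <- function(n_min = 2L, n_max = 5L, level = c("character", "token")) {
  level <- match.arg(level)
  if (!(n_min >= 1 && n_min <= n_max && n_max <= 8)) {
    stop_ade("ade_config_error", "require 1 <= n_min <= n_max <= 8")
  }
  structure(list(n_min = as.integer(n_min), n_max = as.integer(n_max),
                 level = level), class = "ngram_config")
}

char_ngrams <- function(text, n_min, n_max) {
  text <- tolower(text)
  len <- nchar(text)
  out <- character()
  for (n in n_min:n_max) {
    if (len < n) next
    starts <- seq_len(len - n + 1L)
    out <- c(out, substring(text, starts, starts + n - 1L))
  }
  out
}

token_ngrams <- function(text, n_min, n_max) {
  toks <- tokenize_text(text)
  out <- character()
  for (n in n_min:n_max) {
    if (length(toks) < n) next
    starts <- seq_len(length(toks) - n + 1L)
    out <- c(out, vapply(starts, function(s)
      paste(toks[s:(s + n - 1L)], collapse = " "), ""))
  }
  out
}

extract_ngrams <- function(text, config) {
  if (config$level == "character") char_ngrams(text, config$n_min, config$n_max)
  else token_ngrams(text, config$n_min, config$n_max)
}

#' Fit a character/token n-gram TF-IDF vectorizer
#'
#' @param corpus_spans Character vector of training input spans (non-empty).
#' @param config An [ngram_config()].
#' @return A `tfidf_vectorizer` holding the vocabulary and idf weights.
#' @export
char_ngram_tfidf_fit <- function(corpus_spans, config = ngram_config()) {
  if (!length(corpus_spans)) {
    stop_ade("ade_config_error", "corpus_spans must be non-empty")
  }
  max_len <- max(nchar(corpus_spans))
  if (config$level == "character" && config$n_max > max_len) {
    warning(sprintf("n_max %d exceeds longest span (%d chars); vocabulary from shorter grams only",
                    config$n_max, max_len))
  }
  grams <- lapply(corpus_spans, extract_ngrams, config = config)
  vocab <- sort(unique(unlist(grams)))
  if (!length(vocab)) {
    stop_ade("ade_config_error", "no n-grams extractable from the training spans")
  }
  df <- integer(length(vocab))
  names(df) <- vocab
  for (g in grams) {
    u <- unique(g)
    df[u] <- df[u] + 1L
  }
  n_docs <- length(corpus_spans)
  idf <- log((1 + n_docs) / (1 + df)) + 1
  structure(list(vocab = vocab, idf = idf, config = config, n_docs = n_docs),
            class = "tfidf_vectorizer")
}

#' Transform spans with a fitted TF-IDF vectorizer
#'
#' @param vectorizer A fitted `tfidf_vectorizer`.
#' @param spans Character vector.
#' @return Sparse `dgCMatrix` (rows = spans, columns = fitted vocabulary);
#'   rows are L2-unit or all-zero (when a span shares no n-gram with the
#'   vocabulary).
#' @export
tfidf_transform <- function(vectorizer, spans) {
  i <- integer(); j <- integer(); x <- numeric()
  for (r in seq_along(spans)) {
    grams <- extract_ngrams(spans[r], vectorizer$config)
    grams <- grams[grams %in% vectorizer$vocab]
    if (!length(grams)) next
    tab <- table(grams)
    cols <- match(names(tab), vectorizer$vocab)
    vals <- as.numeric(tab) * vectorizer$idf[cols]
    nrm <- sqrt(sum(vals^2))
    if (nrm > 0) vals <- vals / nrm
    i <- c(i, rep.int(r, length(cols))); j <- c(j, cols); x <- c(x, vals)
  }
  Matrix::sparseMatrix(i = i, j = j, x = x,
                       dims = c(length(spans), length(vectorizer$vocab)),
                       dimnames = list(NULL, vectorizer$vocab))
}
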