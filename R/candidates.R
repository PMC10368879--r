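# Candidate-relation construction: every within-sentence (drug, ADE) mention
# pair is a candidate; a candidate is positive iff the gold annotation links
# that exact entity pair, otherwise it is a derived negative. Cross-sentence
# gold relations contribute no candidates (single-sentence scope).

candidate_columns <- c(
  "candidate_id", "doc_id", "sent_index",
  "drug_id", "drug_surface", "drug_start", "drug_end",
  "ade_id", "ade_surface", "ade_start", "ade_end",
  "label", "input_span", "sentence_text", "degenerate", "dedup_key"
)

empty_candidates <- function() {
  out <- data.frame(
    candidate_id = character(), doc_id = character(), sent_index = integer(),
    drug_id = character(), drug_surface = character(),
    drug_start = integer(), drug_end = integer(),
    ade_id = character(), ade_surface = character(),
    ade_start = integer(), ade_end = integer(),
    label = character(), input_span = character(),
    sentence_text = character(), degenerate = logical(),
    dedup_key = character(), stringsAsFactors = FALSE
  )
  out
}

#' Extract the entity-bounded input span
#'
#' The classifier input for a candidate: the sentence substring from the
#' start of the earlier-starting entity to the end of the later-ending
#' entity — the drug, the ADE, and everything between, whichever order they
#' occur in.
#'
#' @param sentence One row of a [segment_sentences()] data frame.
#' @param drug,ade Entity rows (document-level 0-based offsets) lying inside
#'   the sentence.
#' @return List with `span` (string), `degenerate` (`TRUE` when the two
#'   entity spans overlap; the envelope is still returned), and the
#'   document-level `start`/`end` of the span.
#' @export
extract_input_span <- function(sentence, drug, ade) {
  if (drug$start < sentence$start || drug$end > sentence$end ||
      ade$start < sentence$start || ade$end > sentence$end) {
    stop_ade("ade_consistency_error",
             "entity outside sentence span in extract_input_span")
  }
  s <- min(drug$start, ade$start)
  e <- max(drug$end, ade$end)
  list(
    span = slice0(sentence$text, s - sentence$start, e - sentence$start),
    degenerate = drug$start < ade$end && ade$start < drug$end,
    start = s, end = e
  )
}

# Internal fast path working on the sentence text directly.
input_span_text <- function(sentence_text, sent_start, drug, ade) {
  s <- min(drug$start, ade$start) - sent_start
  e <- max(drug$end, ade$end) - sent_start
  slice0(sentence_text, s, e)
}

make_dedup_key <- function(drug_surface, input_span, ade_surface, sentence_text) {
  tolower(paste(str_squish(drug_surface), str_squish(input_span),
                str_squish(ade_surface), str_squish(sentence_text),
                sep = "\x1f"))
}

#' Enumerate drug-ADE candidate pairs within one sentence
#'
#' Emits the full cross product of drug mentions and ADE mentions in the
#' sentence: a sentence with drugs {d1, d2} and ADEs {a1, a2} yields the
#' four combinations (d1,a1), (d1,a2), (d2,a1), (d2,a2). A candidate is
#' labeled `"positive"` iff `gold` contains a `DRUG_ADE` relation whose
#' arguments are exactly that (drug entity, ADE entity) pair; all other
#' combinations are derived negatives. Order is deterministic: drug start,
#' then ADE start.
#'
#' @param sentence One-row data frame from [segment_sentences()].
#' @param entities Entity data frame restricted to this sentence
#'   (document-level offsets).
#' @param gold Relation data frame (`type`, `arg1`, `arg2`); only `DRUG_ADE`
#'   rows are consulted.
#' @param doc_id Document identifier stamped on the candidates.
#' @return Candidate data frame (one row per pair); zero rows when the
#'   sentence lacks a drug or an ADE.
#' @export
enumerate_pairs <- function(sentence, entities, gold = empty_relations(),
                            doc_id = sentence$doc_id) {
  drugs <- entities[entities$label == "DRUG", , drop = FALSE]
  ades <- entities[entities$label == "ADE", , drop = FALSE]
  if (!nrow(drugs) || !nrow(ades)) return(empty_candidates())
  if (nrow(drugs) > 10L || nrow(ades) > 10L) {
    warning(sprintf("sentence %s:%d has %d drugs x %d ADEs; combinatorial blow-up",
                    doc_id, sentence$sent_index, nrow(drugs), nrow(ades)))
  }
  drugs <- drugs[order(drugs$start, drugs$end), , drop = FALSE]
  ades <- ades[order(ades$start, ades$end), , drop = FALSE]
  pos_keys <- character()
  if (nrow(gold)) {
    g <- gold[gold$type == "DRUG_ADE", , drop = FALSE]
    pos_keys <- paste(g$arg1, g$arg2, sep = "\x1f")
  }
  rows <- vector("list", nrow(drugs) * nrow(ades))
  k <- 0L
  for (i in seq_len(nrow(drugs))) {
    for (j in seq_len(nrow(ades))) {
      d <- drugs[i, ]; a <- ades[j, ]
      span <- input_span_text(sentence$text, sentence$start, d, a)
      degenerate <- d$start < a$end && a$start < d$end
      label <- if (paste(d$id, a$id, sep = "\x1f") %in% pos_keys)
        "positive" else "negative"
      k <- k + 1L
      rows[[k]] <- data.frame(
        candidate_id = sprintf("%s:%d:%s:%s", doc_id, sentence$sent_index,
                               d$id, a$id),
        doc_id = doc_id, sent_index = sentence$sent_index,
        drug_id = d$id, drug_surface = d$surface,
        drug_start = d$start, drug_end = d$end,
        ade_id = a$id, ade_surface = a$surface,
        ade_start = a$start, ade_end = a$end,
        label = label, input_span = span,
        sentence_text = sentence$text, degenerate = degenerate,
        dedup_key = make_dedup_key(d$surface, span, a$surface, sentence$text),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build a relation dataset from an annotated corpus
#'
#' Runs sentence segmentation on every document, assigns gold entities to
#' sentences, and enumerates candidates sentence by sentence. Entities
#' spanning a sentence boundary (and hence any gold relation whose two
#' arguments sit in different sentences) contribute nothing: the dataset is
#' strictly single-sentence.
#'
#' @param corpus An `ade_corpus` with gold annotations.
#' @param protected_patterns Passed to [segment_sentences()].
#' @param deduplicate Apply [deduplicate_candidates()] before returning
#'   (default `TRUE`).
#' @return A `relation_dataset`: candidate data frame with attributes
#'   `source_corpus` and `counts` (`n_positive`, `n_negative`).
#' @export
build_relation_dataset <- function(corpus,
                                   protected_patterns = default_protected_patterns(),
                                   deduplicate = TRUE) {
  per_doc <- lapply(corpus$documents, function(doc) {
    sents <- segment_sentences(doc$text, protected_patterns, doc_id = doc$doc_id)
    if (!nrow(sents) || !nrow(doc$entities)) return(empty_candidates())
    ents <- doc$entities
    # a sentence contains an entity iff the entity lies wholly inside it
    sent_of <- rep(NA_integer_, nrow(ents))
    for (si in seq_len(nrow(sents))) {
      inside <- ents$start >= sents$start[si] & ents$end <= sents$end[si]
      sent_of[inside] <- si
    }
    out <- lapply(seq_len(nrow(sents)), function(si) {
      idx <- which(sent_of == si)
      if (!length(idx)) return(empty_candidates())
      enumerate_pairs(sents[si, ], ents[idx, , drop = FALSE], doc$relations,
                      doc_id = doc$doc_id)
    })
    do.call(rbind, out)
  })
  cands <- do.call(rbind, c(per_doc, list(make.row.names = FALSE)))
  cands <- as.data.frame(cands, stringsAsFactors = FALSE)
  rownames(cands) <- NULL
  doc_split <- attr(corpus, "doc_split")
  if (!is.null(doc_split) && nrow(cands)) {
    cands$split <- unname(doc_split[cands$doc_id])
  }
  ds <- new_relation_dataset(cands, source_corpus = corpus$corpus_id)
  if (deduplicate) ds <- deduplicate_candidates(ds)
  ds
}

new_relation_dataset <- function(candidates, source_corpus = "") {
  counts <- c(n_positive = sum(candidates$label == "positive"),
              n_negative = sum(candidates$label == "negative"))
  structure(candidates, class = c("relation_dataset", "data.frame"),
            source_corpus = source_corpus, counts = counts)
}

#' @export
print.relation_dataset <- function(x, ...) {
  cnt <- attr(x, "counts")
  cat(sprintf("<relation_dataset '%s'> %d candidates (%d positive, %d negative)\n",
              attr(x, "source_corpus"), nrow(x), cnt["n_positive"],
              cnt["n_negative"]))
  invisible(x)
}

#' Remove duplicate candidates
#'
#' Due to boilerplate repetition across notes, the same relation instance
#' can recur verbatim. The duplicate key is the case-folded,
#' whitespace-collapsed concatenation of (drug surface, input span, ADE
#' surface, containing-sentence text); exactly one candidate per key is
#' retained (the first in the dataset's deterministic order). Idempotent.
#' Two candidates with the same key but different labels indicate
#' inconsistent gold annotation and raise a conflict error naming both.
#'
#' @param dataset A `relation_dataset`.
#' @return The deduplicated `relation_dataset`.
#' @export
deduplicate_candidates <- function(dataset) {
  if (!nrow(dataset)) return(dataset)
  split_lab <- tapply(dataset$label, dataset$dedup_key,
                      function(l) length(unique(l)))
  if (any(split_lab > 1L)) {
    key <- names(split_lab)[split_lab > 1L][1]
    ids <- dataset$candidate_id[dataset$dedup_key == key]
    stop_ade("ade_conflict_error",
             "candidates %s share a dedup key but disagree on label",
             paste(ids, collapse = ", "))
  }
  keep <- !duplicated(dataset$dedup_key)
  new_relation_dataset(as.data.frame(dataset)[keep, , drop = FALSE],
                       source_corpus = attr(dataset, "source_corpus"))
}

#' Write / read a relation dataset as TSV + JSON manifest
#'
#' @param dataset A `relation_dataset`.
#' @param path Output TSV path; a JSON manifest with the counts is written
#'   next to it as `<path>.json`.
#' @return Invisibly, `path`.
#' @export
write_relation_dataset <- function(dataset, path) {
  utils::write.table(as.data.frame(dataset), path, sep = "\t", quote = TRUE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  cnt <- attr(dataset, "counts")
  jsonlite::write_json(
    list(source_corpus = attr(dataset, "source_corpus"),
         n_candidates = nrow(dataset),
         n_positive = unname(cnt["n_positive"]),
         n_negative = unname(cnt["n_negative"])),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_relation_dataset
#' @param source_corpus Corpus id to record when reading.
#' @export
read_relation_dataset <- function(path, source_corpus = "") {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "\"",
                          stringsAsFactors = FALSE, comment.char = "",
                          fileEncoding = "UTF-8")
  new_relation_dataset(df, source_corpus = source_corpus)
}
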