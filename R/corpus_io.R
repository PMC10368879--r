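# Reading/writing clinical-note corpora in BRAT standoff format.
#
# A corpus is a set of paired files: <doc>.txt holds the note text and
# <doc>.ann holds entity lines ("T1\tLABEL start end\tsurface") and relation
# lines ("R1\tTYPE Arg1:Ti Arg2:Tj"). Offsets are 0-based half-open
# character offsets into the .txt content.

ENTITY_LABELS <- c("DRUG", "ADE", "DRUG_DATE", "ADE_DATE", "CAUSAL_TERM",
                   "GRADE", "DATE")
RELATION_TYPES <- c("DRUG_ADE", "DRUG_DATE_LINK", "ADE_DATE_LINK",
                    "CAUSAL_LINK", "GRADE_LINK")

#' Construct a clinical-note document
#'
#' Bundles one note's text with its entity and relation annotations and the
#' longitudinal metadata (patient, date, within-patient order) used to keep
#' notes in chronological order.
#'
#' @param doc_id Document identifier.
#' @param text Note text (single string).
#' @param entities Data frame with columns `id`, `label`, `start`, `end`,
#'   `surface`, `fragmented` (0-based half-open offsets).
#' @param relations Data frame with columns `id`, `type`, `arg1`, `arg2`.
#' @param patient_id Patient identifier (optional).
#' @param note_date Note date, `Date` or "YYYYMMDD"/"YYYY-MM-DD" string.
#' @param order_index Non-negative integer giving the note's position in the
#'   patient's timeline.
#' @return An object of class `ade_document`.
#' @export
ade_document <- function(doc_id, text, entities = empty_entities(),
                         relations = empty_relations(), patient_id = NA_character_,
                         note_date = NA, order_index = 0L) {
  entities <- as.data.frame(entities, stringsAsFactors = FALSE)
  relations <- as.data.frame(relations, stringsAsFactors = FALSE)
  doc <- structure(
    list(
      doc_id = as.character(doc_id), patient_id = as.character(patient_id),
      note_date = note_date, order_index = as.integer(order_index),
      text = as.character(text), entities = entities, relations = relations
    ),
    class = "ade_document"
  )
  validate_document(doc)
  doc
}

validate_document <- function(doc) {
  ents <- doc$entities
  n <- nchar(doc$text)
  if (nrow(ents)) {
    if (anyDuplicated(ents$id)) {
      stop_ade("ade_consistency_error", "duplicate entity ids in document '%s'",
               doc$doc_id)
    }
    bad <- ents$start < 0L | ents$end > n | ents$start >= ents$end
    if (any(bad)) {
      stop_ade("ade_consistency_error",
               "entity '%s' has offsets [%d,%d) outside text of length %d in document '%s'",
               ents$id[which(bad)[1]], ents$start[which(bad)[1]],
               ents$end[which(bad)[1]], n, doc$doc_id)
    }
    contig <- !ents$fragmented
    mism <- contig & ents$surface != slice0(doc$text, ents$start, ents$end)
    if (any(mism)) {
      i <- which(mism)[1]
      stop_ade("ade_consistency_error",
               "entity '%s' surface %s does not match text slice %s in document '%s'",
               ents$id[i], dQuote(ents$surface[i]),
               dQuote(slice0(doc$text, ents$start[i], ents$end[i])), doc$doc_id)
    }
  }
  rels <- doc$relations
  if (nrow(rels)) {
    known <- c(rels$arg1, rels$arg2) %in% ents$id
    if (!all(known)) {
      missing_id <- c(rels$arg1, rels$arg2)[!known][1]
      stop_ade("ade_dangling_reference_error",
               "relation argument '%s' does not resolve to an entity in document '%s'",
               missing_id, doc$doc_id)
    }
  }
  invisible(doc)
}

#' @export
print.ade_document <- function(x, ...) {
  cat(sprintf("<ade_document '%s'> patient=%s date=%s | %d chars, %d entities, %d relations\n",
              x$doc_id, x$patient_id, as.character(x$note_date),
              nchar(x$text), nrow(x$entities), nrow(x$relations)))
  invisible(x)
}

#' Parse a BRAT standoff annotation pair
#'
#' Reads one note given as in-memory strings: the note text and the content
#' of its `.ann` file. Entity (`T`) and relation (`R`) lines are parsed;
#' event/attribute/note lines (`E`/`A`/`M`/`#`) are tolerated and ignored.
#' Discontinuous spans ("start end;start end") are collapsed to their
#' enclosing envelope and flagged `fragmented`.
#'
#' @param text_content Note text.
#' @param ann_content Content of the `.ann` file ("" for an unannotated note).
#' @param doc_id Document identifier.
#' @param patient_id,note_date,order_index Longitudinal metadata, see
#'   [ade_document()].
#' @return An `ade_document`.
#' @export
read_brat <- function(text_content, ann_content, doc_id = "doc",
                      patient_id = NA_character_, note_date = NA,
                      order_index = 0L) {
  lines <- if (identical(ann_content, "")) character() else
    strsplit(ann_content, "\n", fixed = TRUE)[[1]]
  lines_keep <- which(nzchar(lines))

  ents <- list(); rels <- list()
  for (i in lines_keep) {
    line <- lines[i]
    first <- substr(line, 1, 1)
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (first == "T") {
      if (length(fields) < 3) {
        stop_ade("ade_parse_error", "malformed entity line %d: %s", i, dQuote(line))
      }
      head <- strsplit(fields[2], " ", fixed = TRUE)[[1]]
      label <- head[1]
      span_str <- paste(head[-1], collapse = " ")
      frags <- strsplit(span_str, ";", fixed = TRUE)[[1]]
      offs <- suppressWarnings(lapply(strsplit(trimws(frags), " "), as.integer))
      if (!length(offs) || any(vapply(offs, function(o)
        length(o) != 2 || anyNA(o), TRUE))) {
        stop_ade("ade_parse_error", "malformed entity offsets on line %d: %s",
                 i, dQuote(line))
      }
      starts <- vapply(offs, `[`, 0L, 1L); ends <- vapply(offs, `[`, 0L, 2L)
      ents[[length(ents) + 1L]] <- data.frame(
        id = fields[1], label = toupper(label),
        start = min(starts), end = max(ends),
        surface = fields[3], fragmented = length(offs) > 1L,
        stringsAsFactors = FALSE
      )
    } else if (first == "R") {
      if (length(fields) < 2) {
        stop_ade("ade_parse_error", "malformed relation line %d: %s", i, dQuote(line))
      }
      head <- strsplit(fields[2], " ", fixed = TRUE)[[1]]
      a1 <- head[startsWith(head, "Arg1:")]
      a2 <- head[startsWith(head, "Arg2:")]
      if (length(head) < 3 || !length(a1) || !length(a2)) {
        stop_ade("ade_parse_error", "malformed relation line %d: %s", i, dQuote(line))
      }
      rels[[length(rels) + 1L]] <- data.frame(
        id = fields[1], type = toupper(head[1]),
        arg1 = sub("^Arg1:", "", a1[1]), arg2 = sub("^Arg2:", "", a2[1]),
        stringsAsFactors = FALSE
      )
    } # other line types ignored
  }
  entities <- if (length(ents)) do.call(rbind, ents) else empty_entities()
  relations <- if (length(rels)) do.call(rbind, rels) else empty_relations()
  ade_document(doc_id, text_content, entities, relations,
               patient_id = patient_id, note_date = note_date,
               order_index = order_index)
}

#' Serialize a document to BRAT standoff format
#'
#' Inverse of [read_brat()]: entity lines are emitted sorted by start offset
#' (ties by end, then id), so `read_brat(write_brat(doc))` reproduces `doc`
#' up to entity row order. Fragmented (envelope) entities are written as
#' their contiguous envelope span.
#'
#' @param doc An `ade_document`.
#' @return List with elements `text_content` and `ann_content`.
#' @export
write_brat <- function(doc) {
  validate_document(doc)
  ents <- doc$entities
  ann <- character()
  if (nrow(ents)) {
    ord <- order(ents$start, ents$end, ents$id)
    ents <- ents[ord, , drop = FALSE]
    ann <- sprintf("%s\t%s %d %d\t%s", ents$id, ents$label, ents$start,
                   ents$end, ents$surface)
  }
  rels <- doc$relations
  if (nrow(rels)) {
    ann <- c(ann, sprintf("%s\t%s Arg1:%s Arg2:%s", rels$id, rels$type,
                          rels$arg1, rels$arg2))
  }
  list(
    text_content = doc$text,
    ann_content = if (length(ann)) paste0(paste(ann, collapse = "\n"), "\n") else ""
  )
}

#' Construct a corpus
#'
#' @param corpus_id Corpus identifier.
#' @param documents List of `ade_document`s; must have unique `doc_id`s.
#' @param provenance Free-text provenance note.
#' @return An object of class `ade_corpus`.
#' @export
ade_corpus <- function(corpus_id, documents, provenance = "") {
  ids <- vapply(documents, `[[`, "", "doc_id")
  if (anyDuplicated(ids)) {
    stop_ade("ade_consistency_error", "duplicate doc_ids in corpus '%s'", corpus_id)
  }
  names(documents) <- ids
  structure(list(corpus_id = as.character(corpus_id), documents = documents,
                 provenance = provenance),
            class = "ade_corpus")
}

#' @export
print.ade_corpus <- function(x, ...) {
  cat(sprintf("<ade_corpus '%s'> %d documents\n", x$corpus_id,
              length(x$documents)))
  invisible(x)
}

#' @export
length.ade_corpus <- function(x) length(x$documents)

# Filename convention carrying longitudinal metadata:
#   <patientid>_<YYYYMMDD>_<seq>.txt
parse_doc_filename <- function(stem) {
  m <- regmatches(stem, regexec("^(.+)_([0-9]{8})_([0-9]+)$", stem))[[1]]
  if (length(m) == 4) {
    list(patient_id = m[2],
         note_date = as.Date(m[3], format = "%Y%m%d"),
         order_index = as.integer(m[4]))
  } else {
    list(patient_id = stem, note_date = as.Date(NA), order_index = 0L)
  }
}

#' Load a BRAT corpus from a directory
#'
#' Reads every paired `<stem>.txt` / `<stem>.ann` file in `directory`.
#' Patient id, note date and order index are parsed from the filename
#' convention `<patientid>_<YYYYMMDD>_<seq>.txt`; stems not matching it get
#' the stem as patient id. Documents are ordered by (patient_id, note_date,
#' order_index, doc_id). Unpaired files are skipped with a warning and listed
#' in the load report (`attr(corpus, "load_report")`).
#'
#' @param directory Path containing the `.txt`/`.ann` pairs.
#' @param corpus_id Identifier for the resulting corpus.
#' @return An `ade_corpus` with a `load_report` attribute
#'   (`list(n_loaded, skipped)`).
#' @export
load_corpus <- function(directory, corpus_id = basename(directory)) {
  txts <- sort(list.files(directory, pattern = "\\.txt$"))
  anns <- sort(list.files(directory, pattern = "\\.ann$"))
  stems_txt <- sub("\\.txt$", "", txts)
  stems_ann <- sub("\\.ann$", "", anns)
  paired <- intersect(stems_txt, stems_ann)
  skipped <- c(paste0(setdiff(stems_txt, paired), ".txt", recycle0 = TRUE),
               paste0(setdiff(stems_ann, paired), ".ann", recycle0 = TRUE))
  if (length(skipped)) {
    warning(sprintf("skipping %d unpaired file(s): %s", length(skipped),
                    paste(skipped, collapse = ", ")))
  }
  docs <- lapply(paired, function(stem) {
    meta <- parse_doc_filename(stem)
    read_brat(
      text_content = readChar(file.path(directory, paste0(stem, ".txt")),
                              file.info(file.path(directory, paste0(stem, ".txt")))$size,
                              useBytes = FALSE),
      ann_content = paste0(readLines(file.path(directory, paste0(stem, ".ann")),
                                     warn = FALSE), collapse = "\n"),
      doc_id = stem, patient_id = meta$patient_id,
      note_date = meta$note_date, order_index = meta$order_index
    )
  })
  ord <- order(vapply(docs, `[[`, "", "patient_id"),
               vapply(docs, function(d) as.character(d$note_date), ""),
               vapply(docs, `[[`, 0L, "order_index"),
               vapply(docs, `[[`, "", "doc_id"))
  corpus <- ade_corpus(corpus_id, docs[ord])
  attr(corpus, "load_report") <- list(n_loaded = length(docs), skipped = skipped)
  corpus
}

#' Write a corpus as BRAT `.txt`/`.ann` pairs
#'
#' @param corpus An `ade_corpus`.
#' @param directory Output directory (created if needed). File stems are the
#'   document ids.
#' @return Invisibly, the vector of stems written.
#' @export
write_corpus <- function(corpus, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  stems <- vapply(corpus$documents, `[[`, "", "doc_id")
  for (doc in corpus$documents) {
    out <- write_brat(doc)
    writeLines(out$text_content, file.path(directory, paste0(doc$doc_id, ".txt")),
               sep = "")
    writeLines(out$ann_content, file.path(directory, paste0(doc$doc_id, ".ann")),
               sep = "")
  }
  invisible(unname(stems))
}
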