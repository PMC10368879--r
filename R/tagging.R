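# Dictionary tagging of drug/ADE/causal-term mentions and rule-based date
# tagging. Exact matching only: no stemming, no fuzzy matching — misspelled
# mentions are left to human annotators.

#' Construct a tagging lexicon
#'
#' A lexicon maps each canonical term of one category to its set of surface
#' variants (generic + brand names for drugs; clinical synonyms for ADEs).
#' Variant sets within a category must be pairwise disjoint after case
#' folding.
#'
#' @param category One of `"DRUG"`, `"ADE"`, `"CAUSAL_TERM"`.
#' @param entries Named list: canonical term -> character vector of variants.
#' @return An object of class `ade_lexicon`.
#' @export
ade_lexicon <- function(category, entries) {
  category <- match.arg(toupper(category), c("DRUG", "ADE", "CAUSAL_TERM"))
  if (!length(entries) || is.null(names(entries))) {
    stop_ade("ade_config_error", "lexicon entries must be a non-empty named list")
  }
  entries <- lapply(entries, function(v) unique(as.character(v)))
  if (any(!vapply(entries, length, 0L))) {
    stop_ade("ade_config_error", "every canonical term needs at least one variant")
  }
  folded <- tolower(unlist(entries, use.names = FALSE))
  if (anyDuplicated(folded)) {
    stop_ade("ade_config_error",
             "variant '%s' appears under more than one canonical term",
             folded[duplicated(folded)][1])
  }
  structure(list(category = category, entries = entries), class = "ade_lexicon")
}

#' Read a lexicon file
#'
#' File format: one line per canonical term,
#' `canonical<TAB>variant1|variant2|...`.
#'
#' @param path File path.
#' @param category Lexicon category, see [ade_lexicon()].
#' @return An `ade_lexicon`.
#' @export
read_lexicon <- function(path, category) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) != 2L)
  if (length(bad)) {
    stop_ade("ade_parse_error", "malformed lexicon line %d in %s", bad[1], path)
  }
  entries <- lapply(parts, function(p) strsplit(p[2], "|", fixed = TRUE)[[1]])
  names(entries) <- vapply(parts, `[`, "", 1L)
  ade_lexicon(category, entries)
}

#' Packaged default lexicons
#'
#' The shipped drug lexicon covers the eight immune checkpoint inhibitors
#' (generic + brand names); the ADE lexicon covers the eight
#' immunotherapy-toxicity groups (colitis, pneumonitis, thyroid
#' abnormalities, rash, hepatitis, myalgia, arthralgia, cardiotoxicity); the
#' causal-term lexicon lists common causal cue phrases.
#'
#' @param category `"DRUG"`, `"ADE"`, or `"CAUSAL_TERM"`.
#' @return An `ade_lexicon`.
#' @export
default_lexicon <- function(category = c("DRUG", "ADE", "CAUSAL_TERM")) {
  category <- match.arg(category)
  file <- switch(category, DRUG = "lexicon_drug.tsv", ADE = "lexicon_ade.tsv",
                 CAUSAL_TERM = "lexicon_causal.tsv")
  read_lexicon(system.file("extdata", file, package = "aderelex",
                           mustWork = TRUE), category)
}

regex_escape <- function(x) gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", x)

# All (start, length, canonical) matches of the lexicon in `text`,
# case-insensitive on word boundaries. 1-based starts.
lexicon_matches <- function(text, lexicon) {
  out <- list()
  for (canon in names(lexicon$entries)) {
    for (variant in lexicon$entries[[canon]]) {
      pat <- paste0("(?<![[:alnum:]])", regex_escape(variant), "(?![[:alnum:]])")
      m <- gregexpr(pat, text, ignore.case = TRUE, perl = TRUE)[[1]]
      if (m[1] == -1) next
      out[[length(out) + 1L]] <- data.frame(
        start = as.integer(m), len = attr(m, "match.length"),
        canonical = canon, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), len = integer(),
                      canonical = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Greedy longest-match-wins selection of non-overlapping matches.
# Ties between equal-length overlapping matches go to the leftmost start.
select_longest <- function(matches) {
  if (!nrow(matches)) return(matches)
  ord <- order(-matches$len, matches$start)
  matches <- matches[ord, , drop = FALSE]
  taken_start <- integer(); taken_end <- integer()
  keep <- logical(nrow(matches))
  for (i in seq_len(nrow(matches))) {
    s <- matches$start[i]; e <- matches$start[i] + matches$len[i] - 1L
    if (!any(s <= taken_end & e >= taken_start)) {
      keep[i] <- TRUE
      taken_start <- c(taken_start, s); taken_end <- c(taken_end, e)
    }
  }
  matches <- matches[keep, , drop = FALSE]
  matches[order(matches$start), , drop = FALSE]
}

#' Tag lexicon mentions in segmented sentences
#'
#' Case-insensitive, word-boundary, longest-match-wins exact matching of
#' every lexicon variant against each sentence. Overlapping shorter matches
#' are suppressed; equal-length ties are broken leftmost. Offsets in the
#' returned entities are document-level (the sentence offsets plus the
#' in-sentence match position).
#'
#' @param sentences Data frame from [segment_sentences()].
#' @param lexicon An [ade_lexicon()].
#' @param id_prefix Prefix for generated entity ids (default `"T"`).
#' @param id_start First id number to use.
#' @return Entity data frame (`id`, `label`, `start`, `end`, `surface`,
#'   `fragmented`, plus `canonical` and `doc_id`).
#' @export
tag_lexicon <- function(sentences, lexicon, id_prefix = "T", id_start = 1L) {
  rows <- list()
  for (i in seq_len(nrow(sentences))) {
    m <- select_longest(lexicon_matches(sentences$text[i], lexicon))
    if (!nrow(m)) next
    s0 <- sentences$start[i] + m$start - 1L      # 0-based doc-level
    rows[[length(rows) + 1L]] <- data.frame(
      label = lexicon$category, start = s0, end = s0 + m$len,
      surface = substring(sentences$text[i], m$start, m$start + m$len - 1L),
      fragmented = FALSE, canonical = m$canonical,
      doc_id = sentences$doc_id[i], stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    out <- cbind(empty_entities(),
                 data.frame(canonical = character(), doc_id = character()))
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start), , drop = FALSE]
  out <- cbind(id = paste0(id_prefix, seq_len(nrow(out)) + id_start - 1L), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[, c("id", "label", "start", "end", "surface", "fragmented",
          "canonical", "doc_id")]
}

date_patterns <- function() {
  month <- paste0("(?:Jan(?:uary)?|Feb(?:ruary)?|Mar(?:ch)?|Apr(?:il)?|May|",
                  "Jun(?:e)?|Jul(?:y)?|Aug(?:ust)?|Sep(?:t(?:ember)?)?|",
                  "Oct(?:ober)?|Nov(?:ember)?|Dec(?:ember)?)")
  c(
    # M/D/YYYY, M-D-YY etc.; guards block decimals and version strings
    # (a separator counts as continuation only when a digit follows it)
    "(?<!\\d)(?<!\\d[/.-])(?:0?[1-9]|1[0-2])[/-](?:0?[1-9]|[12][0-9]|3[01])[/-](?:\\d{4}|\\d{2})(?!\\d)(?![/.-]\\d)",
    # ISO YYYY-MM-DD
    "(?<!\\d)(?<!\\d[/.-])(?:19|20)\\d{2}-(?:0?[1-9]|1[0-2])-(?:0?[1-9]|[12][0-9]|3[01])(?!\\d)(?![/.-]\\d)",
    # Month-name dates: "January 5, 2017", "Jan 2017"
    paste0("\\b", month, "\\.?\\s+(?:\\d{1,2},?\\s+)?(?:19|20)\\d{2}\\b")
  )
}

#' Tag calendar dates
#'
#' Rule-based matching of numeric dates (`3/14/2017`, `3-14-17`,
#' `2017-03-14`) and month-name dates (`January 5, 2017`, `Jan 2017`).
#' Decimal numbers and dotted version strings are guarded against. Emits the
#' generic label `DATE`: distinguishing drug dates from ADE dates needs
#' relational context the tagger lacks and is left to annotation.
#'
#' @inheritParams tag_lexicon
#' @return Entity data frame as in [tag_lexicon()] (canonical = `"DATE"`).
#' @export
tag_dates <- function(sentences, id_prefix = "T", id_start = 1L) {
  rows <- list()
  for (i in seq_len(nrow(sentences))) {
    ms <- list()
    for (pat in date_patterns()) {
      m <- gregexpr(pat, sentences$text[i], perl = TRUE)[[1]]
      if (m[1] == -1) next
      ms[[length(ms) + 1L]] <- data.frame(
        start = as.integer(m), len = attr(m, "match.length"),
        canonical = "DATE", stringsAsFactors = FALSE
      )
    }
    if (!length(ms)) next
    m <- select_longest(do.call(rbind, ms))
    s0 <- sentences$start[i] + m$start - 1L
    rows[[length(rows) + 1L]] <- data.frame(
      label = "DATE", start = s0, end = s0 + m$len,
      surface = substring(sentences$text[i], m$start, m$start + m$len - 1L),
      fragmented = FALSE, canonical = "DATE",
      doc_id = sentences$doc_id[i], stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    return(cbind(empty_entities(),
                 data.frame(canonical = character(), doc_id = character())))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start), , drop = FALSE]
  out <- cbind(id = paste0(id_prefix, seq_len(nrow(out)) + id_start - 1L), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[, c("id", "label", "start", "end", "surface", "fragmented",
          "canonical", "doc_id")]
}
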