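# Text cleaning and rule-based sentence segmentation.
#
# Pipeline order matters: cleaning runs BEFORE tagging/annotation, so no
# gold-offset remapping across cleaning is ever needed. Segmentation offsets
# always refer to the text actually segmented.

#' Cleaning configuration
#'
#' @param variant_map Named character vector mapping surface variants to
#'   canonical terms (e.g. `c(opdivo = "nivolumab")`). Matching is
#'   case-insensitive on word boundaries.
#' @param abbreviation_map Named character vector mapping abbreviations to
#'   expansions, applied the same way.
#' @param collapse_whitespace Collapse runs of spaces/tabs and excess blank
#'   lines (default `TRUE`).
#' @return An object of class `cleaning_config`.
#' @export
cleaning_config <- function(variant_map = character(),
                            abbreviation_map = character(),
                            collapse_whitespace = TRUE) {
  check_map <- function(m, what) {
    if (length(m)) {
      if (is.null(names(m)) || any(!nzchar(names(m)))) {
        stop_ade("ade_config_error", "%s must be a named vector with non-empty keys", what)
      }
    }
  }
  check_map(variant_map, "variant_map")
  check_map(abbreviation_map, "abbreviation_map")
  structure(list(variant_map = variant_map, abbreviation_map = abbreviation_map,
                 collapse_whitespace = isTRUE(collapse_whitespace)),
            class = "cleaning_config")
}

apply_map <- function(text, map) {
  for (key in names(map)) {
    # word-boundary, case-insensitive; keys are plain phrases, not regexes
    pat <- paste0("(?<![[:alnum:]])", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", key),
                  "(?![[:alnum:]])")
    text <- gsub(pat, map[[key]], text, ignore.case = TRUE, perl = TRUE)
  }
  text
}

#' Clean raw note text
#'
#' Normalizes whitespace (runs of spaces/tabs to one space; three or more
#' consecutive newlines to two), replaces drug-name surface variants by
#' their canonical terms, and expands abbreviations. Idempotent: cleaning an
#' already-clean text is the identity, provided the map values are fixed
#' points of the maps (canonical terms map to themselves or are absent).
#'
#' @param raw Raw note text.
#' @param config A [cleaning_config()].
#' @return Cleaned text.
#' @export
clean_text <- function(raw, config = cleaning_config()) {
  if (!nzchar(raw)) return(raw)
  x <- raw
  if (config$collapse_whitespace) {
    x <- gsub("[ \t]+", " ", x)
    x <- gsub(" ?\n ?", "\n", x)      # strip spaces hugging line breaks
    x <- gsub("\n{3,}", "\n\n", x)
  }
  x <- apply_map(x, config$variant_map)
  x <- apply_map(x, config$abbreviation_map)
  x
}

# Default protected patterns: substrings whose periods must never split a
# sentence. Order is irrelevant (all matches are masked before splitting).
#' Default protected patterns for sentence segmentation
#'
#' Regular expressions matching period-bearing substrings that must not end
#' a sentence: honorifics ("Dr."), dosing abbreviations ("q.d.", "b.i.d."),
#' decimal numbers ("1.5"), numbered-list markers at line starts ("2."),
#' and common clinical abbreviations.
#' @return Character vector of PCRE patterns.
#' @export
default_protected_patterns <- function() {
  c(
    "\\b(?:Dr|Mr|Mrs|Ms|Prof|St|vs|etc|approx|Fig|No)\\.",
    "\\b(?:[a-zA-Z]\\.){2,}",              # q.d., b.i.d., t.i.d., p.r.n., i.v.
    "\\b\\d+\\.\\d+",                      # decimals: 1.5 mg
    "(?m)^\\s*\\d{1,2}\\.(?=\\s)",         # numbered list marker "3. "
    "\\b(?:mg|mcg|mL|cc)\\."
  )
}

#' Segment cleaned text into sentences
#'
#' Three-phase protect/split/restore segmentation: (1) every match of a
#' protected pattern is masked with a placeholder byte so its punctuation is
#' invisible to the splitter; (2) sentence boundaries are placed after
#' sentence-final punctuation (`.?!`, optionally followed by closing quotes
#' or brackets) that is followed by whitespace, and at blank lines — a lone
#' newline is NOT a boundary (clinical notes wrap lines), a blank line IS;
#' (3) offsets are reported against the original string, so concatenating
#' the sentence slices with the skipped inter-sentence separators
#' reconstructs the input exactly.
#'
#' @param doc_text Cleaned document text.
#' @param protected_patterns Character vector of PCRE patterns; defaults to
#'   [default_protected_patterns()].
#' @param doc_id Document id recorded on each sentence row.
#' @return Data frame with columns `doc_id`, `sent_index` (0-based),
#'   `start`, `end` (0-based half-open), `text`.
#' @export
segment_sentences <- function(doc_text, protected_patterns = default_protected_patterns(),
                              doc_id = "doc") {
  empty <- data.frame(doc_id = character(), sent_index = integer(),
                      start = integer(), end = integer(), text = character(),
                      stringsAsFactors = FALSE)
  if (!nzchar(doc_text)) return(empty)
  placeholder <- "\x01"
  if (grepl(placeholder, doc_text, fixed = TRUE)) {
    stop_ade("ade_internal_error",
             "document text contains the reserved placeholder byte \\x01")
  }
  # Phase 1: protect. Mask protected matches with same-length placeholder
  # runs; lengths are preserved so offsets in the masked copy equal offsets
  # in the original.
  masked <- doc_text
  for (pat in protected_patterns) {
    m <- gregexpr(pat, masked, perl = TRUE)[[1]]
    if (m[1] == -1) next
    lens <- attr(m, "match.length")
    for (k in seq_along(m)) {
      repl <- strrep(placeholder, lens[k])
      substr(masked, m[k], m[k] + lens[k] - 1L) <- repl
    }
  }
  stopifnot(nchar(masked) == nchar(doc_text))

  # Phase 2: split on the masked copy. Boundaries are character positions
  # (1-based, in masked == original coordinates) where a sentence ends.
  boundary_after <- integer()
  m <- gregexpr("[.?!]+[\"')\\]]*(?=[ \t\r\n])", masked, perl = TRUE)[[1]]
  if (m[1] != -1) {
    boundary_after <- m + attr(m, "match.length") - 1L
  }
  # blank lines always terminate the preceding sentence
  m2 <- gregexpr("\n[ \t]*\n", masked, perl = TRUE)[[1]]
  if (m2[1] != -1) {
    boundary_after <- c(boundary_after, m2 - 1L)
  }
  boundary_after <- sort(unique(c(boundary_after[boundary_after > 0],
                                  nchar(doc_text))))

  # Phase 3: restore = slice the ORIGINAL text; trim separator whitespace
  # into the inter-sentence gaps.
  sents <- list()
  cursor <- 1L  # 1-based position of the next unconsumed character
  for (b in boundary_after) {
    seg <- substring(doc_text, cursor, b)
    # shrink to non-whitespace core
    lead <- regmatches(seg, regexpr("^[ \t\r\n]*", seg))
    trail <- regmatches(seg, regexpr("[ \t\r\n]*$", seg))
    s1 <- cursor + nchar(lead)
    e1 <- b - nchar(trail)
    if (e1 >= s1) {
      sents[[length(sents) + 1L]] <- c(s1, e1)
    }
    cursor <- b + 1L
  }
  if (!length(sents)) return(empty)
  starts <- vapply(sents, `[`, 0, 1) - 1L   # to 0-based
  ends <- vapply(sents, `[`, 0, 2)          # half-open end
  data.frame(
    doc_id = doc_id, sent_index = seq_along(starts) - 1L,
    start = as.integer(starts), end = as.integer(ends),
    text = slice0(doc_text, starts, ends),
    stringsAsFactors = FALSE
  )
}

#' Check the sentence reconstruction property
#'
#' Verifies that sentence spans are sorted, non-overlapping, each equals its
#' text slice, and that the characters between/around them are pure
#' whitespace — i.e. the spans partition the non-separator text.
#'
#' @param doc_text The segmented text.
#' @param sentences Result of [segment_sentences()].
#' @return `TRUE` (invisibly) or an error describing the violation.
#' @export
check_segmentation <- function(doc_text, sentences) {
  if (!nrow(sentences)) {
    if (grepl("[^ \t\r\n]", doc_text)) {
      stop_ade("ade_consistency_error", "non-whitespace text but zero sentences")
    }
    return(invisible(TRUE))
  }
  if (is.unsorted(sentences$start, strictly = TRUE)) {
    stop_ade("ade_consistency_error", "sentence starts not strictly increasing")
  }
  if (any(sentences$start[-1] < sentences$end[-nrow(sentences)])) {
    stop_ade("ade_consistency_error", "overlapping sentences")
  }
  if (!all(sentences$text == slice0(doc_text, sentences$start, sentences$end))) {
    stop_ade("ade_consistency_error", "sentence text does not equal its slice")
  }
  gaps <- character()
  prev_end <- 0L
  for (i in seq_len(nrow(sentences))) {
    gaps <- c(gaps, slice0(doc_text, prev_end, sentences$start[i]))
    prev_end <- sentences$end[i]
  }
  gaps <- c(gaps, slice0(doc_text, prev_end, nchar(doc_text)))
  if (any(grepl("[^ \t\r\n]", gaps))) {
    stop_ade("ade_consistency_error", "non-whitespace characters between sentences")
  }
  invisible(TRUE)
}
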