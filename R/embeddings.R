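# Tokenization and word-embedding tables.

#' Tokenize text for the token-level models
#'
#' Lowercases and splits on whitespace and punctuation; hyphenated compounds
#' split into their parts ("nivolumab-induced" -> "nivolumab", "induced").
#' Digits are kept as tokens.
#'
#' @param text Character scalar.
#' @return Character vector of tokens (possibly empty).
#' @export
tokenize_text <- function(text) {
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

#' Load a pretrained embedding table
#'
#' Reads the whitespace-delimited text format `token v1 v2 ... vD`, one
#' token per line, all lines the same dimension.
#'
#' @param path File path.
#' @param oov_policy Out-of-vocabulary lookup policy: `"zero"` (zero vector)
#'   or `"random"` (seeded standard-normal draw, cached per token).
#' @param case_fold Lowercase tokens at load and lookup time (default `TRUE`).
#' @param seed Seed for the `"random"` OOV policy.
#' @return An `embedding_table`.
#' @export
load_embeddings <- function(path, oov_policy = c("zero", "random"),
                            case_fold = TRUE, seed = 1L) {
  oov_policy <- match.arg(oov_policy)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[ \t]+")
  dims <- vapply(parts, length, 0L) - 1L
  if (!length(dims)) {
    stop_ade("ade_format_error", "embedding file %s is empty", path)
  }
  if (length(unique(dims)) != 1L) {
    bad <- which(dims != dims[1])[1]
    stop_ade("ade_format_error",
             "ragged embedding dimensions: line %d has %d values, expected %d",
             bad, dims[bad], dims[1])
  }
  tokens <- vapply(parts, `[`, "", 1L)
  if (case_fold) tokens <- tolower(tokens)
  vecs <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1])))
  if (anyNA(vecs)) {
    stop_ade("ade_format_error", "non-numeric embedding value in %s", path)
  }
  rownames(vecs) <- tokens
  embedding_table(vecs, oov_policy = oov_policy, case_fold = case_fold,
                  seed = seed)
}

#' Construct an embedding table from a matrix
#'
#' @param matrix Numeric matrix with token rownames.
#' @inheritParams load_embeddings
#' @return An `embedding_table`.
#' @export
embedding_table <- function(matrix, oov_policy = "zero", case_fold = TRUE,
                            seed = 1L) {
  structure(list(vectors = matrix, dim = ncol(matrix),
                 oov_policy = oov_policy, case_fold = case_fold,
                 seed = as.integer(seed),
                 oov_cache = new.env(parent = emptyenv())),
            class = "embedding_table")
}

#' Look up token vectors
#'
#' @param table An `embedding_table`.
#' @param tokens Character vector.
#' @return Numeric matrix, one row per token.
#' @export
lookup_embeddings <- function(table, tokens) {
  if (table$case_fold) tokens <- tolower(tokens)
  out <- matrix(0, nrow = length(tokens), ncol = table$dim)
  known <- tokens %in% rownames(table$vectors)
  if (any(known)) out[known, ] <- table$vectors[tokens[known], , drop = FALSE]
  if (any(!known) && table$oov_policy == "random") {
    for (idx in which(!known)) {
      tok <- tokens[idx]
      v <- table$oov_cache[[tok]]
      if (is.null(v)) {
        # token-specific deterministic draw, independent of lookup order
        v <- with_seed(table$seed + sum(utf8ToInt(tok)) %% 1000003L,
                       stats::rnorm(table$dim))
        table$oov_cache[[tok]] <- v
      }
      out[idx, ] <- v
    }
  }
  out
}
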