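# Internal helpers shared across modules.

# All annotation offsets in this package are 0-based, half-open [start, end),
# the BRAT standoff convention. These helpers are the only place the 1-based
# R indexing conversion happens.
slice0 <- function(text, start, end) {
  substring(text, start + 1L, end)
}

# Collapse internal whitespace runs to single spaces and trim.
str_squish <- function(x) {
  x <- gsub("[ \t\r\n]+", " ", x)
  sub("^ ", "", sub(" $", "", x))
}

# Deterministic RNG scoping: run `expr` under `seed` and restore the caller's
# RNG state afterwards so library code never perturbs user randomness.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stop_ade <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "aderelex_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_entities <- function() {
  data.frame(
    id = character(), label = character(),
    start = integer(), end = integer(),
    surface = character(), fragmented = logical(),
    stringsAsFactors = FALSE
  )
}

empty_relations <- function() {
  data.frame(
    id = character(), type = character(),
    arg1 = character(), arg2 = character(),
    stringsAsFactors = FALSE
  )
}
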