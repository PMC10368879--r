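# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# small general-purpose corpus (noisy, mixed signal)
small_gen <- function() {
  fixture("small", function() {
    generate_corpus(synth_config(
      n_patients = 30, notes_per_patient = c(4, 6),
      p_positive_sentence = 0.35, signal_strength = 0.9,
      p_boilerplate_repeat = 0.15, seed = 101
    ))
  })
}

# perfect-signal corpus large enough for model training
signal_gen <- function() {
  fixture("signal", function() {
    generate_corpus(synth_config(
      n_patients = 16, notes_per_patient = c(4, 6),
      p_positive_sentence = 0.4, signal_strength = 1.0,
      p_cross_sentence_relation = 0, seed = 202
    ))
  })
}

small_dataset <- function() {
  fixture("small_ds", function() build_relation_dataset(small_gen()$corpus))
}

signal_dataset <- function() {
  fixture("signal_ds", function() build_relation_dataset(signal_gen()$corpus))
}

# deterministic 70/30 split of a dataset into train/test pieces
split_dataset <- function(ds, seed = 1L, p = 0.3) {
  sp <- stratified_holdout(ds$label, p, seed = seed)
  df <- as.data.frame(ds)
  list(train = aderelex:::new_relation_dataset(df[sp$train, , drop = FALSE],
                                               attr(ds, "source_corpus")),
       test = aderelex:::new_relation_dataset(df[sp$holdout, , drop = FALSE],
                                              attr(ds, "source_corpus")))
}

f1_of <- function(pred, gold_df) {
  aderelex:::f1_binary(pred$y[match(gold_df$candidate_id, pred$candidate_id)],
                       as.integer(gold_df$label == "positive"))
}

# independent brute-force candidate enumeration oracle (double loop over
# entity rows, no shared code with enumerate_pairs)
brute_force_pairs <- function(sentence, entities, gold) {
  drugs <- entities[entities$label == "DRUG", , drop = FALSE]
  ades <- entities[entities$label == "ADE", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(drugs))) {
    for (j in seq_len(nrow(ades))) {
      pos <- FALSE
      if (nrow(gold)) {
        for (k in seq_len(nrow(gold))) {
          if (gold$type[k] == "DRUG_ADE" &&
              gold$arg1[k] == drugs$id[i] && gold$arg2[k] == ades$id[j]) {
            pos <- TRUE
          }
        }
      }
      lo <- min(drugs$start[i], ades$start[j]) - sentence$start
      hi <- max(drugs$end[i], ades$end[j]) - sentence$start
      out[[length(out) + 1L]] <- data.frame(
        drug_id = drugs$id[i], ade_id = ades$id[j],
        label = if (pos) "positive" else "negative",
        span = substring(sentence$text, lo + 1, hi),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) return(NULL)
  df <- do.call(rbind, out)
  df[order(df$drug_id, df$ade_id), , drop = FALSE]
}
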