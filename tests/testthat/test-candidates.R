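mk_sentence <- function(text, start = 0L, doc_id = "doc") {
  data.frame(doc_id = doc_id, sent_index = 0L, start = start,
             end = start + nchar(text), text = text, stringsAsFactors = FALSE)
}

mk_entities <- function(text, spec) {
  # spec: list of c(id, label, surface); offsets located in text
  rows <- lapply(spec, function(x) {
    at <- regexpr(x[3], text, fixed = TRUE)
    data.frame(id = x[1], label = x[2], start = as.integer(at) - 1L,
               end = as.integer(at) - 1L + nchar(x[3]), surface = x[3],
               fragmented = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

test_that("two drugs x two ADEs yield exactly four combinations", {
  txt <- "Started nivolumab and ipilimumab, later developed colitis and rash."
  ents <- mk_entities(txt, list(c("T1", "DRUG", "nivolumab"),
                                c("T2", "DRUG", "ipilimumab"),
                                c("T3", "ADE", "colitis"),
                                c("T4", "ADE", "rash")))
  gold <- data.frame(id = "R1", type = "DRUG_ADE", arg1 = "T1", arg2 = "T3",
                     stringsAsFactors = FALSE)
  cand <- enumerate_pairs(mk_sentence(txt), ents, gold)
  expect_equal(nrow(cand), 4)
  expect_equal(sum(cand$label == "positive"), 1)
  expect_equal(sum(cand$label == "negative"), 3)
  # deterministic order: drug start, then ADE start
  expect_equal(cand$drug_id, c("T1", "T1", "T2", "T2"))
  expect_equal(cand$ade_id, c("T3", "T4", "T3", "T4"))
})

test_that("a sentence without both entity kinds yields no candidates", {
  txt <- "Continues nivolumab as planned."
  ents <- mk_entities(txt, list(c("T1", "DRUG", "nivolumab")))
  expect_equal(nrow(enumerate_pairs(mk_sentence(txt), ents)), 0)
  expect_equal(nrow(enumerate_pairs(mk_sentence(txt), ents[0, ])), 0)
})

test_that("entity-level positivity: only the annotated mention pair is positive", {
  txt <- "nivolumab rash then nivolumab again."
  ents <- rbind(
    data.frame(id = "T1", label = "DRUG", start = 0L, end = 9L,
               surface = "nivolumab", fragmented = FALSE),
    data.frame(id = "T2", label = "ADE", start = 10L, end = 14L,
               surface = "rash", fragmented = FALSE),
    data.frame(id = "T3", label = "DRUG", start = 20L, end = 29L,
               surface = "nivolumab", fragmented = FALSE)
  )
  gold <- data.frame(id = "R1", type = "DRUG_ADE", arg1 = "T1", arg2 = "T2")
  cand <- enumerate_pairs(mk_sentence(txt), ents, gold)
  expect_equal(cand$label[cand$drug_id == "T1"], "positive")
  expect_equal(cand$label[cand$drug_id == "T3"], "negative")
})

test_that("extract_input_span is entity-order agnostic and flags overlap", {
  txt <- "Started nivolumab, later developed colitis here."
  s <- mk_sentence(txt)
  ents <- mk_entities(txt, list(c("T1", "DRUG", "nivolumab"),
                                c("T2", "ADE", "colitis")))
  sp <- extract_input_span(s, ents[1, ], ents[2, ])
  expect_identical(sp$span, "nivolumab, later developed colitis")
  expect_false(sp$degenerate)

  txt2 <- "colitis attributed to nivolumab today."
  ents2 <- mk_entities(txt2, list(c("T1", "DRUG", "nivolumab"),
                                  c("T2", "ADE", "colitis")))
  sp2 <- extract_input_span(mk_sentence(txt2), ents2[1, ], ents2[2, ])
  expect_identical(sp2$span, "colitis attributed to nivolumab")

  # overlapping spans: envelope + degenerate flag
  ents3 <- data.frame(id = c("T1", "T2"), label = c("DRUG", "ADE"),
                      start = c(0L, 4L), end = c(9L, 12L),
                      surface = c("nivolumab", "lumab ra"), fragmented = FALSE)
  sp3 <- extract_input_span(mk_sentence("nivolumab rash"), ents3[1, ], ents3[2, ])
  expect_true(sp3$degenerate)
  expect_equal(sp3$start, 0L)
  expect_equal(sp3$end, 12L)

  # entity outside the sentence is an error
  expect_error(extract_input_span(mk_sentence("short."), ents3[1, ],
                                  transform(ents3[2, ], end = 99L)),
               class = "ade_consistency_error")
})

test_that("enumerate_pairs matches the brute-force oracle on generated corpora", {
  corpus <- small_gen()$corpus
  n_sent <- 0
  for (doc in corpus$documents) {
    sents <- segment_sentences(doc$text, doc_id = doc$doc_id)
    for (si in seq_len(nrow(sents))) {
      inside <- doc$entities$start >= sents$start[si] &
        doc$entities$end <= sents$end[si]
      ents <- doc$entities[inside, , drop = FALSE]
      got <- enumerate_pairs(sents[si, ], ents, doc$relations,
                             doc_id = doc$doc_id)
      want <- brute_force_pairs(sents[si, ], ents, doc$relations)
      n_sent <- n_sent + 1
      if (is.null(want)) {
        expect_equal(nrow(got), 0)
      } else {
        got_s <- got[order(got$drug_id, got$ade_id),
                     c("drug_id", "ade_id", "label", "input_span")]
        expect_equal(got_s$label, want$label)
        expect_equal(got_s$input_span, want$span)
        expect_equal(nrow(got), sum(ents$label == "DRUG") * sum(ents$label == "ADE"))
      }
    }
    if (n_sent > 400) break
  }
  expect_gte(n_sent, 400)
})

test_that("labels partition candidates and counts match tallies", {
  ds <- small_dataset()
  cnt <- attr(ds, "counts")
  expect_equal(unname(cnt["n_positive"] + cnt["n_negative"]), nrow(ds))
  expect_true(all(ds$label %in% c("positive", "negative")))
})

test_that("cross-sentence gold relations contribute zero candidates", {
  gen <- fixture("crossy", function() {
    generate_corpus(synth_config(n_patients = 6, notes_per_patient = c(3, 4),
                                 p_positive_sentence = 0.2,
                                 p_cross_sentence_relation = 0.25, seed = 55))
  })
  expect_gt(gen$manifest$n_cross_relations, 0)
  ds <- build_relation_dataset(gen$corpus)
  # pipeline candidate count equals the generator's single-sentence
  # accounting; cross-sentence relations add gold relations but no rows
  expect_equal(nrow(ds), gen$manifest$n_unique_keys)
  n_gold_rel <- sum(vapply(gen$corpus$documents, function(d)
    sum(d$relations$type == "DRUG_ADE"), 0))
  expect_gt(n_gold_rel, sum(ds$label == "positive"))
})

test_that("deduplication keeps one candidate per key and is idempotent", {
  txt <- "colitis due to nivolumab."
  ents <- mk_entities(txt, list(c("T1", "DRUG", "nivolumab"),
                                c("T2", "ADE", "colitis")))
  gold <- data.frame(id = "R1", type = "DRUG_ADE", arg1 = "T1", arg2 = "T2")
  c1 <- enumerate_pairs(mk_sentence(txt, doc_id = "a"), ents, gold, doc_id = "a")
  c2 <- enumerate_pairs(mk_sentence(txt, doc_id = "b"), ents, gold, doc_id = "b")
  ds <- aderelex:::new_relation_dataset(rbind(c1, c2))
  dd <- deduplicate_candidates(ds)
  expect_equal(nrow(dd), 1)
  expect_identical(as.data.frame(deduplicate_candidates(dd)),
                   as.data.frame(dd))
  # all-unique dataset is unchanged
  ds2 <- small_dataset()
  expect_equal(nrow(deduplicate_candidates(ds2)), nrow(ds2))
})

test_that("conflicting labels under one dedup key raise a conflict error", {
  txt <- "colitis due to nivolumab."
  ents <- mk_entities(txt, list(c("T1", "DRUG", "nivolumab"),
                                c("T2", "ADE", "colitis")))
  gold <- data.frame(id = "R1", type = "DRUG_ADE", arg1 = "T1", arg2 = "T2")
  pos <- enumerate_pairs(mk_sentence(txt, doc_id = "a"), ents, gold, doc_id = "a")
  neg <- enumerate_pairs(mk_sentence(txt, doc_id = "b"), ents,
                         aderelex:::empty_relations(), doc_id = "b")
  ds <- aderelex:::new_relation_dataset(rbind(pos, neg))
  expect_error(deduplicate_candidates(ds), class = "ade_conflict_error")
})

test_that("boilerplate-heavy corpora deduplicate to the manifest count", {
  gen <- fixture("boiler", function() {
    generate_corpus(synth_config(n_patients = 8, notes_per_patient = c(3, 5),
                                 p_positive_sentence = 0.35,
                                 p_boilerplate_repeat = 0.3, seed = 77))
  })
  raw <- build_relation_dataset(gen$corpus, deduplicate = FALSE)
  expect_equal(nrow(raw), gen$manifest$n_candidates)
  expect_gt(nrow(raw), gen$manifest$n_unique_keys)  # duplicates existed
  dd <- deduplicate_candidates(raw)
  expect_equal(nrow(dd), gen$manifest$n_unique_keys)
  expect_equal(sum(dd$label == "positive"), gen$manifest$n_unique_positive)
})

test_that("combinatorial blow-up triggers a warning but still processes", {
  words <- c(paste0("nivolumab", ""), "rash")
  txt <- paste(c(rep("nivolumab", 11), rep("rash", 2)), collapse = " ")
  ents <- do.call(rbind, lapply(seq_len(13), function(i) {
    w <- c(rep("nivolumab", 11), rep("rash", 2))[i]
    start <- (i - 1L) * 10L + (i > 11) * 0L
    # compute exact offsets: words are space-separated
    offs <- cumsum(c(0, nchar(c(rep("nivolumab", 11), rep("rash", 2))) + 1))
    data.frame(id = paste0("T", i), label = if (w == "rash") "ADE" else "DRUG",
               start = offs[i], end = offs[i] + nchar(w), surface = w,
               fragmented = FALSE, stringsAsFactors = FALSE)
  }))
  expect_warning(cand <- enumerate_pairs(mk_sentence(txt), ents),
                 "blow-up")
  expect_equal(nrow(cand), 22)
})

test_that("datasets round-trip through TSV serialization", {
  ds <- small_dataset()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_relation_dataset(ds, path)
  back <- read_relation_dataset(path, attr(ds, "source_corpus"))
  expect_equal(nrow(back), nrow(ds))
  expect_identical(back$dedup_key, ds$dedup_key)
  expect_identical(back$input_span, ds$input_span)
  expect_true(file.exists(paste0(path, ".json")))
})
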