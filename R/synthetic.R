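# Synthetic clinical-note corpus generator.
#
# Emulated features of real oncology notes: multi-sentence notes with
# drug/ADE/date/causal-term/grade mentions, boilerplate sentences repeated
# verbatim across notes, irregular whitespace and mid-sentence line wraps,
# sentences holding several drugs and ADEs at once, a minority of
# cross-sentence relations, and a configurable positive:negative candidate
# ratio. All randomness flows from a single seed; (config, seed) determines
# the corpus byte for byte. Noise is injected only between template pieces,
# never inside an entity surface, so gold offsets are valid by construction.

#' Synthetic corpus configuration
#'
#' @param n_patients Number of patients.
#' @param notes_per_patient Integer range `c(lo, hi)` of notes per patient.
#' @param sentences_per_note Integer range `c(lo, hi)` of sentences per note.
#' @param p_positive_sentence Probability that a sentence carries a drug-ADE
#'   co-mention scenario (and hence candidates).
#' @param signal_strength Probability that a positive pair is realized with a
#'   causal cue and that a negative pair is realized cue-free. At 1 the
#'   cue/label mapping is deterministic; lower values inject label-signal
#'   noise in both directions.
#' @param causal_lexicon Character vector of causal cue phrases.
#' @param p_multi_entity_sentence Fraction of relation sentences realized
#'   with 2 drugs x 2 ADEs and exactly one gold relation.
#' @param p_cross_sentence_relation Probability that a sentence slot becomes
#'   a cross-sentence relation (drug in one sentence, ADE in the next; the
#'   gold relation is planted but contributes no single-sentence candidate).
#' @param p_boilerplate_repeat Probability that a relation sentence is a
#'   verbatim copy of an earlier relation sentence.
#' @param noise List with elements `p_extra_whitespace`, `p_brand_name`,
#'   `p_abbreviation`, `p_mid_sentence_linebreak`.
#' @param target_ratio Desired positive:negative candidate ratio (e.g.
#'   `189/698`).
#' @param seed Integer seed; fully determines the output.
#' @param corpus_id Corpus identifier.
#' @param split Optional `c(n_train, n_test)` document counts; when given,
#'   documents are randomly assigned to a fixed train/test split recorded in
#'   the manifest (discharge-summary style corpora with provider-defined
#'   splits).
#' @return A `synth_config` object.
#' @export
synth_config <- function(n_patients = 10,
                         notes_per_patient = c(2, 4),
                         sentences_per_note = c(4, 8),
                         p_positive_sentence = 0.2,
                         signal_strength = 0.9,
                         causal_lexicon = c("attributed to", "due to",
                                            "caused by", "induced"),
                         p_multi_entity_sentence = 0.1,
                         p_cross_sentence_relation = 0.01,
                         p_boilerplate_repeat = 0.1,
                         noise = list(),
                         target_ratio = 189 / 698,
                         seed = 1L,
                         corpus_id = "synthetic",
                         split = NULL) {
  noise_def <- list(p_extra_whitespace = 0.05, p_brand_name = 0.2,
                    p_abbreviation = 0.1, p_mid_sentence_linebreak = 0.02)
  noise <- utils::modifyList(noise_def, noise)
  probs <- c(p_positive_sentence, signal_strength, p_multi_entity_sentence,
             p_cross_sentence_relation, p_boilerplate_repeat,
             unlist(noise))
  if (any(probs < 0 | probs > 1)) {
    stop_ade("ade_config_error", "all probabilities must lie in [0, 1]")
  }
  if (length(notes_per_patient) != 2 || notes_per_patient[1] > notes_per_patient[2] ||
      length(sentences_per_note) != 2 || sentences_per_note[1] > sentences_per_note[2]) {
    stop_ade("ade_config_error", "ranges must be c(lo, hi) with lo <= hi")
  }
  if (target_ratio <= 0) {
    stop_ade("ade_config_error", "target_ratio must be positive")
  }
  if (!length(causal_lexicon)) {
    stop_ade("ade_config_error", "causal_lexicon must be non-empty")
  }
  cfg <- structure(list(
    n_patients = as.integer(n_patients),
    notes_per_patient = as.integer(notes_per_patient),
    sentences_per_note = as.integer(sentences_per_note),
    p_positive_sentence = p_positive_sentence,
    signal_strength = signal_strength,
    causal_lexicon = causal_lexicon,
    p_multi_entity_sentence = p_multi_entity_sentence,
    p_cross_sentence_relation = p_cross_sentence_relation,
    p_boilerplate_repeat = p_boilerplate_repeat,
    noise = noise, target_ratio = target_ratio,
    seed = as.integer(seed), corpus_id = corpus_id, split = split
  ), class = "synth_config")
  solve_type_mixture(cfg)  # fail fast on unsatisfiable ratios
  cfg
}

#' Shipped corpus presets
#'
#' `"ici-like"`: 47 patients with ~30 longitudinal notes each and a sparse
#' positive:negative candidate ratio near 189:698. `"n2c2-like"`: 505
#' single-note patients (discharge-summary style) with a 303/202 fixed
#' train/test split and ratio near 1355:865.
#'
#' @param name Preset name.
#' @param seed Seed override.
#' @return A `synth_config`.
#' @export
synth_preset <- function(name = c("ici-like", "n2c2-like"), seed = 1L) {
  name <- match.arg(name)
  if (name == "ici-like") {
    synth_config(
      n_patients = 47, notes_per_patient = c(25, 34),
      sentences_per_note = c(4, 8), p_positive_sentence = 0.08,
      signal_strength = 0.9, p_multi_entity_sentence = 0.1,
      p_cross_sentence_relation = 0.01, p_boilerplate_repeat = 0.1,
      target_ratio = 189 / 698, seed = seed, corpus_id = "ici-like"
    )
  } else {
    synth_config(
      n_patients = 505, notes_per_patient = c(1, 1),
      sentences_per_note = c(25, 40), p_positive_sentence = 0.105,
      signal_strength = 0.9, p_multi_entity_sentence = 0.1,
      p_cross_sentence_relation = 0.01, p_boilerplate_repeat = 0.1,
      target_ratio = 1355 / 865, seed = seed, corpus_id = "n2c2-like",
      split = c(303, 202)
    )
  }
}

# Mixture of relation-sentence types hitting the target candidate ratio.
# A multi-entity sentence contributes 1 positive + 3 negatives; a single
# co-mention contributes 1 of either. With multi fraction m and single
# positive fraction q, ratio r solves:
#   m + (1-m) q = r (3m + (1-m)(1-q))
solve_type_mixture <- function(config) {
  m <- config$p_multi_entity_sentence
  r <- config$target_ratio
  if (m >= 1) {
    # all-multi corpora have a fixed 1:3 ratio
    if (abs(r - 1 / 3) > 1e-9) {
      stop_ade("ade_config_error",
               "p_multi_entity_sentence = 1 forces ratio 1:3; target %.3f unreachable", r)
    }
    return(list(m = 1, q = 0))
  }
  q <- (3 * r * m + r * (1 - m) - m) / ((1 - m) * (1 + r))
  if (q < 0 || q > 1) {
    stop_ade("ade_config_error",
             paste0("target_ratio %.3f is unsatisfiable with ",
                    "p_multi_entity_sentence %.2f (single-positive fraction ",
                    "solves to %.3f outside [0,1]); lower the multi-entity ",
                    "probability or move the ratio toward [%.3f, %.3f]"),
             r, m, q, m / (3 * m + (1 - m)), (m + (1 - m)) / (3 * m))
  }
  list(m = m, q = q)
}

# ---- template material ------------------------------------------------

synth_drug_pool <- function() {
  lex <- default_lexicon("DRUG")
  data.frame(
    canonical = names(lex$entries),
    brand = vapply(lex$entries, function(v) {
      alt <- setdiff(v, names(lex$entries))
      if (length(alt)) alt[1] else v[1]
    }, ""),
    stringsAsFactors = FALSE
  )
}

synth_ade_pool <- function() {
  lex <- default_lexicon("ADE")
  lapply(lex$entries, identity)
}

el <- function(text, glue = " ", label = NULL, canonical = NULL) {
  list(text = text, glue = glue, label = label, canonical = canonical)
}

# Assemble a sentence from elements; separators may pick up whitespace noise
# but entity element text is never touched.
assemble_sentence <- function(elements, noise) {
  text <- ""
  ents <- list()
  for (i in seq_along(elements)) {
    e <- elements[[i]]
    g <- if (i == 1) "" else e$glue
    if (g == " ") {
      u <- stats::runif(1)
      if (u < noise$p_mid_sentence_linebreak) {
        g <- "\n"
      } else if (u < noise$p_mid_sentence_linebreak + noise$p_extra_whitespace) {
        g <- "  "
      }
    }
    text <- paste0(text, g)
    start <- nchar(text)
    text <- paste0(text, e$text)
    if (!is.null(e$label)) {
      ents[[length(ents) + 1L]] <- data.frame(
        label = e$label, start = start, end = start + nchar(e$text),
        surface = e$text, canonical = e$canonical %||% e$text,
        stringsAsFactors = FALSE
      )
    }
  }
  list(text = text,
       entities = if (length(ents)) do.call(rbind, ents) else
         data.frame(label = character(), start = integer(), end = integer(),
                    surface = character(), canonical = character(),
                    stringsAsFactors = FALSE))
}

pick <- function(x) x[[sample.int(length(x), 1L)]]

pick_drug_surface <- function(drugs, noise) {
  row <- drugs[sample.int(nrow(drugs), 1L), ]
  surf <- if (stats::runif(1) < noise$p_brand_name) row$brand else row$canonical
  list(surface = surf, canonical = row$canonical)
}

pick_ade_surface <- function(ades) {
  canon <- names(ades)[sample.int(length(ades), 1L)]
  vars <- ades[[canon]]
  surf <- if (stats::runif(1) < 0.7 || length(vars) == 1L) canon else
    pick(setdiff(vars, canon))
  list(surface = surf, canonical = canon)
}

random_date_string <- function() {
  y <- sample(2015:2018, 1); m <- sample(1:12, 1); d <- sample(1:28, 1)
  style <- sample.int(3, 1)
  if (style == 1) sprintf("%d/%d/%d", m, d, y)
  else if (style == 2) sprintf("%04d-%02d-%02d", y, m, d)
  else paste(month.name[m], paste0(d, ","), y)
}

# Long-tail padding (~24 tokens) exercising extreme sentence lengths.
long_padding <- function() {
  paste("with review of systems otherwise negative including fevers chills",
        "nausea vomiting headache dizziness fatigue weakness and unintentional",
        "weight change over the interval period since the previous visit")
}

# cue elements; "induced" realizes as the hyphenated "{drug}-induced {ade}"
cue_elements <- function(cue, drug_el, ade_el) {
  if (cue == "induced") {
    list(drug_el,
         el("-", glue = ""),
         el("induced", glue = "", label = "CAUSAL_TERM"),
         ade_el)
  } else {
    list(ade_el, el(cue, label = "CAUSAL_TERM"), drug_el)
  }
}

# ---- sentence realizers ----------------------------------------------
# Each returns list(text, entities (sentence-relative), rels (index pairs),
# kind, cand (generator-side candidate accounting rows, span text included)).

realize_single <- function(positive, cued, cue, drugs, ades, noise, long = FALSE) {
  d <- pick_drug_surface(drugs, noise)
  a <- pick_ade_surface(ades)
  d_el <- el(d$surface, label = "DRUG", canonical = d$canonical)
  a_el <- el(a$surface, label = "ADE", canonical = a$canonical)
  if (cued) {
    prefix <- pick(list("Assessment:", "Impression:", "Oncology note:",
                        "Plan discussed:", "Interval history:"))
    suffix <- pick(list(", plan steroids", ", monitoring closely",
                        ", will hold next dose", ", reviewed with team", ""))
    core <- cue_elements(cue, d_el, a_el)
    elements <- c(list(el(prefix)), core)
  } else {
    tmpl <- sample.int(6, 1)
    elements <- switch(
      tmpl,
      list(el("Patient remains on"), d_el, el("and"), a_el, el("was noted")),
      list(el("While on"), d_el, el("the patient reported"), a_el),
      list(a_el, el("documented while"), d_el, el("was continued")),
      list(el("He was taking"), d_el, el("when"), a_el, el("developed")),
      list(el("Clinic discussion covered"), d_el, el("and recent"), a_el),
      list(el("Ongoing"), d_el, el("therapy with intermittent"), a_el)
    )
    suffix <- ""
  }
  rels <- list()
  # decorations: drug date and ADE grade with their link relations
  if (cued && stats::runif(1) < 0.3) {
    elements <- c(elements, list(el("started on"),
                                 el(random_date_string(), label = "DRUG_DATE")))
  }
  if (stats::runif(1) < 0.25) {
    elements <- c(elements,
                  list(el(paste("grade", sample(1:3, 1)), label = "GRADE")))
  }
  if (long) elements <- c(elements, list(el(long_padding())))
  if (cued && nzchar(suffix)) elements <- c(elements, list(el(suffix, glue = "")))
  elements <- c(elements, list(el(".", glue = "")))
  s <- assemble_sentence(elements, noise)
  ents <- s$entities
  di <- which(ents$label == "DRUG"); ai <- which(ents$label == "ADE")
  if (positive) {
    rels <- list(list(type = "DRUG_ADE", a1 = di[1], a2 = ai[1]))
    ci <- which(ents$label == "CAUSAL_TERM")
    if (length(ci)) {
      rels <- c(rels, list(list(type = "CAUSAL_LINK", a1 = di[1], a2 = ci[1])))
    }
  }
  gi <- which(ents$label == "GRADE")
  if (length(gi)) {
    rels <- c(rels, list(list(type = "GRADE_LINK", a1 = ai[1], a2 = gi[1])))
  }
  ddi <- which(ents$label == "DRUG_DATE")
  if (length(ddi)) {
    rels <- c(rels, list(list(type = "DRUG_DATE_LINK", a1 = di[1], a2 = ddi[1])))
  }
  list(text = s$text, entities = ents, rels = rels,
       kind = if (positive) "single_pos" else "single_neg")
}

realize_multi <- function(cued, cue, drugs, ades, noise) {
  d1 <- pick_drug_surface(drugs, noise)
  repeat {
    d2 <- pick_drug_surface(drugs, noise)
    if (d2$canonical != d1$canonical) break
  }
  a1 <- pick_ade_surface(ades)
  repeat {
    a2 <- pick_ade_surface(ades)
    if (a2$canonical != a1$canonical) break
  }
  d1_el <- el(d1$surface, label = "DRUG", canonical = d1$canonical)
  d2_el <- el(d2$surface, label = "DRUG", canonical = d2$canonical)
  a1_el <- el(a1$surface, label = "ADE", canonical = a1$canonical)
  a2_el <- el(a2$surface, label = "ADE", canonical = a2$canonical)
  if (cued) {
    # arrangement d2 a2 [a1 cue d1]: the cue sits inside the gold pair's
    # envelope and outside the (d2,a2) and (d2,a1) envelopes
    core <- cue_elements(cue, d1_el, a1_el)
    elements <- c(list(el(pick(list("Course:", "Summary:", "Review:"))),
                       d2_el, el("was held while"), a2_el,
                       el("improved, and then")),
                  core, list(el(".", glue = "")))
  } else {
    elements <- list(el(pick(list("Both", "Currently both"))), d2_el,
                     el("and"), d1_el, el("continued with"), a2_el,
                     el("and"), a1_el, el("monitored"), el(".", glue = ""))
  }
  s <- assemble_sentence(elements, noise)
  ents <- s$entities
  gold_d <- which(ents$label == "DRUG" & ents$surface == d1$surface)
  gold_a <- which(ents$label == "ADE" & ents$surface == a1$surface)
  rels <- list(list(type = "DRUG_ADE", a1 = gold_d[1], a2 = gold_a[1]))
  ci <- which(ents$label == "CAUSAL_TERM")
  if (length(ci)) {
    rels <- c(rels, list(list(type = "CAUSAL_LINK", a1 = gold_d[1], a2 = ci[1])))
  }
  list(text = s$text, entities = ents, rels = rels, kind = "multi")
}

realize_filler <- function(drugs, ades, noise) {
  kind <- sample.int(10, 1)
  if (kind <= 6) {
    base <- pick(list(
      list(el("Vital signs stable and reviewed")),
      list(el("Will follow up in two weeks")),
      list(el("Labs reviewed and unremarkable")),
      list(el("No new complaints reported today")),
      list(el("Imaging pending at this time")),
      list(el("Counseling provided regarding therapy goals"))
    ))
    if (stats::runif(1) < noise$p_abbreviation) {
      base <- c(base, list(pick(list(
        el("per Dr. Lee"), el("taken b.i.d. as directed"),
        el("at 1.5 mg for now"), el("discussed w Dr. Patel")
      ))))
    }
  } else if (kind <= 8) {
    d <- pick_drug_surface(drugs, noise)
    base <- list(pick(list(el("Continues"), el("Next cycle of"))),
                 el(d$surface, label = "DRUG", canonical = d$canonical),
                 pick(list(el("without concern"), el("as planned"))))
  } else {
    a <- pick_ade_surface(ades)
    base <- list(pick(list(el("Prior"), el("Previous"))),
                 el(a$surface, label = "ADE", canonical = a$canonical),
                 pick(list(el("has resolved"), el("remains quiescent"))))
  }
  base <- c(base, list(el(".", glue = "")))
  s <- assemble_sentence(base, noise)
  list(text = s$text, entities = s$entities, rels = list(), kind = "filler")
}

realize_cross_pair <- function(drugs, ades, noise) {
  d <- pick_drug_surface(drugs, noise)
  a <- pick_ade_surface(ades)
  s1 <- assemble_sentence(list(
    el("Received"), el(d$surface, label = "DRUG", canonical = d$canonical),
    el("during the last cycle"), el(".", glue = "")
  ), noise)
  s2 <- assemble_sentence(list(
    el("New"), el(a$surface, label = "ADE", canonical = a$canonical),
    el("reported, likely immune mediated"), el(".", glue = "")
  ), noise)
  list(
    list(text = s1$text, entities = s1$entities, rels = list(),
         kind = "cross_drug"),
    list(text = s2$text, entities = s2$entities, rels = list(),
         kind = "cross_ade")
  )
}

# Generator-side candidate accounting for one realized relation sentence:
# the |drugs| x |ADEs| cross product computed directly from the generator's
# own records (independent of the candidates module).
sentence_candidates <- function(sent) {
  ents <- sent$entities
  di <- which(ents$label == "DRUG"); ai <- which(ents$label == "ADE")
  if (!length(di) || !length(ai)) return(NULL)
  gold <- vapply(sent$rels, function(r)
    if (r$type == "DRUG_ADE") paste(r$a1, r$a2) else "", "")
  rows <- list()
  for (i in di[order(ents$start[di])]) {
    for (j in ai[order(ents$start[ai])]) {
      s <- min(ents$start[i], ents$start[j])
      e <- max(ents$end[i], ents$end[j])
      span <- slice0(sent$text, s, e)
      lab <- if (paste(i, j) %in% gold) "positive" else "negative"
      rows[[length(rows) + 1L]] <- data.frame(
        drug_surface = ents$surface[i], ade_surface = ents$surface[j],
        span = span, label = lab,
        key = make_dedup_key(ents$surface[i], span, ents$surface[j], sent$text),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

# ---- corpus generation ------------------------------------------------

#' Generate a synthetic annotated corpus
#'
#' See [synth_config()] for the dials. Relation-sentence types (single
#' positive / single negative / multi-entity) are allocated by deterministic
#' quota so the realized candidate ratio tracks `target_ratio`; boilerplate
#' slots copy earlier relation sentences verbatim. The returned manifest is
#' the generator's own ground-truth accounting (planted mentions, dates,
#' per-sentence candidate predictions with dedup keys, cross-sentence
#' relations) computed independently of the pipeline modules, so it can act
#' as an oracle in tests.
#'
#' @param config A `synth_config`.
#' @return List with elements `corpus` (an `ade_corpus`, gold-annotated) and
#'   `manifest`.
#' @export
generate_corpus <- function(config) {
  with_seed(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(config) {
  drugs <- synth_drug_pool()
  ades <- synth_ade_pool()
  mix <- solve_type_mixture(config)
  noise <- config$noise

  # ---- plan pass: slot roles for every sentence of every note
  plan <- list()
  for (p in seq_len(config$n_patients)) {
    n_notes <- sample(seq(config$notes_per_patient[1],
                          config$notes_per_patient[2]), 1L)
    base_date <- as.Date("2015-01-01") + sample.int(700, 1L)
    for (nn in seq_len(n_notes)) {
      n_sent <- sample(seq(config$sentences_per_note[1],
                           config$sentences_per_note[2]), 1L)
      roles <- character(n_sent)
      si <- 1L
      while (si <= n_sent) {
        u <- stats::runif(1)
        if (u < config$p_cross_sentence_relation && si < n_sent) {
          roles[si] <- "cross"; roles[si + 1L] <- "cross2"; si <- si + 2L
        } else if (u < config$p_cross_sentence_relation + config$p_positive_sentence) {
          roles[si] <- "relation"; si <- si + 1L
        } else {
          roles[si] <- "filler"; si <- si + 1L
        }
      }
      note_date <- base_date + (nn - 1L) * sample(3:15, 1L)
      plan[[length(plan) + 1L]] <- list(
        patient = sprintf("P%03d", p), seq = nn,
        date = note_date, roles = roles
      )
    }
  }

  # deterministic type quota. Sized for every relation slot (a boilerplate
  # slot falls back to an original while the registry is still empty), but
  # consumed only by originals, so the realized composition follows the
  # mixture.
  rel_slots <- sum(vapply(plan, function(nt) sum(nt$roles == "relation"), 0L))
  is_boiler <- stats::runif(rel_slots) < config$p_boilerplate_repeat
  n_multi <- round(mix$m * rel_slots)
  n_single <- rel_slots - n_multi
  n_pos <- round(mix$q * n_single)
  types <- sample(c(rep("multi", n_multi), rep("single_pos", n_pos),
                    rep("single_neg", n_single - n_pos)))

  # ---- realize pass
  registry <- list()        # realized relation sentences available for copy
  text_seen <- new.env(parent = emptyenv())  # sentence text -> registry index
                                             # (identical text must carry
                                             # identical gold, as a human
                                             # annotator would label it)
  docs <- list()
  mentions <- list(); dates <- list(); cands <- list()
  cross_count <- 0L
  rel_i <- 0L; orig_i <- 0L
  sent_uid <- 0L

  for (nt in plan) {
    sents <- list()
    roles <- nt$roles
    si <- 1L
    while (si <= length(roles)) {
      role <- roles[si]
      if (role == "cross") {
        pair <- realize_cross_pair(drugs, ades, noise)
        sents[[length(sents) + 1L]] <- pair[[1]]
        sents[[length(sents) + 1L]] <- pair[[2]]
        cross_count <- cross_count + 1L
        si <- si + 2L
      } else if (role == "relation") {
        rel_i <- rel_i + 1L
        from_boiler <- is_boiler[rel_i] && length(registry) > 0L
        if (from_boiler) {
          sent <- registry[[sample.int(length(registry), 1L)]]
        } else {
          orig_i <- orig_i + 1L
          type <- types[orig_i]
          long <- stats::runif(1) < 0.02
          sent <- switch(
            type,
            single_pos = realize_single(TRUE, stats::runif(1) < config$signal_strength,
                                        pick(config$causal_lexicon), drugs, ades,
                                        noise, long),
            single_neg = realize_single(FALSE, stats::runif(1) >= config$signal_strength,
                                        pick(config$causal_lexicon), drugs, ades,
                                        noise, long),
            multi = realize_multi(stats::runif(1) < config$signal_strength,
                                  pick(config$causal_lexicon), drugs, ades, noise)
          )
          tkey <- tolower(str_squish(sent$text))
          prior <- text_seen[[tkey]]
          if (!is.null(prior)) {
            sent <- registry[[prior]]   # textual collision: reuse prior gold
          } else {
            registry[[length(registry) + 1L]] <- sent
            text_seen[[tkey]] <- length(registry)
          }
        }
        sent$from_boilerplate <- from_boiler
        sents[[length(sents) + 1L]] <- sent
        si <- si + 1L
      } else {
        sents[[length(sents) + 1L]] <- realize_filler(drugs, ades, noise)
        si <- si + 1L
      }
    }

    # assemble the note: sentences joined by " " or a paragraph break
    doc_id <- sprintf("%s_%s_%02d", nt$patient, format(nt$date, "%Y%m%d"), nt$seq)
    text <- ""
    ent_rows <- list(); rel_rows <- list()
    cross_pending <- NULL   # entity index of a cross-sentence drug mention
    for (k in seq_along(sents)) {
      sep <- if (k == 1) "" else if (stats::runif(1) < 0.15) "\n\n" else " "
      if (sep == " " && stats::runif(1) < noise$p_extra_whitespace) sep <- "  "
      text <- paste0(text, sep)
      off <- nchar(text)
      text <- paste0(text, sents[[k]]$text)
      ents <- sents[[k]]$entities
      base_idx <- length(ent_rows)
      if (nrow(ents)) {
        for (r in seq_len(nrow(ents))) {
          ent_rows[[base_idx + r]] <- data.frame(
            label = ents$label[r], start = off + ents$start[r],
            end = off + ents$end[r], surface = ents$surface[r],
            stringsAsFactors = FALSE
          )
        }
      }
      for (rl in sents[[k]]$rels) {
        rel_rows[[length(rel_rows) + 1L]] <- c(rl$type, base_idx + rl$a1,
                                               base_idx + rl$a2)
      }
      if (sents[[k]]$kind == "cross_drug") {
        cross_pending <- base_idx + which(ents$label == "DRUG")[1]
      } else if (sents[[k]]$kind == "cross_ade" && !is.null(cross_pending)) {
        rel_rows[[length(rel_rows) + 1L]] <-
          c("DRUG_ADE", cross_pending, base_idx + which(ents$label == "ADE")[1])
        cross_pending <- NULL
      }
      # manifest accounting
      sent_uid <- sent_uid + 1L
      cc <- sentence_candidates(sents[[k]])
      if (!is.null(cc)) {
        cc$doc_id <- doc_id
        cc$sent_uid <- sent_uid
        cc$from_boilerplate <- isTRUE(sents[[k]]$from_boilerplate)
        cands[[length(cands) + 1L]] <- cc
      }
      if (nrow(ents)) {
        keep <- ents$label %in% c("DRUG", "ADE")
        if (any(keep)) {
          mm <- ents[keep, , drop = FALSE]
          mentions[[length(mentions) + 1L]] <- data.frame(
            doc_id = doc_id, label = mm$label, start = off + mm$start,
            end = off + mm$end, surface = mm$surface, stringsAsFactors = FALSE
          )
        }
        dk <- ents$label == "DRUG_DATE"
        if (any(dk)) {
          dd <- ents[dk, , drop = FALSE]
          dates[[length(dates) + 1L]] <- data.frame(
            doc_id = doc_id, start = off + dd$start, end = off + dd$end,
            surface = dd$surface, stringsAsFactors = FALSE
          )
        }
      }
    }

    entities <- if (length(ent_rows)) do.call(rbind, ent_rows) else empty_entities()
    if (nrow(entities)) {
      entities$id <- paste0("T", seq_len(nrow(entities)))
      entities$fragmented <- FALSE
      entities <- entities[, c("id", "label", "start", "end", "surface",
                               "fragmented")]
    }
    relations <- if (length(rel_rows)) {
      data.frame(
        id = paste0("R", seq_along(rel_rows)),
        type = vapply(rel_rows, `[`, "", 1L),
        arg1 = paste0("T", vapply(rel_rows, `[`, "", 2L)),
        arg2 = paste0("T", vapply(rel_rows, `[`, "", 3L)),
        stringsAsFactors = FALSE
      )
    } else empty_relations()

    docs[[length(docs) + 1L]] <- ade_document(
      doc_id, text, entities, relations, patient_id = nt$patient,
      note_date = nt$date, order_index = nt$seq
    )
  }

  corpus <- ade_corpus(config$corpus_id, docs,
                       provenance = sprintf("synthetic (seed %d)", config$seed))

  cand_df <- if (length(cands)) do.call(rbind, cands) else
    data.frame(drug_surface = character(), ade_surface = character(),
               span = character(), label = character(), key = character(),
               doc_id = character(), sent_uid = integer(),
               from_boilerplate = logical(), stringsAsFactors = FALSE)
  first <- !duplicated(cand_df$key)
  doc_split <- NULL
  if (!is.null(config$split)) {
    ids <- vapply(docs, `[[`, "", "doc_id")
    if (sum(config$split) != length(ids)) {
      stop_ade("ade_config_error",
               "split %d+%d does not match %d generated documents",
               config$split[1], config$split[2], length(ids))
    }
    train_ids <- sample(ids, config$split[1])
    doc_split <- stats::setNames(ifelse(ids %in% train_ids, "train", "test"), ids)
    attr(corpus, "doc_split") <- doc_split
  }

  manifest <- list(
    config = config,
    n_documents = length(docs),
    mentions = if (length(mentions)) do.call(rbind, mentions) else NULL,
    dates = if (length(dates)) do.call(rbind, dates) else NULL,
    candidates = cand_df,
    n_candidates = nrow(cand_df),
    n_positive = sum(cand_df$label == "positive"),
    n_negative = sum(cand_df$label == "negative"),
    n_unique_keys = length(unique(cand_df$key)),
    n_unique_positive = sum(cand_df$label[first] == "positive"),
    n_unique_negative = sum(cand_df$label[first] == "negative"),
    n_cross_relations = cross_count,
    doc_split = doc_split
  )
  list(corpus = corpus, manifest = manifest)
}

#' Generate paired corpora with controlled causal-cue overlap
#'
#' Emulates corpora annotated under diverging guidelines: the two causal-cue
#' lexicons share the stated fraction of cues. `cue_overlap = 1` gives
#' identical lexicons, `0` disjoint ones. Used for inter-corpus degradation
#' experiments.
#'
#' @param config_a,config_b `synth_config`s for the two corpora (seeds
#'   should differ).
#' @param cue_overlap Shared fraction of the cue lexicons, in `[0, 1]`.
#' @return List with elements `a` and `b`, each a
#'   `list(corpus, manifest)`.
#' @export
make_paired_corpora <- function(config_a, config_b, cue_overlap = 1) {
  if (cue_overlap < 0 || cue_overlap > 1) {
    stop_ade("ade_config_error", "cue_overlap must lie in [0, 1]")
  }
  cues_a <- c("attributed to", "due to", "caused by", "induced")
  cues_alt <- c("secondary to", "resulting from", "linked with", "triggered by")
  k <- round(cue_overlap * length(cues_a))
  cues_b <- c(cues_a[seq_len(k)],
              cues_alt[seq_len(length(cues_a) - k)])
  config_a$causal_lexicon <- cues_a
  config_b$causal_lexicon <- cues_b
  list(a = generate_corpus(config_a), b = generate_corpus(config_b))
}
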