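# Seed-reproducible synthetic annotated-corpus generator.
#
# The generator emulates the statistical structure an ADE-annotated clinical
# corpus exposes to the pipeline -- entity-class proportions, multiword
# ("compound") entity rate, mean sentences per note, the fraction of notes
# carrying at least one explicit ADE relation, and schema-valid relations
# realized close enough together for a 3-sentence passage window -- using
# pseudo-Swedish template filler rather than clinical language.

#' Configuration for the synthetic corpus generator
#'
#' Defaults mirror the corpus statistics the generator emulates: entity-class
#' proportions 0.35/0.29/0.20/0.12/0.04 (Finding/Drug/Disorder/
#' BodyStructure/AdeCue), a 23% multiword-entity rate, a mean of 14
#' sentences per note, and 62% of notes containing at least one explicit
#' ADE-flavored relation.
#'
#' @param n_notes Number of notes to generate.
#' @param entity_class_weights Named proportions over [entity_classes()],
#'   summing to 1.
#' @param compound_entity_rate Probability that an entity mention spans >= 2
#'   tokens.
#' @param ade_note_fraction Probability that a note contains at least one
#'   relation from the ADE-indicating set (`ADE`, `AdeCause`, `AdeOutcome`).
#' @param lexical_overlap_rate Fraction of `AdeCue` head terms shared with
#'   the `Disorder` vocabulary. At 0 (the default, "separable mode") all
#'   class vocabularies are pairwise disjoint; positive values reproduce the
#'   cue/disorder/finding surface-form ambiguity of real clinical text.
#' @param mean_sentences_per_note Poisson mean for sentences per note
#'   (floored at 3).
#' @param relation_attach_prob Probability that an adjacent permissible
#'   in-sentence entity pair is realized as a primary relation (with an
#'   explicit lexical trigger between the two mentions).
#' @param cross_sentence_rate Probability that a sentence boundary carries a
#'   relation joining the flanking sentences' nearest entities, so that some
#'   gold relations span two sentences.
#' @param seed Integer seed; identical configs produce bit-identical corpora.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_notes = 500L,
                             entity_class_weights = c(Finding = 0.35, Drug = 0.29,
                                                      Disorder = 0.20,
                                                      BodyStructure = 0.12,
                                                      AdeCue = 0.04),
                             compound_entity_rate = 0.23,
                             ade_note_fraction = 0.62,
                             lexical_overlap_rate = 0,
                             mean_sentences_per_note = 14,
                             relation_attach_prob = 0.5,
                             cross_sentence_rate = 0.15,
                             seed = 1L) {
  stopifnot(n_notes >= 1L,
            setequal(names(entity_class_weights), entity_classes()),
            abs(sum(entity_class_weights) - 1) < 1e-8,
            compound_entity_rate >= 0, compound_entity_rate <= 1,
            ade_note_fraction >= 0, ade_note_fraction <= 1,
            lexical_overlap_rate >= 0, lexical_overlap_rate <= 1,
            mean_sentences_per_note > 0,
            relation_attach_prob >= 0, relation_attach_prob <= 1)
  structure(list(n_notes = as.integer(n_notes),
                 entity_class_weights = entity_class_weights[entity_classes()],
                 compound_entity_rate = compound_entity_rate,
                 ade_note_fraction = ade_note_fraction,
                 lexical_overlap_rate = lexical_overlap_rate,
                 mean_sentences_per_note = mean_sentences_per_note,
                 relation_attach_prob = relation_attach_prob,
                 cross_sentence_rate = cross_sentence_rate,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# deterministic pseudo-Swedish word stock: CV(C) syllable strings
make_words <- function(n, n_syll = 2:3) {
  cons <- c("b", "d", "f", "g", "h", "k", "l", "m", "n", "p", "r", "s", "t", "v",
            "sk", "st", "tr", "kl")
  vow <- c("a", "e", "i", "o", "u", "y", "å", "ä", "ö")
  out <- character(0)
  while (length(out) < n) {
    k <- sample(n_syll, 1L)
    w <- paste0(paste0(sample(cons, k, replace = TRUE),
                       sample(vow, k, replace = TRUE), collapse = ""),
                sample(c("", "n", "r", "t"), 1L))
    out <- unique(c(out, w))
  }
  out[seq_len(n)]
}

#' Build the generator's lexicon
#'
#' Produces disjoint per-class head-term and modifier vocabularies, filler
#' words, and one trigger vocabulary per primary relation class. With
#' `lexical_overlap_rate > 0`, the configured fraction of `AdeCue` heads is
#' replaced by terms drawn from the `Disorder` vocabulary, so the two classes
#' share surface forms.
#'
#' @param config A [generator_config()].
#' @return A list of class `ade_lexicon` with elements `heads`, `modifiers`
#'   (both named by entity class), `filler`, and `triggers` (named by primary
#'   relation class).
#' @export
build_lexicon <- function(config) {
  sizes <- c(Finding = 40L, Drug = 30L, Disorder = 30L, BodyStructure = 20L,
             AdeCue = 12L)
  with_seed(config$seed, {
    total <- sum(sizes) + 5L * 8L + 50L + 4L * 3L
    words <- make_words(total)
    take <- function(k) { w <- words[seq_len(k)]; words <<- words[-seq_len(k)]; w }
    heads <- lapply(sizes, take)
    modifiers <- lapply(stats::setNames(entity_classes(), entity_classes()),
                        function(cls) take(8L))
    filler <- take(50L)
    triggers <- lapply(stats::setNames(primary_relation_classes(),
                                       primary_relation_classes()),
                       function(cls) take(3L))
    if (config$lexical_overlap_rate > 0) {
      k <- min(length(heads$AdeCue),
               ceiling(config$lexical_overlap_rate * length(heads$AdeCue)))
      heads$AdeCue[seq_len(k)] <- sample(heads$Disorder, k)
    }
    structure(list(heads = heads, modifiers = modifiers, filler = filler,
                   triggers = triggers),
              class = "ade_lexicon")
  })
}

# permissible unordered type pairs and how a primary label orients its args:
# arg1 is the semantic source (Indication: Finding/Disorder -> Drug;
# ADE: Drug -> Finding/Disorder; AdeOutcome: AdeCue -> Finding/Disorder;
# AdeCause: Drug -> AdeCue)
orient_relation <- function(label, id_a, cls_a, id_b, cls_b) {
  src_cls <- switch(label,
    Indication = c("Finding", "Disorder"),
    ADE = "Drug",
    AdeOutcome = "AdeCue",
    AdeCause = "Drug",
    stop("cannot orient label ", label))
  if (cls_a %in% src_cls) c(id_a, id_b) else c(id_b, id_a)
}

# primary labels available to a note given its ADE flag, for one type pair
allowed_labels <- function(cls_a, cls_b, ade_ok) {
  pair <- sort(c(cls_a, cls_b))
  prim <- if (pair[1] == "Drug" && pair[2] %in% c("Finding", "Disorder")) {
    c("Indication", "ADE")
  } else if (identical(pair, sort(c("AdeCue", "Finding"))) ||
             identical(pair, sort(c("AdeCue", "Disorder")))) {
    "AdeOutcome"
  } else if (identical(pair, sort(c("AdeCue", "Drug")))) {
    "AdeCause"
  } else character(0)
  if (!ade_ok) prim <- intersect(prim, "Indication")
  prim
}

# sample a label from the allowed set (Indication favored 0.6 over ADE when
# both are available, echoing the corpus' relation-class mix)
pick_label <- function(allowed) {
  if (setequal(allowed, c("Indication", "ADE")))
    sample(c("Indication", "ADE"), 1L, prob = c(0.6, 0.4))
  else sample(allowed, 1L)
}

# draw one entity mention: tokens + class
draw_mention <- function(config, lexicon) {
  cls <- sample(entity_classes(), 1L, prob = config$entity_class_weights)
  head <- sample(lexicon$heads[[cls]], 1L)
  toks <- if (stats::runif(1) < config$compound_entity_rate)
    c(sample(lexicon$modifiers[[cls]], 1L), head) else head
  list(cls = cls, tokens = toks)
}

#' Generate one synthetic note
#'
#' Sentences are templated sequences of filler words and entity mentions.
#' Primary relations are realized by inserting a class-specific trigger word
#' between the two argument mentions (possibly across one sentence boundary),
#' so every gold relation joins entities at most two sentences apart and is
#' schema-permissible. A note drawn as ADE-positive is guaranteed at least
#' one relation from {ADE, AdeCause, AdeOutcome} (a dedicated relation
#' sentence is appended if none arose); an ADE-negative note carries only
#' Indication relations.
#'
#' Consumes the current RNG stream; [generate_corpus()] seeds it once per
#' corpus.
#'
#' @param config A [generator_config()].
#' @param lexicon A lexicon from [build_lexicon()].
#' @param id Note id string.
#' @return An [ade_note()].
#' @export
generate_note <- function(config, lexicon, id = "note_1") {
  has_ade <- stats::runif(1) < config$ade_note_fraction
  n_sent <- max(3L, stats::rpois(1L, config$mean_sentences_per_note))

  toks <- character(0); sent_starts <- integer(0)
  ents <- empty_entities(); rels <- empty_relations()
  next_eid <- 1L
  # last/first entity of each sentence, for cross-sentence attachment
  sent_edge <- vector("list", n_sent)

  emit_entity <- function(mention, at) {
    # 'at' = token index (0-based) where the mention starts
    eid <- paste0("T", next_eid); next_eid <<- next_eid + 1L
    ents <<- rbind(ents, data.frame(
      id = eid, cls = mention$cls, token_start = at,
      token_end = at + length(mention$tokens), stringsAsFactors = FALSE))
    eid
  }

  fill <- function(k) sample(lexicon$filler, k, replace = TRUE)

  for (s in seq_len(n_sent)) {
    sent_starts <- c(sent_starts, length(toks))
    n_ent <- sample(0:3, 1L, prob = c(0.20, 0.35, 0.30, 0.15))
    mentions <- if (n_ent > 0) replicate(n_ent, draw_mention(config, lexicon),
                                         simplify = FALSE) else list()
    sent_toks <- fill(sample(1:2, 1L))
    sent_eids <- character(0); sent_ecls <- character(0)
    for (m in seq_along(mentions)) {
      if (m > 1L) {
        # gap between consecutive mentions: maybe a relation trigger
        a <- length(sent_eids); lab <- NULL
        allowed <- allowed_labels(sent_ecls[a], mentions[[m]]$cls, has_ade)
        if (length(allowed) && stats::runif(1) < config$relation_attach_prob)
          lab <- pick_label(allowed)
        if (is.null(lab)) {
          sent_toks <- c(sent_toks, fill(sample(1:2, 1L)))
        } else {
          sent_toks <- c(sent_toks, sample(lexicon$triggers[[lab]], 1L))
        }
        eid <- emit_entity(mentions[[m]], length(toks) + length(sent_toks))
        if (!is.null(lab)) {
          args <- orient_relation(lab, sent_eids[a], sent_ecls[a],
                                  eid, mentions[[m]]$cls)
          rels <- rbind(rels, data.frame(label = lab, arg1 = args[1L],
                                         arg2 = args[2L], stringsAsFactors = FALSE))
        }
      } else {
        eid <- emit_entity(mentions[[m]], length(toks) + length(sent_toks))
      }
      sent_toks <- c(sent_toks, mentions[[m]]$tokens)
      sent_eids <- c(sent_eids, eid); sent_ecls <- c(sent_ecls, mentions[[m]]$cls)
    }
    sent_toks <- c(sent_toks, fill(1L), ".")
    # cross-sentence relation: join this sentence's first entity to the
    # previous sentence's last entity, trigger placed early in this sentence
    prev <- if (s > 1L) sent_edge[[s - 1L]] else NULL
    if (!is.null(prev) && length(sent_eids) &&
          stats::runif(1) < config$cross_sentence_rate &&
          config$relation_attach_prob > 0) {
      allowed <- allowed_labels(prev$cls, sent_ecls[1L], has_ade)
      if (length(allowed)) {
        lab <- pick_label(allowed)
        # insert trigger token right before this sentence's first mention
        at <- ents$token_start[ents$id == sent_eids[1L]] - length(toks)
        trig <- sample(lexicon$triggers[[lab]], 1L)
        sent_toks <- append(sent_toks, trig, after = at)
        ents$token_start <- ifelse(ents$token_start >= at + length(toks),
                                   ents$token_start + 1L, ents$token_start)
        ents$token_end <- ifelse(ents$token_end > at + length(toks),
                                 ents$token_end + 1L, ents$token_end)
        args <- orient_relation(lab, prev$id, prev$cls,
                                sent_eids[1L], sent_ecls[1L])
        rels <- rbind(rels, data.frame(label = lab, arg1 = args[1L],
                                       arg2 = args[2L], stringsAsFactors = FALSE))
      }
    }
    if (length(sent_eids))
      sent_edge[[s]] <- list(id = sent_eids[length(sent_eids)],
                             cls = sent_ecls[length(sent_ecls)])
    toks <- c(toks, sent_toks)
  }

  ade_set <- c("ADE", "AdeCause", "AdeOutcome")
  if (has_ade && !any(rels$label %in% ade_set)) {
    # force one explicit ADE relation sentence
    sent_starts <- c(sent_starts, length(toks))
    drug <- list(cls = "Drug", tokens = sample(lexicon$heads$Drug, 1L))
    find <- list(cls = "Finding", tokens = sample(lexicon$heads$Finding, 1L))
    sent_toks <- fill(1L)
    d_id <- emit_entity(drug, length(toks) + length(sent_toks))
    sent_toks <- c(sent_toks, drug$tokens, sample(lexicon$triggers$ADE, 1L))
    f_id <- emit_entity(find, length(toks) + length(sent_toks))
    sent_toks <- c(sent_toks, find$tokens, ".")
    rels <- rbind(rels, data.frame(label = "ADE", arg1 = d_id, arg2 = f_id,
                                   stringsAsFactors = FALSE))
    toks <- c(toks, sent_toks)
  }

  ade_note(id, toks, sentence_starts = sent_starts,
           entities = ents, relations = rels)
}

#' Generate a synthetic annotated corpus
#'
#' Generates `config$n_notes` notes deterministically from `config$seed`;
#' optionally writes each note as a `<id>.txt` / `.conll` / `.ann` triple
#' plus a JSON manifest of gold note-level ADE flags and the configuration.
#'
#' @param config A [generator_config()].
#' @param dir Optional output directory; when given, files are written and
#'   must re-parse to the identical in-memory corpus.
#' @return Named list of [ade_note()] objects with attributes `config` and
#'   `ade_flags` (named logical vector: gold note-level ADE labels).
#' @export
generate_corpus <- function(config, dir = NULL) {
  lexicon <- build_lexicon(config)
  width <- nchar(as.character(config$n_notes))
  ids <- sprintf(paste0("note_%0", width, "d"), seq_len(config$n_notes))
  notes <- with_seed(config$seed + 1L, {
    lapply(ids, function(id) generate_note(config, lexicon, id))
  })
  names(notes) <- ids
  flags <- vapply(notes, function(nt)
    any(nt$relations$label %in% c("ADE", "AdeCause", "AdeOutcome")), logical(1))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (nt in notes) write_note_files(nt, dir)
    manifest <- list(config = unclass(config), ade_flags = as.list(flags))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  structure(notes, config = config, ade_flags = flags)
}

#' Gold note-level ADE flags of a corpus
#'
#' @param notes A list of [ade_note()] objects.
#' @param rule An [ade_rule()]; defaults to the standard ADE-indicating set.
#' @return Named logical vector.
#' @export
corpus_ade_flags <- function(notes, rule = ade_rule()) {
  vapply(notes, function(nt) detect_note_ade(nt$relations, rule), logical(1))
}
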