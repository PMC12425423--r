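# Relation extraction: 3-sentence passages (stride 1), schema-constrained
# candidate pair generation with No-relation construction, entity-marked
# pair rendering, and a 5-class pair classifier.

#' The permissible-relation schema
#'
#' Maps unordered entity-type pairs to their candidate label sets. Pairs not
#' listed are never relation candidates (e.g. Drug with BodyStructure is
#' invalid by definition):
#' \itemize{
#'   \item \{Drug, Finding\} and \{Drug, Disorder\}: Indication, ADE, NoRelation
#'   \item \{AdeCue, Finding\} and \{AdeCue, Disorder\}: AdeOutcome, NoRelation
#'   \item \{Drug, AdeCue\}: AdeCause, NoRelation
#' }
#'
#' @return Named list of class `relation_schema`; names are sorted
#'   `"clsA|clsB"` type-pair keys, values the candidate label sets.
#' @export
relation_schema <- function() {
  key <- function(a, b) paste(sort(c(a, b)), collapse = "|")
  structure(stats::setNames(
    list(c("Indication", "ADE", "NoRelation"),
         c("Indication", "ADE", "NoRelation"),
         c("AdeOutcome", "NoRelation"),
         c("AdeOutcome", "NoRelation"),
         c("AdeCause", "NoRelation")),
    c(key("Drug", "Finding"), key("Drug", "Disorder"),
      key("AdeCue", "Finding"), key("AdeCue", "Disorder"),
      key("Drug", "AdeCue"))), class = "relation_schema")
}

schema_labels <- function(schema, cls_a, cls_b) {
  schema[[paste(sort(c(cls_a, cls_b)), collapse = "|")]]
}

#' Segment a note into 3-sentence passages with stride 1
#'
#' Passages start at every sentence index `0 .. S-3`; a note with fewer than
#' 3 sentences yields a single passage covering all of them.
#'
#' @param note An [ade_note()] with sentence ranges.
#' @param entities Entity data frame used to compute containment; defaults
#'   to the note's own entities.
#' @return Data frame with 0-based half-open columns `sent_start`,
#'   `sent_end`, `token_start`, `token_end`, and a list-column `entity_ids`
#'   of entities fully inside each passage.
#' @export
make_passages <- function(note, entities = note$entities) {
  S <- nrow(note$sentences)
  starts <- if (S < 3L) 0L else 0:(S - 3L)
  ends <- pmin(starts + 3L, S)
  tok_s <- note$sentences$start[starts + 1L]
  tok_e <- note$sentences$end[ends]
  eids <- lapply(seq_along(starts), function(k) {
    inside <- entities$token_start >= tok_s[k] & entities$token_end <= tok_e[k]
    entities$id[inside]
  })
  out <- data.frame(sent_start = starts, sent_end = ends,
                    token_start = tok_s, token_end = tok_e)
  out$entity_ids <- eids
  out
}

#' Render a candidate pair as marked passage text
#'
#' The passage tokens are emitted with the first entity wrapped in
#' `[E1] ... [/E1]` and the second in `[E2] ... [/E2]`. If the marked
#' passage exceeds `max_tokens`, context is truncated symmetrically around
#' the pair; the entities and everything between them are always kept.
#'
#' @param note An [ade_note()].
#' @param passage One row of [make_passages()] output.
#' @param e1,e2 Entity rows (document order: `e1` precedes `e2`).
#' @param max_tokens Maximum rendered length in tokens.
#' @return A single string.
#' @export
render_pair_input <- function(note, passage, e1, e2, max_tokens = 512L) {
  idx <- (passage$token_start + 1L):passage$token_end
  words <- note$tokens$text[idx]
  # positions of entity bounds relative to the passage (1-based)
  r1 <- c(e1$token_start - passage$token_start + 1L,
          e1$token_end - passage$token_start)
  r2 <- c(e2$token_start - passage$token_start + 1L,
          e2$token_end - passage$token_start)
  n_extra <- 4L
  if (length(words) + n_extra > max_tokens) {
    keep_lo <- r1[1L]; keep_hi <- r2[2L]
    budget <- max_tokens - n_extra - (keep_hi - keep_lo + 1L)
    left <- max(1L, keep_lo - max(0L, budget %/% 2L))
    right <- min(length(words), keep_hi + max(0L, budget - (keep_lo - left)))
    shift <- left - 1L
    words <- words[left:right]
    r1 <- r1 - shift; r2 <- r2 - shift
  }
  out <- character(0)
  for (i in seq_along(words)) {
    if (i == r1[1L]) out <- c(out, "[E1]")
    if (i == r2[1L]) out <- c(out, "[E2]")
    out <- c(out, words[i])
    if (i == r1[2L]) out <- c(out, "[/E1]")
    if (i == r2[2L]) out <- c(out, "[/E2]")
  }
  paste(out, collapse = " ")
}

#' Generate relation candidates for a note
#'
#' Enumerates every unordered entity pair whose type pair is permissible
#' under the schema and that co-occurs fully inside at least one 3-sentence
#' passage; each such pair yields exactly one candidate, attached to its
#' canonical passage (the one where the pair sits most centered; ties go to
#' the earliest passage). The gold label is the annotated relation joining
#' the pair if one exists, else `NoRelation` -- at inference time, with
#' unannotated (predicted) entities, every candidate is generated through
#' this same label-blind path.
#'
#' @param note An [ade_note()].
#' @param schema A [relation_schema()].
#' @param entities Entity data frame (gold at training time, predicted at
#'   inference); defaults to the note's gold entities.
#' @param relations Relation data frame used for gold labels; defaults to
#'   the note's gold relations.
#' @return Data frame of candidates: `note_id`, `e1`, `e2` (ids, document
#'   order), `cls1`, `cls2`, `passage` (row index into [make_passages()]),
#'   `gold_label`, `text` (rendered marked passage).
#' @export
generate_candidates <- function(note, schema = relation_schema(),
                                entities = note$entities,
                                relations = note$relations) {
  out <- data.frame(note_id = character(), e1 = character(), e2 = character(),
                    cls1 = character(), cls2 = character(),
                    passage = integer(), gold_label = character(),
                    text = character(), stringsAsFactors = FALSE)
  if (nrow(entities) < 2L) return(out)
  passages <- make_passages(note, entities)
  S <- nrow(note$sentences)
  tok_sent <- rep(seq_len(S) - 1L, note$sentences$end - note$sentences$start)
  ents <- entities[order(entities$token_start), , drop = FALSE]
  first_sent <- tok_sent[ents$token_start + 1L]
  last_sent <- tok_sent[ents$token_end]
  orphan <- ents$id[last_sent - first_sent + 1L > 3L]
  if (length(orphan))
    warning("note ", note$id, ": entity spans wider than the passage window, ",
            "skipped: ", paste(orphan, collapse = ", "))
  n <- nrow(ents)
  rows <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    labels <- schema_labels(schema, ents$cls[i], ents$cls[j])
    if (is.null(labels)) next
    # passage starts p with p <= min(first sentences) and p + 3 > max(last)
    lo <- min(first_sent[i], first_sent[j])
    hi <- max(last_sent[i], last_sent[j])
    p_min <- max(0L, hi - 2L)
    p_max <- min(lo, max(0L, S - 3L))
    if (p_min > p_max) next
    ks <- (p_min:p_max) + 1L  # row indices into `passages`
    span_lo <- ents$token_start[i]; span_hi <- ents$token_end[j]
    margin <- pmin(span_lo - passages$token_start[ks],
                   passages$token_end[ks] - span_hi)
    k <- ks[which.max(margin)]  # which.max takes the earliest on ties
    gold <- "NoRelation"
    if (nrow(relations)) {
      hit <- (relations$arg1 == ents$id[i] & relations$arg2 == ents$id[j]) |
        (relations$arg1 == ents$id[j] & relations$arg2 == ents$id[i])
      if (any(hit)) gold <- relations$label[which(hit)[1L]]
    }
    rows[[length(rows) + 1L]] <- data.frame(
      note_id = note$id, e1 = ents$id[i], e2 = ents$id[j],
      cls1 = ents$cls[i], cls2 = ents$cls[j], passage = k,
      gold_label = gold,
      text = render_pair_input(note, passages[k, ],
                               ents[i, ], ents[j, ]),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(out)
  cand <- do.call(rbind, rows)
  # schema closure is asserted on every run
  ok <- vapply(seq_len(nrow(cand)), function(r)
    cand$gold_label[r] %in% schema_labels(schema, cand$cls1[r], cand$cls2[r]),
    logical(1))
  if (!all(ok)) stop("candidate with non-permissible gold label (schema breach)")
  cand
}

#' Generate candidates for a list of notes
#'
#' @param notes List of [ade_note()] objects.
#' @inheritParams generate_candidates
#' @return Row-bound candidate data frame.
#' @export
corpus_candidates <- function(notes, schema = relation_schema()) {
  do.call(rbind, lapply(notes, generate_candidates, schema = schema))
}

# feature bag for one candidate: the (known) entity type pair, the tokens
# between the two markers, and a bucketed pair distance. Word identity of
# the entity mentions themselves is deliberately not a feature -- the label
# depends on the type pair and the intervening context, and mention
# memorization would not transfer to unseen mentions.
candidate_features <- function(cand_row) {
  toks <- strsplit(cand_row$text, " ", fixed = TRUE)[[1L]]
  m1e <- which(toks == "[/E1]")
  m2 <- which(toks == "[E2]")
  mid <- if (m2 > m1e + 1L) toks[(m1e + 1L):(m2 - 1L)] else character(0)
  c(paste0("T1:", cand_row$cls1), paste0("T2:", cand_row$cls2),
    if (length(mid)) paste0("MID:", utils::head(mid, 40L)),
    paste0("DIST:", min(length(mid) %/% 5L, 5L)))
}

candidates_features <- function(cands) {
  lapply(seq_len(nrow(cands)), function(r) candidate_features(cands[r, ]))
}

#' Training configuration for the relation classifier
#'
#' Defaults are the selected fine-tuning hyperparameters: batch size 32, up
#' to 50 epochs with early-stopping patience of 3 epochs, Adam with
#' learning rate 2.575e-5, cross-entropy loss, weight decay 1e-4, and a
#' 512-token maximum input length. As with [ner_config()], the lightweight
#' default encoder is usually trained with a larger learning rate at desk
#' scale.
#'
#' @param batch_size,epochs,patience_epochs,learning_rate,weight_decay,
#'   dropout,grad_clip,dim,seed Encoder settings; see [encoder_opts()].
#' @param max_input_tokens Maximum rendered passage length.
#' @return List of class `re_config`.
#' @export
re_config <- function(batch_size = 32L, epochs = 50L, patience_epochs = 3L,
                      learning_rate = 2.575e-5, weight_decay = 1e-4,
                      dropout = 0, grad_clip = 1.0, dim = 24L,
                      max_input_tokens = 512L, seed = 1L) {
  stopifnot(patience_epochs >= 1L, patience_epochs <= epochs,
            max_input_tokens >= 16L)
  structure(list(max_input_tokens = as.integer(max_input_tokens),
                 patience_epochs = as.integer(patience_epochs),
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 dropout = dropout, grad_clip = grad_clip, dim = as.integer(dim),
                 seed = as.integer(seed)),
            class = "re_config")
}

#' Fine-tune the 5-class relation classifier
#'
#' Fits the encoder backend on candidate pairs under cross-entropy loss,
#' with early stopping (patience in epochs) on validation loss, and returns
#' the best-on-validation model.
#'
#' @param candidates,val_candidates Candidate data frames from
#'   [generate_candidates()] with `gold_label` filled.
#' @param config A [re_config()].
#' @return Object of class `re_model`.
#' @export
train_re <- function(candidates, val_candidates, config = re_config()) {
  if (is.null(candidates) || !nrow(candidates)) stop("empty candidate set")
  if (length(unique(candidates$gold_label)) < 2L)
    stop("training data contains a single label; need >= 2 classes")
  steps_per_epoch <- max(1L, ceiling(nrow(candidates) / config$batch_size))
  opts <- encoder_opts(dim = config$dim, batch_size = config$batch_size,
                       learning_rate = config$learning_rate,
                       epochs = config$epochs,
                       patience_steps = config$patience_epochs * steps_per_epoch,
                       dropout = config$dropout,
                       weight_decay = config$weight_decay,
                       grad_clip = config$grad_clip, seed = config$seed)
  net <- train_softmax_net(candidates_features(candidates),
                           candidates$gold_label,
                           candidates_features(val_candidates),
                           val_candidates$gold_label,
                           classes = relation_classes(), opts = opts)
  structure(list(net = net, config = config), class = "re_model")
}

#' @export
print.re_model <- function(x, ...) {
  cat(sprintf("<re_model> %d features, best val loss %.4f\n",
              length(x$net$vocab), x$net$best_val_loss))
  invisible(x)
}

#' Classify candidate pairs
#'
#' @param model A fitted `re_model`.
#' @param candidates Candidate data frame.
#' @return List with `labels` (argmax relation class per candidate) and
#'   `scores` (matrix of normalized class probabilities).
#' @export
classify_pairs <- function(model, candidates) {
  if (is.null(candidates) || !nrow(candidates))
    return(list(labels = character(0),
                scores = matrix(0, 0L, 5L,
                                dimnames = list(NULL, relation_classes()))))
  scores <- predict_softmax_net(model$net, candidates_features(candidates))
  list(labels = colnames(scores)[max.col(scores, ties.method = "first")],
       scores = scores)
}

#' @export
#' @method predict re_model
predict.re_model <- function(object, candidates, ...) {
  classify_pairs(object, candidates)$labels
}

#' @rdname save_ner_model
#' @export
save_re_model <- function(model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(unclass(model$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE)
  save_softmax_net(model$net, file.path(dir, "weights.json"))
  invisible(dir)
}

#' @rdname save_ner_model
#' @export
load_re_model <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  structure(list(net = load_softmax_net(file.path(dir, "weights.json")),
                 config = do.call(re_config, as.list(cfg))),
            class = "re_model")
}

#' Serialize candidates as line-delimited JSON
#'
#' @param candidates Candidate data frame.
#' @param path Output path.
#' @export
write_candidates <- function(candidates, path) {
  lines <- vapply(seq_len(nrow(candidates)), function(r)
    as.character(jsonlite::toJSON(as.list(candidates[r, ]), auto_unbox = TRUE)),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
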