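# End-to-end stacking of the fitted NER and RE models, the rule-based
# note-level ADE decision, and grid search over training configurations.
#
# Error propagation is inherent to the stack: entities the NER stage misses
# or mistypes never reach candidate generation, so the relations they carry
# cannot be recovered downstream.

#' Note-level ADE decision rule configuration
#'
#' A note is labeled as containing an ADE when at least one extracted
#' relation belongs to the ADE-indicating set. The default set is
#' `{ADE, AdeCause, AdeOutcome}` -- the incomplete-information classes
#' AdeCause and AdeOutcome still indicate the presence of an adverse event
#' -- but the set is configurable (e.g. `"ADE"` alone).
#'
#' @param ade_indicating_labels Non-empty subset of the primary relation
#'   classes.
#' @return List of class `ade_rule`.
#' @export
ade_rule <- function(ade_indicating_labels = c("ADE", "AdeCause", "AdeOutcome")) {
  if (!length(ade_indicating_labels))
    stop("the ADE-indicating label set must be non-empty")
  bad <- setdiff(ade_indicating_labels, primary_relation_classes())
  if (length(bad))
    stop("not a primary relation class: ", paste(bad, collapse = ", "))
  structure(list(ade_indicating_labels = ade_indicating_labels),
            class = "ade_rule")
}

#' Rule-based note-level ADE decision
#'
#' @param relations A relation data frame (column `label`) or a character
#'   vector of relation labels.
#' @param rule An [ade_rule()].
#' @return `TRUE` iff at least one relation label is in the ADE-indicating
#'   set. Monotone: adding relations can never flip `TRUE` to `FALSE`.
#' @export
detect_note_ade <- function(relations, rule = ade_rule()) {
  labels <- if (is.data.frame(relations)) relations$label else relations
  any(labels %in% rule$ade_indicating_labels)
}

# assign directed arguments to a predicted pair from its label semantics
orient_candidates <- function(cands, labels) {
  out <- empty_relations()
  for (r in seq_len(nrow(cands))) {
    if (labels[r] == "NoRelation") next
    args <- orient_relation(labels[r], cands$e1[r], cands$cls1[r],
                            cands$e2[r], cands$cls2[r])
    out <- rbind(out, data.frame(label = labels[r], arg1 = args[1L],
                                 arg2 = args[2L], stringsAsFactors = FALSE))
  }
  out
}

#' Run the stacked NER-RE pipeline on one note
#'
#' Predicts BIO tags, reconstructs entities, generates schema-permissible
#' candidate pairs from the predicted entities, classifies them, discards
#' `NoRelation` predictions, orients the surviving relations by their label
#' semantics, and applies the note-level ADE rule.
#'
#' @param ner_model A fitted `ner_model`.
#' @param re_model A fitted `re_model`.
#' @param note An [ade_note()]; its gold annotations (if any) are ignored.
#' @param schema A [relation_schema()].
#' @param rule An [ade_rule()].
#' @param entities Optional entity data frame to inject in place of the NER
#'   output (e.g. gold entities, to measure the RE stage in isolation).
#' @return List of class `ade_prediction`: `note_id`, `entities`,
#'   `relations` (primary classes only), `note_ade_flag`.
#' @export
run_end_to_end <- function(ner_model, re_model, note,
                           schema = relation_schema(), rule = ade_rule(),
                           entities = NULL) {
  if (is.null(entities)) {
    tags <- predict_note_tags(ner_model, note)
    entities <- bio_to_entities(tags)
  }
  cands <- generate_candidates(note, schema, entities = entities,
                               relations = empty_relations())
  labels <- if (nrow(cands)) classify_pairs(re_model, cands)$labels
            else character(0)
  relations <- orient_candidates(cands, labels)
  structure(list(note_id = note$id, entities = entities,
                 relations = relations,
                 note_ade_flag = detect_note_ade(relations, rule)),
            class = "ade_prediction")
}

#' @export
print.ade_prediction <- function(x, ...) {
  cat(sprintf("<ade_prediction %s> %d entities, %d relations, ADE: %s\n",
              x$note_id, nrow(x$entities), nrow(x$relations),
              x$note_ade_flag))
  invisible(x)
}

#' Run the pipeline over a corpus
#'
#' @param ner_model,re_model Fitted models.
#' @param notes List of [ade_note()] objects.
#' @inheritParams run_end_to_end
#' @return Named list of `ade_prediction` objects.
#' @export
predict_corpus <- function(ner_model, re_model, notes,
                           schema = relation_schema(), rule = ade_rule()) {
  preds <- lapply(notes, function(nt)
    run_end_to_end(ner_model, re_model, nt, schema, rule))
  names(preds) <- vapply(notes, `[[`, character(1), "id")
  preds
}

#' Grid search over training configurations
#'
#' Trains one model per grid point and selects the configuration with the
#' highest validation macro-F1 (token-level macro over the five entity
#' classes for `"ner"`; candidate-label macro over all relation classes for
#' `"re"`); ties go to the first grid entry. The full score table is
#' returned.
#'
#' @param config_grid Non-empty list of [ner_config()] or [re_config()]
#'   objects.
#' @param train,val For `task = "ner"`: lists of notes. For `task = "re"`:
#'   candidate data frames.
#' @param task `"ner"` or `"re"`.
#' @return List with `best_config`, `best_index`, `best_model`, `scores`
#'   (numeric vector of validation macro-F1 per grid point).
#' @export
grid_search <- function(config_grid, train, val, task = c("ner", "re")) {
  task <- match.arg(task)
  if (!length(config_grid)) stop("empty configuration grid")
  scores <- numeric(length(config_grid)); models <- vector("list", length(config_grid))
  for (i in seq_along(config_grid)) {
    if (task == "ner") {
      model <- train_ner(train, val, config_grid[[i]])
      gold <- lapply(val, function(nt) entities_to_bio(nt$entities, nrow(nt$tokens)))
      pred <- lapply(val, function(nt) predict_note_tags(model, nt))
      scores[i] <- score_ner(gold, pred)$macro[["f1"]]
    } else {
      model <- train_re(train, val, config_grid[[i]])
      pred <- classify_pairs(model, val)$labels
      scores[i] <- score_classification(val$gold_label, pred,
                                        classes = relation_classes())$macro[["f1"]]
    }
    models[[i]] <- model
  }
  best <- which.max(scores)  # first on ties
  list(best_config = config_grid[[best]], best_index = best,
       best_model = models[[best]], scores = scores)
}
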