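# Evaluation: per-class and micro/macro precision, recall, F1, F2; strict
# vs relaxed span matching; note-level scoring; confusion matrices and
# term-level error analysis.

#' F-beta score
#'
#' `(1 + beta^2) * P * R / (beta^2 * P + R)`, with the convention that the
#' score is 0 when both precision and recall are 0. Vectorized.
#'
#' @param precision,recall Values in `[0, 1]`.
#' @param beta Positive weight on recall (1 = F1, 2 = F2).
#' @return F-beta score(s) in `[0, 1]`.
#' @export
fbeta <- function(precision, recall, beta = 1) {
  if (any(precision < 0 | precision > 1 | recall < 0 | recall > 1))
    stop("precision and recall must lie in [0, 1]")
  if (any(beta <= 0)) stop("beta must be positive")
  den <- beta^2 * precision + recall
  ifelse(den == 0, 0, (1 + beta^2) * precision * recall / den)
}

prf_row <- function(tp, fp, fn) {
  tp <- unname(tp); fp <- unname(fp); fn <- unname(fn)
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  c(precision = p, recall = r,
    f1 = unname(fbeta(p, r, 1)), f2 = unname(fbeta(p, r, 2)))
}

# assemble an eval report from per-class TP/FP/FN counts
build_report <- function(counts, macro_classes = rownames(counts),
                         confusion = NULL) {
  per <- t(apply(counts, 1L, function(x) prf_row(x["tp"], x["fp"], x["fn"])))
  per_class <- data.frame(class = rownames(counts), per,
                          support = counts[, "tp"] + counts[, "fn"],
                          row.names = NULL, stringsAsFactors = FALSE)
  mc <- counts[macro_classes, , drop = FALSE]
  macro <- colMeans(t(apply(mc, 1L, function(x) prf_row(x["tp"], x["fp"], x["fn"]))))
  tot <- colSums(mc)
  micro <- prf_row(tot["tp"], tot["fp"], tot["fn"])
  structure(list(per_class = per_class, micro = micro, macro = macro,
                 confusion = confusion),
            class = "ade_eval_report")
}

#' @export
print.ade_eval_report <- function(x, digits = 3, ...) {
  cat("Per-class metrics:\n")
  pc <- x$per_class
  pc[2:5] <- lapply(pc[2:5], round, digits)
  print(pc, row.names = FALSE)
  cat(sprintf("micro: P %.3f R %.3f F1 %.3f F2 %.3f\n",
              x$micro["precision"], x$micro["recall"], x$micro["f1"], x$micro["f2"]))
  cat(sprintf("macro: P %.3f R %.3f F1 %.3f F2 %.3f\n",
              x$macro["precision"], x$macro["recall"], x$macro["f1"], x$macro["f2"]))
  invisible(x)
}

#' Token-level NER report over merged BIO categories
#'
#' Tags are collapsed to their entity category (`B-X`/`I-X` both count as
#' `X`; `O` counts as `Other`). Per-class precision/recall/F1/F2 are
#' computed for the five entity classes, the macro average runs over those
#' five classes (excluding `Other`), and the micro average pools their
#' counts. The confusion matrix includes `Other`.
#'
#' @param gold_tags,pred_tags Lists of per-note BIO tag vectors (or single
#'   vectors); per-note lengths must agree.
#' @return An `ade_eval_report`.
#' @export
score_ner <- function(gold_tags, pred_tags) {
  if (!is.list(gold_tags)) gold_tags <- list(gold_tags)
  if (!is.list(pred_tags)) pred_tags <- list(pred_tags)
  if (length(gold_tags) != length(pred_tags) ||
        any(lengths(gold_tags) != lengths(pred_tags)))
    stop("gold and predicted tag sequences must align in length")
  g <- tag_class(unlist(gold_tags, use.names = FALSE))
  p <- tag_class(unlist(pred_tags, use.names = FALSE))
  cats <- c(entity_classes(), "Other")
  conf <- table(factor(g, cats), factor(p, cats))
  cls <- entity_classes()
  counts <- t(vapply(cls, function(k) {
    c(tp = sum(g == k & p == k), fp = sum(p == k & g != k),
      fn = sum(g == k & p != k))
  }, numeric(3)))
  build_report(counts, macro_classes = cls, confusion = unclass(conf))
}

#' Flat multi-class classification report
#'
#' Per-class precision/recall/F1/F2 with micro and macro aggregates and a
#' confusion matrix, for aligned gold/predicted label vectors (e.g. relation
#' candidates classified against their gold labels).
#'
#' @param gold,pred Character vectors of equal length.
#' @param classes Class set; defaults to the union of observed labels.
#' @param macro_classes Classes included in the macro/micro aggregates.
#' @return An `ade_eval_report`.
#' @export
score_classification <- function(gold, pred, classes = sort(unique(c(gold, pred))),
                                 macro_classes = classes) {
  stopifnot(length(gold) == length(pred))
  conf <- table(factor(gold, classes), factor(pred, classes))
  counts <- t(vapply(classes, function(k) {
    c(tp = sum(gold == k & pred == k), fp = sum(pred == k & gold != k),
      fn = sum(gold == k & pred != k))
  }, numeric(3)))
  build_report(counts, macro_classes = macro_classes, confusion = unclass(conf))
}

overlap_len <- function(s1, e1, s2, e2) pmax(0L, pmin(e1, e2) - pmax(s1, s2))

#' Match predicted entities against gold entities
#'
#' Strict mode matches a prediction to a gold entity only when class and
#' token range are identical; relaxed mode requires the same class and at
#' least one shared token. Matching is one-to-one and greedy: candidate
#' pairs are taken in order of decreasing token overlap, ties broken by
#' earliest gold then earliest predicted position.
#'
#' @param gold,pred Entity data frames (`id`, `cls`, `token_start`,
#'   `token_end`) from the same note.
#' @param mode `"strict"` or `"relaxed"`.
#' @return List with `pairs` (data frame `gold_id`, `pred_id`, `overlap`),
#'   `unmatched_gold`, `unmatched_pred` (id vectors).
#' @export
match_entities <- function(gold, pred, mode = c("strict", "relaxed")) {
  mode <- match.arg(mode)
  cand <- expand.grid(g = seq_len(nrow(gold)), p = seq_len(nrow(pred)))
  if (nrow(cand)) {
    same_cls <- gold$cls[cand$g] == pred$cls[cand$p]
    ov <- overlap_len(gold$token_start[cand$g], gold$token_end[cand$g],
                      pred$token_start[cand$p], pred$token_end[cand$p])
    keep <- if (mode == "strict") {
      same_cls & gold$token_start[cand$g] == pred$token_start[cand$p] &
        gold$token_end[cand$g] == pred$token_end[cand$p]
    } else same_cls & ov > 0L
    cand <- cand[keep, , drop = FALSE]
    ov <- ov[keep]
    o <- order(-ov, gold$token_start[cand$g], pred$token_start[cand$p])
    cand <- cand[o, , drop = FALSE]; ov <- ov[o]
  } else ov <- integer(0)
  g_used <- logical(nrow(gold)); p_used <- logical(nrow(pred))
  pairs <- data.frame(gold_id = character(), pred_id = character(),
                      overlap = integer(), stringsAsFactors = FALSE)
  for (r in seq_len(nrow(cand))) {
    gi <- cand$g[r]; pi <- cand$p[r]
    if (g_used[gi] || p_used[pi]) next
    g_used[gi] <- TRUE; p_used[pi] <- TRUE
    pairs <- rbind(pairs, data.frame(gold_id = gold$id[gi], pred_id = pred$id[pi],
                                     overlap = ov[r], stringsAsFactors = FALSE))
  }
  list(pairs = pairs,
       unmatched_gold = gold$id[!g_used],
       unmatched_pred = pred$id[!p_used])
}

#' Entity-level NER report under a match mode
#'
#' Complements the token-level [score_ner()]: entities are matched per note
#' with [match_entities()] and per-class precision/recall/F1/F2 computed
#' over entity instances.
#'
#' @param gold_notes List of per-note gold entity data frames.
#' @param pred_notes List of per-note predicted entity data frames (same
#'   order).
#' @param mode `"strict"` or `"relaxed"`.
#' @return An `ade_eval_report` (no confusion matrix).
#' @export
score_entities <- function(gold_notes, pred_notes, mode = c("strict", "relaxed")) {
  mode <- match.arg(mode)
  stopifnot(length(gold_notes) == length(pred_notes))
  cls <- entity_classes()
  counts <- matrix(0, length(cls), 3L,
                   dimnames = list(cls, c("tp", "fp", "fn")))
  for (i in seq_along(gold_notes)) {
    g <- gold_notes[[i]]; p <- pred_notes[[i]]
    m <- match_entities(g, p, mode)
    for (k in cls) {
      tp <- sum(g$cls[match(m$pairs$gold_id, g$id)] == k)
      counts[k, "tp"] <- counts[k, "tp"] + tp
      counts[k, "fp"] <- counts[k, "fp"] + sum(p$cls == k) - tp
      counts[k, "fn"] <- counts[k, "fn"] + sum(g$cls == k) - tp
    }
  }
  build_report(counts, macro_classes = cls)
}

#' Relation report under strict/relaxed entity matching
#'
#' Entities are first matched per note under the given mode; a predicted
#' relation is a true positive iff a gold relation of the same label joins
#' the gold entities matched to the prediction's two arguments (direction
#' respected), each gold relation matching at most one prediction. Macro
#' averages are reported both over the four primary classes
#' (`macro`) and over all classes including `NoRelation` (`macro_all`);
#' the confusion matrix aligns relation instances by their argument pairs,
#' with `None` rows/columns for unaligned instances.
#'
#' @param gold,pred Lists (same length, one element per note) of
#'   `list(entities = <data frame>, relations = <data frame>)`.
#' @param mode `"strict"` or `"relaxed"`.
#' @return An `ade_eval_report` with an extra `macro_all` element.
#' @export
score_relations <- function(gold, pred, mode = c("strict", "relaxed")) {
  mode <- match.arg(mode)
  stopifnot(length(gold) == length(pred))
  cls <- relation_classes()
  counts <- matrix(0, length(cls), 3L, dimnames = list(cls, c("tp", "fp", "fn")))
  conf_lv <- c(cls, "None")
  conf <- matrix(0L, length(conf_lv), length(conf_lv),
                 dimnames = list(conf_lv, conf_lv))
  for (i in seq_along(gold)) {
    g <- gold[[i]]; p <- pred[[i]]
    if (length(bad <- setdiff(c(g$relations$arg1, g$relations$arg2), g$entities$id)) ||
        length(bad2 <- setdiff(c(p$relations$arg1, p$relations$arg2), p$entities$id)))
      stop("relation with dangling entity argument")
    m <- match_entities(g$entities, p$entities, mode)
    to_gold <- stats::setNames(m$pairs$gold_id, m$pairs$pred_id)
    pr <- p$relations; gr <- g$relations
    mapped1 <- unname(to_gold[pr$arg1]); mapped2 <- unname(to_gold[pr$arg2])
    gold_used <- logical(nrow(gr))
    # label-sensitive TP/FP, one-to-one over gold relations
    for (r in seq_len(nrow(pr))) {
      hit <- which(!gold_used & gr$label == pr$label[r] &
                     gr$arg1 == mapped1[r] & gr$arg2 == mapped2[r])
      if (length(hit) && !is.na(mapped1[r]) && !is.na(mapped2[r])) {
        gold_used[hit[1L]] <- TRUE
        counts[pr$label[r], "tp"] <- counts[pr$label[r], "tp"] + 1
      } else {
        counts[pr$label[r], "fp"] <- counts[pr$label[r], "fp"] + 1
      }
    }
    for (lab in cls)
      counts[lab, "fn"] <- counts[lab, "fn"] + sum(gr$label == lab & !gold_used)
    # confusion: align instances by argument pair, label-blind
    gkey <- paste(gr$arg1, gr$arg2)
    pkey <- paste(mapped1, mapped2)
    hit <- match(pkey, gkey)
    for (r in seq_len(nrow(pr))) {
      glab <- if (!is.na(hit[r])) gr$label[hit[r]] else "None"
      conf[glab, pr$label[r]] <- conf[glab, pr$label[r]] + 1L
    }
    missed <- setdiff(seq_len(nrow(gr)), hit[!is.na(hit)])
    for (r in missed) conf[gr$label[r], "None"] <- conf[gr$label[r], "None"] + 1L
  }
  rep <- build_report(counts, macro_classes = primary_relation_classes(),
                      confusion = conf)
  # macro over all classes that occur (gold or predicted), incl. NoRelation
  # when the evaluation is candidate-level and NoRelation instances exist
  all_cls <- rownames(counts)[rowSums(counts) > 0 | rownames(counts) %in%
                                primary_relation_classes()]
  rep$macro_all <- colMeans(t(apply(counts[all_cls, , drop = FALSE], 1L,
                                    function(x) prf_row(x["tp"], x["fp"], x["fn"]))))
  rep
}

#' Note-level ADE classification report
#'
#' Binary report over the classes `ContainingADE` and `NoADE`, with a macro
#' average.
#'
#' @param gold_flags,pred_flags Named logical vectors over the same note
#'   ids.
#' @return An `ade_eval_report`.
#' @export
score_notes <- function(gold_flags, pred_flags) {
  if (is.null(names(gold_flags)) || is.null(names(pred_flags)) ||
        !setequal(names(gold_flags), names(pred_flags)))
    stop("gold and predicted flags must cover the same note ids")
  pred_flags <- pred_flags[names(gold_flags)]
  g <- ifelse(gold_flags, "ContainingADE", "NoADE")
  p <- ifelse(pred_flags, "ContainingADE", "NoADE")
  score_classification(g, p, classes = c("ContainingADE", "NoADE"))
}

#' Write an evaluation report to disk
#'
#' Emits the per-class table and aggregates as JSON and, when present, the
#' confusion matrix as CSV alongside it.
#'
#' @param report An `ade_eval_report`.
#' @param path Output path for the JSON report; the confusion matrix (if
#'   any) is written next to it with suffix `_confusion.csv`.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  obj <- list(per_class = report$per_class,
              micro = as.list(report$micro), macro = as.list(report$macro))
  if (!is.null(report$macro_all)) obj$macro_all <- as.list(report$macro_all)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(report$confusion)) {
    csv <- sub("\\.json$", "", path)
    utils::write.csv(as.data.frame.matrix(report$confusion),
                     paste0(csv, "_confusion.csv"))
  }
  invisible(path)
}

#' Confusion matrix with most frequently misclassified terms
#'
#' Collapses token-aligned gold and predicted tags to entity categories and
#' reports the 6x6 confusion matrix (five classes plus `Other`) together
#' with, for each off-diagonal cell, the `k` most frequent case-folded token
#' strings falling in that cell.
#'
#' @param gold_tags,pred_tags Lists of per-note BIO tag vectors.
#' @param tokens List of per-note token text vectors, aligned with the tags.
#' @param k Number of terms to report per cell.
#' @return List with `confusion` (matrix) and `terms` (data frame `gold`,
#'   `pred`, `term`, `count`).
#' @export
error_analysis <- function(gold_tags, pred_tags, tokens, k = 10L) {
  if (!is.list(gold_tags)) gold_tags <- list(gold_tags)
  if (!is.list(pred_tags)) pred_tags <- list(pred_tags)
  if (!is.list(tokens)) tokens <- list(tokens)
  g <- tag_class(unlist(gold_tags, use.names = FALSE))
  p <- tag_class(unlist(pred_tags, use.names = FALSE))
  w <- tolower(unlist(tokens, use.names = FALSE))
  stopifnot(length(g) == length(p), length(g) == length(w))
  cats <- c(entity_classes(), "Other")
  conf <- unclass(table(factor(g, cats), factor(p, cats)))
  terms <- list()
  for (gc in cats) for (pc in cats) {
    if (gc == pc) next
    sel <- g == gc & p == pc
    if (!any(sel)) next
    tab <- sort(table(w[sel]), decreasing = TRUE)
    top <- utils::head(tab, k)
    terms[[length(terms) + 1L]] <- data.frame(
      gold = gc, pred = pc, term = names(top), count = as.integer(top),
      stringsAsFactors = FALSE)
  }
  list(confusion = conf,
       terms = if (length(terms)) do.call(rbind, terms)
               else data.frame(gold = character(), pred = character(),
                               term = character(), count = integer()))
}
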