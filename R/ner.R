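# Named entity recognition: token classification over the 11-tag BIO scheme
# with overlapping fixed-length windows, overlap-merged whole-note
# prediction, and BIO validity repair.

#' Training configuration for the NER model
#'
#' Defaults are the selected fine-tuning hyperparameters: batch size 128,
#' dropout 0.1, Adam with learning rate 5e-5, gradient accumulation 3,
#' gradient clipping 1.0, early stopping patience of 1600 steps, weight
#' decay 0.01, and 128-token windows with a 96-token stride. For the
#' lightweight default encoder trained from random initialization, a larger
#' learning rate and a desk-scale step budget are appropriate (see the
#' package vignette); the defaults here are the reference schedule.
#'
#' @param window Window length in tokens for note chunking.
#' @param stride Stride in tokens between consecutive window starts
#'   (0 < stride <= window).
#' @param batch_size,dropout,learning_rate,gradient_accumulation,grad_clip,
#'   patience_steps,weight_decay,epochs,eval_every,dim,seed Passed to the
#'   encoder backend; see [encoder_opts()].
#' @return List of class `ner_config`.
#' @export
ner_config <- function(window = 128L, stride = 96L, batch_size = 128L,
                       dropout = 0.1, learning_rate = 5e-5,
                       gradient_accumulation = 3L, grad_clip = 1.0,
                       patience_steps = 1600L, weight_decay = 0.01,
                       epochs = 10L, eval_every = NULL, dim = 24L, seed = 1L) {
  if (stride <= 0L || window < stride) stop("need 0 < stride <= window")
  structure(list(window = as.integer(window), stride = as.integer(stride),
                 opts = encoder_opts(dim = dim, batch_size = batch_size,
                                     learning_rate = learning_rate,
                                     epochs = epochs,
                                     patience_steps = patience_steps,
                                     eval_every = eval_every,
                                     dropout = dropout,
                                     weight_decay = weight_decay,
                                     grad_clip = grad_clip,
                                     gradient_accumulation = gradient_accumulation,
                                     seed = seed)),
            class = "ner_config")
}

#' Chunk a token sequence into overlapping windows
#'
#' Window starts are `0, stride, 2*stride, ...`; the last window is clipped
#' to the note length and generation stops at the first window whose end
#' reaches the note end, so the union of the half-open ranges covers
#' `[0, n_tokens)`.
#'
#' @param n_tokens Number of tokens (>= 1).
#' @param window Window length in tokens.
#' @param stride Stride between window starts.
#' @return Data frame with half-open 0-based columns `start`, `end`.
#' @export
chunk_tokens <- function(n_tokens, window = 128L, stride = 96L) {
  if (stride <= 0L || window < stride) stop("need 0 < stride <= window")
  stopifnot(n_tokens >= 1L)
  starts <- integer(0); s <- 0L
  repeat {
    starts <- c(starts, s)
    if (s + window >= n_tokens) break
    s <- s + stride
  }
  data.frame(start = starts, end = pmin(starts + window, n_tokens))
}

# context-window features for one chunk: word identity at relative offsets
# -2..2, with sentinel padding at chunk boundaries (tokens see only their
# own chunk, so boundary tokens genuinely lack context)
ner_chunk_features <- function(words) {
  n <- length(words)
  pad <- function(off) {
    w <- rep("<pad>", n)
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    w[ok] <- words[src[ok]]
    paste0(off, ":", w)
  }
  cols <- lapply(c(-2L, -1L, 0L, 1L, 2L), pad)
  lapply(seq_len(n), function(i) vapply(cols, `[[`, character(1), i))
}

ner_examples <- function(notes, config) {
  feats <- list(); labels <- character(0)
  for (note in notes) {
    words <- note$tokens$text
    tags <- entities_to_bio(note$entities, length(words))
    ch <- chunk_tokens(length(words), config$window, config$stride)
    for (k in seq_len(nrow(ch))) {
      idx <- (ch$start[k] + 1L):ch$end[k]
      feats <- c(feats, ner_chunk_features(words[idx]))
      labels <- c(labels, tags[idx])
    }
  }
  list(feats = feats, labels = labels)
}

#' Fine-tune the token classifier
#'
#' Builds overlapping window examples from the training notes, fits the
#' encoder backend with early stopping on validation loss, and returns the
#' best-on-validation model.
#'
#' @param train_notes,val_notes Lists of [ade_note()] objects with gold
#'   entities.
#' @param config A [ner_config()].
#' @return Object of class `ner_model`.
#' @export
train_ner <- function(train_notes, val_notes, config = ner_config()) {
  if (!length(train_notes)) stop("empty training set")
  tr <- ner_examples(train_notes, config)
  va <- ner_examples(val_notes, config)
  net <- train_softmax_net(tr$feats, tr$labels, va$feats, va$labels,
                           classes = bio_tags(), opts = config$opts)
  structure(list(net = net, config = config), class = "ner_model")
}

#' @export
print.ner_model <- function(x, ...) {
  cat(sprintf("<ner_model> %d features, best val loss %.4f\n",
              length(x$net$vocab), x$net$best_val_loss))
  invisible(x)
}

#' Repair a tag sequence into a valid BIO sequence
#'
#' A stray `I-X` with no valid predecessor (start of sequence, after `O`, or
#' after a different class) becomes `B-X`; everything else is unchanged.
#' Idempotent, and the identity on already-valid sequences.
#'
#' @param tags Character vector of BIO tags.
#' @return Valid BIO tag sequence of the same length.
#' @export
repair_bio <- function(tags) {
  check_tags(tags)
  if (!length(tags)) return(tags)
  cls <- tag_class(tags)
  for (i in seq_along(tags)) {
    if (startsWith(tags[i], "I-")) {
      ok <- i > 1L && tags[i - 1L] != "O" && cls[i - 1L] == cls[i]
      if (!ok) tags[i] <- sub("^I-", "B-", tags[i])
    }
  }
  tags
}

# merge rule for tokens covered by several chunks: keep the chunk in which
# the token's minimum distance to a chunk boundary is largest; ties go to
# the earlier chunk (boundary tokens lack context)
merge_chunk_choice <- function(chunks, n_tokens) {
  choice <- integer(n_tokens); margin <- rep(-1L, n_tokens)
  for (k in seq_len(nrow(chunks))) {
    idx <- (chunks$start[k] + 1L):chunks$end[k]
    m <- pmin(idx - 1L - chunks$start[k], chunks$end[k] - idx)
    better <- m > margin[idx]
    choice[idx[better]] <- k
    margin[idx[better]] <- m[better]
  }
  choice
}

#' Predict BIO tags for a whole note
#'
#' The note is chunked with the configured window/stride, each chunk is
#' tagged by the encoder, overlapping chunk predictions are merged (each
#' token keeps the prediction of the chunk where it sits deepest from a
#' boundary), and the merged sequence is repaired to BIO validity.
#'
#' @param model A fitted `ner_model`.
#' @param note An [ade_note()] (annotations, if any, are ignored).
#' @return Character vector of valid BIO tags, one per token.
#' @export
predict_note_tags <- function(model, note) {
  words <- note$tokens$text
  n <- length(words)
  ch <- chunk_tokens(n, model$config$window, model$config$stride)
  choice <- merge_chunk_choice(ch, n)
  tags <- character(n)
  for (k in seq_len(nrow(ch))) {
    keep <- which(choice == k)
    if (!length(keep)) next
    idx <- (ch$start[k] + 1L):ch$end[k]
    probs <- predict_softmax_net(model$net, ner_chunk_features(words[idx]))
    pred <- model$net$classes[max.col(probs, ties.method = "first")]
    tags[keep] <- pred[match(keep, idx)]
  }
  repair_bio(tags)
}

#' @export
#' @method predict ner_model
predict.ner_model <- function(object, note, type = c("tags", "entities"), ...) {
  type <- match.arg(type)
  tags <- predict_note_tags(object, note)
  if (type == "tags") tags else bio_to_entities(tags)
}

#' Save / load a fitted NER model under a run directory
#'
#' The configuration, feature vocabulary and weights are serialized as JSON
#' and the training log as line-delimited JSON, so a run directory is plain
#' text.
#'
#' @param model A `ner_model`.
#' @param dir Run directory.
#' @export
save_ner_model <- function(model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- list(window = model$config$window, stride = model$config$stride,
              opts = unclass(model$config$opts))
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE)
  save_softmax_net(model$net, file.path(dir, "weights.json"))
  if (!is.null(model$net$log) && nrow(model$net$log))
    writeLines(vapply(seq_len(nrow(model$net$log)), function(i)
      jsonlite::toJSON(as.list(model$net$log[i, ]), auto_unbox = TRUE),
      character(1)), file.path(dir, "train_log.ndjson"))
  invisible(dir)
}

#' @rdname save_ner_model
#' @export
load_ner_model <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  config <- do.call(ner_config, c(list(window = cfg$window, stride = cfg$stride),
                                  as.list(cfg$opts)[c("dim", "batch_size",
                                                      "learning_rate", "epochs",
                                                      "patience_steps", "dropout",
                                                      "weight_decay", "grad_clip",
                                                      "gradient_accumulation",
                                                      "seed")]))
  structure(list(net = load_softmax_net(file.path(dir, "weights.json")),
                 config = config), class = "ner_model")
}
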