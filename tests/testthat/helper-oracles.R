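# Independent brute-force oracles, kept deliberately naive.

# enumerate every valid BIO sequence up to max_len over the 11-tag alphabet
enumerate_valid_bio <- function(max_len) {
  tags <- bio_tags()
  succ <- function(tag) {
    if (tag == "O") tags[!startsWith(tags, "I-")]
    else c("O", tags[startsWith(tags, "B-")],
           sub("^B-", "I-", if (startsWith(tag, "B-")) tag
               else sub("^I-", "B-", tag)))
  }
  out <- list()
  grow <- function(prefix) {
    if (length(prefix)) out[[length(out) + 1L]] <<- prefix
    if (length(prefix) == max_len) return()
    nxt <- if (!length(prefix)) tags[!startsWith(tags, "I-")]
           else succ(prefix[length(prefix)])
    for (t in nxt) grow(c(prefix, t))
  }
  grow(character(0))
  out
}

# naive per-token counting report over merged categories
oracle_token_counts <- function(gold_cats, pred_cats, cls) {
  t(vapply(cls, function(k) c(
    tp = sum(gold_cats == k & pred_cats == k),
    fp = sum(pred_cats == k & gold_cats != k),
    fn = sum(gold_cats == k & pred_cats != k)), numeric(3)))
}

oracle_prf <- function(tp, fp, fn) {
  tp <- unname(tp); fp <- unname(fp); fn <- unname(fn)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  f2 <- if (4 * p + r > 0) 5 * p * r / (4 * p + r) else 0
  c(precision = p, recall = r, f1 = f1, f2 = f2)
}

# all-pairs candidate enumeration filtered by schema and passage
# co-occurrence, scanning passages explicitly
oracle_candidates <- function(note, schema = relation_schema()) {
  passages <- make_passages(note)
  ents <- note$entities[order(note$entities$token_start), , drop = FALSE]
  keys <- character(0); labs <- character(0)
  n <- nrow(ents)
  if (n >= 2L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    allowed <- schema[[paste(sort(c(ents$cls[i], ents$cls[j])), collapse = "|")]]
    if (is.null(allowed)) next
    together <- any(vapply(passages$entity_ids, function(ids)
      all(c(ents$id[i], ents$id[j]) %in% ids), logical(1)))
    if (!together) next
    gl <- "NoRelation"
    r <- note$relations
    hit <- (r$arg1 == ents$id[i] & r$arg2 == ents$id[j]) |
      (r$arg1 == ents$id[j] & r$arg2 == ents$id[i])
    if (any(hit)) gl <- r$label[which(hit)[1L]]
    keys <- c(keys, paste(ents$id[i], ents$id[j]))
    labs <- c(labs, gl)
  }
  data.frame(key = keys, gold_label = labs, stringsAsFactors = FALSE)
}

# exact maximum one-to-one entity matching by exhaustive assignment
oracle_match_size <- function(gold, pred, mode) {
  ok <- function(gi, pi) {
    if (gold$cls[gi] != pred$cls[pi]) return(FALSE)
    if (mode == "strict")
      return(gold$token_start[gi] == pred$token_start[pi] &&
               gold$token_end[gi] == pred$token_end[pi])
    min(gold$token_end[gi], pred$token_end[pi]) >
      max(gold$token_start[gi], pred$token_start[pi])
  }
  ng <- nrow(gold); np <- nrow(pred)
  best <- 0L
  recurse <- function(gi, used_p, size) {
    best <<- max(best, size)
    if (gi > ng) return()
    recurse(gi + 1L, used_p, size)  # leave gi unmatched
    for (pi in seq_len(np)) {
      if (!used_p[pi] && ok(gi, pi)) {
        used_p[pi] <- TRUE
        recurse(gi + 1L, used_p, size + 1L)
        used_p[pi] <- FALSE
      }
    }
  }
  recurse(1L, logical(np), 0L)
  best
}

# random non-overlapping entity set over n_tokens
random_entities <- function(n_tokens, n_ents, prefix = "E") {
  starts <- sort(sample(0:(n_tokens - 2L), n_ents))
  ends <- pmin(starts + sample(1:3, n_ents, replace = TRUE),
               c(starts[-1L], n_tokens))
  keep <- ends > starts
  data.frame(id = paste0(prefix, seq_len(sum(keep))),
             cls = sample(entity_classes(), sum(keep), replace = TRUE),
             token_start = starts[keep], token_end = ends[keep],
             stringsAsFactors = FALSE)
}

# perturb gold entities into a plausible prediction set: drop some, shift
# or truncate spans, flip some classes
perturb_entities <- function(ents, p_drop = 0.2, p_shift = 0.3, p_flip = 0.15) {
  keep <- stats::runif(nrow(ents)) > p_drop
  out <- ents[keep, , drop = FALSE]
  for (i in seq_len(nrow(out))) {
    if (stats::runif(1) < p_shift && out$token_end[i] - out$token_start[i] > 1L)
      out$token_end[i] <- out$token_end[i] - 1L
    if (stats::runif(1) < p_flip)
      out$cls[i] <- sample(setdiff(entity_classes(), out$cls[i]), 1L)
  }
  if (nrow(out)) out$id <- paste0("P", seq_len(nrow(out)))
  out
}
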