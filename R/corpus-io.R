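# Corpus I/O: CoNLL-BIO and brat standoff parsing/serialization, BIO <->
# entity-span conversion, deterministic corpus splitting.
#
# CoNLL dialect: two whitespace-separated columns (token, tag); a blank line
# marks a sentence boundary. brat standoff: T-lines carry typed character
# spans, R-lines typed binary relations between T ids.

#' Convert a BIO tag sequence to entity spans
#'
#' One entity is produced per maximal `B-X (I-X)*` run, with a half-open
#' token range. The input must be a valid BIO sequence: an `I-X` tag may only
#' follow a `B-X` or `I-X` of the same class (use [repair_bio()] to coerce
#' model output first).
#'
#' @param tags Character vector of BIO tags (see [bio_tags()]).
#' @return Data frame of entities with columns `id`, `cls`, `token_start`,
#'   `token_end`; ids are `T1`, `T2`, ... in document order.
#' @seealso [entities_to_bio()] for the exact inverse.
#' @export
bio_to_entities <- function(tags) {
  check_tags(tags)
  ents <- empty_entities()
  if (!length(tags)) return(ents)
  cls <- tag_class(tags)
  is_b <- startsWith(tags, "B-")
  is_i <- startsWith(tags, "I-")
  prev_cls <- c("Other", cls[-length(cls)])
  prev_ent <- c(FALSE, (is_b | is_i)[-length(tags)])
  bad <- which(is_i & !(prev_ent & prev_cls == cls))
  if (length(bad))
    stop("invalid BIO sequence: ", tags[bad[1L]], " at position ", bad[1L],
         " has no valid predecessor")
  starts <- which(is_b)
  if (!length(starts)) return(ents)
  ends <- vapply(starts, function(s) {
    e <- s
    while (e < length(tags) && is_i[e + 1L]) e <- e + 1L
    e
  }, integer(1))
  data.frame(id = paste0("T", seq_along(starts)),
             cls = cls[starts],
             token_start = starts - 1L, token_end = ends,
             stringsAsFactors = FALSE)
}

check_tags <- function(tags) {
  unknown <- setdiff(tags, bio_tags())
  if (length(unknown))
    stop("unknown BIO tag: ", paste(unique(unknown), collapse = ", "))
  invisible(tags)
}

#' Convert entity spans to a BIO tag sequence
#'
#' Exact inverse of [bio_to_entities()] on valid input: each entity becomes a
#' `B-X` tag followed by `I-X` tags over its half-open token range, all other
#' positions are `O`.
#'
#' @param entities Data frame with columns `cls`, `token_start`, `token_end`;
#'   ranges must be non-overlapping and lie within `[0, n_tokens)`.
#' @param n_tokens Length of the output tag sequence.
#' @return Character vector of `n_tokens` BIO tags.
#' @export
entities_to_bio <- function(entities, n_tokens) {
  tags <- rep("O", n_tokens)
  if (!nrow(entities)) return(tags)
  if (any(entities$token_start < 0L | entities$token_start >= entities$token_end |
            entities$token_end > n_tokens))
    stop("entity range out of [0, n_tokens)")
  o <- order(entities$token_start)
  if (nrow(entities) > 1L &&
        any(entities$token_end[o][-nrow(entities)] > entities$token_start[o][-1L]))
    stop("overlapping entities")
  for (i in seq_len(nrow(entities))) {
    s <- entities$token_start[i] + 1L; e <- entities$token_end[i]
    tags[s] <- tag_for("B", entities$cls[i])
    if (e > s) tags[(s + 1L):e] <- tag_for("I", entities$cls[i])
  }
  tags
}

#' Parse one note from CoNLL-BIO lines
#'
#' Each non-blank line holds a token and its BIO tag separated by whitespace;
#' blank lines delimit sentences. Gold entities are reconstructed from the
#' tag sequence; relations are not representable in this format and are left
#' empty. Token character offsets are synthesized by joining tokens with
#' single spaces.
#'
#' @param lines Character vector of file lines.
#' @param note_id Identifier for the resulting note.
#' @return An [ade_note()] with tokens, sentence ranges and gold entities.
#' @export
parse_conll_note <- function(lines, note_id) {
  blank <- !nzchar(trimws(lines))
  if (all(blank)) stop("empty CoNLL input for note ", note_id)
  toks <- character(0); tags <- character(0); sent_starts <- integer(0)
  at_boundary <- TRUE
  for (i in seq_along(lines)) {
    if (blank[i]) { at_boundary <- TRUE; next }
    parts <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
    if (length(parts) != 2L)
      stop("line ", i, ": expected 'token tag', got ", sQuote(lines[i]))
    if (!parts[2L] %in% bio_tags())
      stop("line ", i, ": unknown tag ", sQuote(parts[2L]))
    if (at_boundary) { sent_starts <- c(sent_starts, length(toks)); at_boundary <- FALSE }
    toks <- c(toks, parts[1L]); tags <- c(tags, parts[2L])
  }
  ade_note(note_id, toks, sentence_starts = sent_starts,
           entities = bio_to_entities(tags))
}

#' Serialize a note to CoNLL-BIO lines
#'
#' @param note An [ade_note()].
#' @return Character vector of lines (token + tag columns, blank line between
#'   sentences).
#' @export
write_conll <- function(note) {
  tags <- entities_to_bio(note$entities, nrow(note$tokens))
  out <- character(0)
  for (s in seq_len(nrow(note$sentences))) {
    idx <- (note$sentences$start[s] + 1L):note$sentences$end[s]
    out <- c(out, paste(note$tokens$text[idx], tags[idx]))
    if (s < nrow(note$sentences)) out <- c(out, "")
  }
  out
}

#' Parse brat standoff annotations onto a note
#'
#' T-lines (`T<id>\tClass start end\tsurface`) become entities whose token
#' range is the minimal token span covering the character span; R-lines
#' (`R<id>\tClass Arg1:T<i> Arg2:T<j>`) become directed relations.
#'
#' @param ann_lines Character vector of `.ann` file lines.
#' @param note An [ade_note()] providing text and tokenization (its existing
#'   entities/relations are replaced).
#' @return The note with entities and relations attached.
#' @export
parse_brat <- function(ann_lines, note) {
  ents <- empty_entities(); rels <- empty_relations()
  ann_lines <- ann_lines[nzchar(trimws(ann_lines))]
  for (ln in ann_lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    id <- fields[1L]
    if (startsWith(id, "T")) {
      spec <- strsplit(fields[2L], " ", fixed = TRUE)[[1L]]
      cls_ser <- spec[1L]
      if (!cls_ser %in% names(.cls_from_serial))
        stop("unknown entity class in brat line: ", sQuote(cls_ser))
      cs <- as.integer(spec[2L]); ce <- as.integer(spec[3L])
      cover <- which(note$tokens$char_start < ce & note$tokens$char_end > cs)
      if (!length(cover))
        stop("brat span [", cs, ",", ce, ") covers no token in note ", note$id)
      ents <- rbind(ents, data.frame(
        id = id, cls = .cls_from_serial[[cls_ser]],
        token_start = min(cover) - 1L, token_end = max(cover),
        stringsAsFactors = FALSE))
    } else if (startsWith(id, "R")) {
      spec <- strsplit(fields[2L], " ", fixed = TRUE)[[1L]]
      lab_ser <- spec[1L]
      if (!lab_ser %in% names(.rel_from_serial))
        stop("unknown relation class in brat line: ", sQuote(lab_ser))
      a1 <- sub("^Arg1:", "", spec[2L]); a2 <- sub("^Arg2:", "", spec[3L])
      rels <- rbind(rels, data.frame(
        label = .rel_from_serial[[lab_ser]], arg1 = a1, arg2 = a2,
        stringsAsFactors = FALSE))
    }
    # other brat line types (events, attributes, notes) are out of scope
  }
  dangling <- setdiff(c(rels$arg1, rels$arg2), ents$id)
  if (length(dangling))
    stop("relation references unknown entity id: ", paste(dangling, collapse = ", "))
  note$entities <- ents
  note$relations <- rels
  validate_note(note)
}

#' Serialize a note's annotations to brat standoff lines
#'
#' @param note An [ade_note()].
#' @return Character vector of T- and R-lines.
#' @export
write_brat <- function(note) {
  e <- note$entities
  t_lines <- vapply(seq_len(nrow(e)), function(i) {
    cs <- note$tokens$char_start[e$token_start[i] + 1L]
    ce <- note$tokens$char_end[e$token_end[i]]
    surface <- substring(note$text, cs + 1L, ce)
    sprintf("%s\t%s %d %d\t%s", e$id[i], .cls_serial[[e$cls[i]]], cs, ce, surface)
  }, character(1))
  r <- note$relations
  r_lines <- vapply(seq_len(nrow(r)), function(i) {
    sprintf("R%d\t%s Arg1:%s Arg2:%s", i, .rel_serial[[r$label[i]]],
            r$arg1[i], r$arg2[i])
  }, character(1))
  c(t_lines, r_lines)
}

#' Write a note as a txt/conll/ann file triple
#'
#' @param note An [ade_note()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the three file paths.
#' @export
write_note_files <- function(note, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- file.path(dir, note$id)
  paths <- paste0(base, c(".txt", ".conll", ".ann"))
  writeLines(note$text, paths[1L])
  writeLines(write_conll(note), paths[2L])
  writeLines(write_brat(note), paths[3L])
  invisible(paths)
}

#' Read a corpus directory of txt/conll/ann triples
#'
#' @param dir Directory holding `<id>.txt`, `<id>.conll`, `<id>.ann` triples
#'   as written by [write_corpus()].
#' @return Named list of [ade_note()] objects, ordered by note id.
#' @export
read_corpus <- function(dir) {
  conll_files <- sort(list.files(dir, pattern = "\\.conll$", full.names = TRUE))
  if (!length(conll_files)) stop("no .conll files found in ", dir)
  notes <- lapply(conll_files, function(f) {
    id <- sub("\\.conll$", "", basename(f))
    note <- parse_conll_note(readLines(f), id)
    txt <- file.path(dir, paste0(id, ".txt"))
    if (file.exists(txt)) {
      raw <- paste(readLines(txt), collapse = "\n")
      if (!identical(raw, note$text))
        stop("txt/conll tokenization mismatch for note ", id)
    }
    ann <- file.path(dir, paste0(id, ".ann"))
    if (file.exists(ann)) note <- parse_brat(readLines(ann), note)
    note
  })
  names(notes) <- vapply(notes, `[[`, character(1), "id")
  notes[order(names(notes))]
}

half_up <- function(x) as.integer(floor(x + 0.5))

#' Split note ids into train/validation/test partitions
#'
#' Sizes follow the 70/10/20 convention: the test partition gets
#' `round(r_test * N)` and the validation partition `round(r_val * N)` notes
#' (half-up rounding), the remainder goes to training. The assignment is a
#' seeded permutation, so the same seed always reproduces the same split.
#'
#' @param note_ids Character vector of note ids (>= 3).
#' @param ratios Train/validation/test proportions summing to 1.
#' @param seed Integer seed controlling the permutation.
#' @return A list of class `corpus_split` with elements `train`,
#'   `validation`, `test`.
#' @export
split_corpus <- function(note_ids, ratios = c(0.7, 0.1, 0.2), seed = 1L) {
  stopifnot(length(ratios) == 3L, abs(sum(ratios) - 1) < 1e-8)
  n <- length(note_ids)
  if (n < 3L) stop("need at least 3 notes to form three partitions")
  n_test <- half_up(ratios[3L] * n)
  n_val <- half_up(ratios[2L] * n)
  n_train <- n - n_test - n_val
  if (n_train < 1L || n_val < 1L || n_test < 1L)
    stop("too few notes for the requested ratios")
  perm <- with_seed(seed, sample(note_ids))
  structure(list(train = perm[seq_len(n_train)],
                 validation = perm[n_train + seq_len(n_val)],
                 test = perm[n_train + n_val + seq_len(n_test)]),
            class = "corpus_split")
}

#' @export
print.corpus_split <- function(x, ...) {
  cat(sprintf("<corpus_split> train %d / validation %d / test %d\n",
              length(x$train), length(x$validation), length(x$test)))
  invisible(x)
}

#' Write a split manifest as JSON
#'
#' @param split A `corpus_split`.
#' @param path Output path.
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(unclass(split), path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
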