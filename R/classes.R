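#' @keywords internal
"_PACKAGE"

# Closed label sets ----------------------------------------------------------

#' Entity, tag and relation label sets
#'
#' The annotation scheme covers five clinical entity classes (`Finding`,
#' `Drug`, `Disorder`, `BodyStructure`, `AdeCue`), the eleven BIO tags they
#' induce (`O` plus `B-`/`I-` per class), and four directed relation classes
#' plus the catch-all `NoRelation` used for permissible but unannotated
#' entity pairs.
#'
#' Class names containing spaces in prose ("Body Structure", "ADE Cue")
#' serialize in tags and standoff files with underscores
#' (`B-Body_Structure`, `ADE_Cue`) so that whitespace-delimited formats stay
#' parseable.
#'
#' @return Character vectors of labels, in canonical order.
#' @export
entity_classes <- function() c("Finding", "Drug", "Disorder", "BodyStructure", "AdeCue")

#' @rdname entity_classes
#' @export
relation_classes <- function() c("Indication", "ADE", "AdeOutcome", "AdeCause", "NoRelation")

#' @rdname entity_classes
#' @export
primary_relation_classes <- function() c("Indication", "ADE", "AdeOutcome", "AdeCause")

# serialized (file-format) names for entity classes
.cls_serial <- c(
  Finding = "Finding", Drug = "Drug", Disorder = "Disorder",
  BodyStructure = "Body_Structure", AdeCue = "ADE_Cue"
)
.cls_from_serial <- stats::setNames(names(.cls_serial), unname(.cls_serial))

.rel_serial <- c(
  Indication = "Indication", ADE = "ADE",
  AdeOutcome = "ADE_Outcome", AdeCause = "ADE_Cause", NoRelation = "No_Relation"
)
.rel_from_serial <- stats::setNames(names(.rel_serial), unname(.rel_serial))

#' @rdname entity_classes
#' @export
bio_tags <- function() {
  c("O", as.vector(rbind(paste0("B-", .cls_serial), paste0("I-", .cls_serial))))
}

# tag -> entity class ("Other" for O); vectorized
tag_class <- function(tags) {
  cls <- ifelse(tags == "O", "Other", .cls_from_serial[sub("^[BI]-", "", tags)])
  unname(cls)
}

tag_for <- function(prefix, cls) paste0(prefix, "-", .cls_serial[[cls]])

# Note container --------------------------------------------------------------

#' Construct a clinical note object
#'
#' A note bundles the raw text, its tokenization (with half-open character
#' offsets), sentence boundaries (half-open token ranges partitioning the
#' token sequence), gold entities (half-open token ranges, non-overlapping)
#' and gold relations (directed, resolving to entity ids).
#'
#' @param id Note identifier.
#' @param tokens Character vector of token strings.
#' @param sentence_starts Integer vector of 0-based token indices at which
#'   sentences start; must begin with 0.
#' @param entities Data frame with columns `id`, `cls`, `token_start`,
#'   `token_end` (0-based half-open token range).
#' @param relations Data frame with columns `label`, `arg1`, `arg2`
#'   (entity ids; `arg1` is the semantic source of the directed relation).
#' @param text Raw note text; if `NULL`, synthesized by joining tokens with
#'   single spaces.
#' @return An object of class `ade_note`.
#' @export
ade_note <- function(id, tokens, sentence_starts = 0L,
                     entities = empty_entities(), relations = empty_relations(),
                     text = NULL) {
  stopifnot(is.character(tokens), length(tokens) >= 1L)
  n <- length(tokens)
  if (is.null(text)) {
    text <- paste(tokens, collapse = " ")
    char_end <- cumsum(nchar(tokens) + 1L) - 1L
    char_start <- char_end - nchar(tokens)
  } else {
    # locate each token left-to-right in the provided text
    char_start <- integer(n); char_end <- integer(n)
    pos <- 1L
    for (i in seq_len(n)) {
      m <- regexpr(tokens[i], substring(text, pos), fixed = TRUE)
      if (m < 0L) stop("token ", sQuote(tokens[i]), " not found in note text")
      char_start[i] <- pos + m - 2L          # 0-based
      char_end[i] <- char_start[i] + attr(m, "match.length")
      pos <- char_end[i] + 1L
    }
  }
  sentence_starts <- as.integer(sentence_starts)
  if (length(sentence_starts) == 0L || sentence_starts[1L] != 0L)
    stop("sentence_starts must begin at token 0")
  sent <- data.frame(start = sentence_starts,
                     end = c(sentence_starts[-1L], n))
  note <- structure(list(
    id = as.character(id), text = text,
    tokens = data.frame(text = tokens, char_start = as.integer(char_start),
                        char_end = as.integer(char_end),
                        stringsAsFactors = FALSE),
    sentences = sent,
    entities = entities, relations = relations
  ), class = "ade_note")
  validate_note(note)
}

#' Empty entity / relation tables
#'
#' Zero-row data frames with the canonical entity and relation columns.
#' @return A zero-row data frame.
#' @export
empty_entities <- function() {
  data.frame(id = character(), cls = character(),
             token_start = integer(), token_end = integer(),
             stringsAsFactors = FALSE)
}

#' @rdname empty_entities
#' @export
empty_relations <- function() {
  data.frame(label = character(), arg1 = character(), arg2 = character(),
             stringsAsFactors = FALSE)
}

validate_note <- function(note) {
  n <- nrow(note$tokens)
  e <- note$entities
  if (nrow(e)) {
    if (any(!e$cls %in% entity_classes()))
      stop("unknown entity class: ", paste(setdiff(e$cls, entity_classes()), collapse = ", "))
    if (any(e$token_start < 0L | e$token_start >= e$token_end | e$token_end > n))
      stop("entity token range out of bounds in note ", note$id)
    # non-overlap check on token ranges
    if (nrow(e) > 1L) {
      o <- order(e$token_start)
      if (any(e$token_end[o][-nrow(e)] > e$token_start[o][-1L]))
        stop("overlapping entities in note ", note$id)
    }
    if (anyDuplicated(e$id)) stop("duplicate entity ids in note ", note$id)
  }
  r <- note$relations
  if (nrow(r)) {
    if (any(!r$label %in% relation_classes()))
      stop("unknown relation class: ", paste(setdiff(r$label, relation_classes()), collapse = ", "))
    bad <- !(r$arg1 %in% e$id) | !(r$arg2 %in% e$id)
    if (any(bad))
      stop("relation argument does not resolve to an entity in note ", note$id)
    if (any(r$arg1 == r$arg2)) stop("relation with identical arguments in note ", note$id)
  }
  s <- note$sentences
  if (s$start[1L] != 0L || s$end[nrow(s)] != n || any(s$start >= s$end))
    stop("sentence ranges must partition the token sequence in note ", note$id)
  note
}

#' @export
print.ade_note <- function(x, ...) {
  cat(sprintf("<ade_note %s> %d tokens, %d sentences, %d entities, %d relations\n",
              x$id, nrow(x$tokens), nrow(x$sentences),
              nrow(x$entities), nrow(x$relations)))
  invisible(x)
}

# RNG scoping: run code under a seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
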