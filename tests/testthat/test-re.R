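test_that("make_passages slides a 3-sentence window with stride 1", {
  toks <- rep(c("a", "b", "."), 5)
  nt <- ade_note("p", toks, sentence_starts = c(0L, 3L, 6L, 9L, 12L))
  p <- make_passages(nt)
  expect_equal(nrow(p), 3L)
  expect_equal(p$sent_start, 0:2)
  expect_equal(p$sent_end, 3:5)
  short <- ade_note("s", c("a", ".", "b", "."), sentence_starts = c(0L, 2L))
  ps <- make_passages(short)
  expect_equal(nrow(ps), 1L)
  expect_equal(ps$token_end, 4L)
})

test_that("every entity within 3 sentences lands in at least one passage", {
  corp <- fixture_corpus(20L, 5L)
  for (nt in corp) {
    p <- make_passages(nt)
    covered <- unique(unlist(p$entity_ids))
    expect_setequal(covered, nt$entities$id)
  }
})

test_that("candidate generation respects the permissible-relation schema", {
  # one sentence: Drug, Finding, BodyStructure; gold ADE(drug -> finding)
  nt <- ade_note("c1", c("x", "d1", "t", "f1", "b1", "."),
                 entities = data.frame(
                   id = c("T1", "T2", "T3"),
                   cls = c("Drug", "Finding", "BodyStructure"),
                   token_start = c(1L, 3L, 4L), token_end = c(2L, 4L, 5L),
                   stringsAsFactors = FALSE),
                 relations = data.frame(label = "ADE", arg1 = "T1", arg2 = "T2",
                                        stringsAsFactors = FALSE))
  cands <- generate_candidates(nt)
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$gold_label, "ADE")
  expect_setequal(c(cands$e1, cands$e2), c("T1", "T2"))

  # Drug + AdeCue + Finding co-occurring: three candidates, three label slots
  nt2 <- ade_note("c2", c("d1", "k1", "f1", "."),
                  entities = data.frame(
                    id = c("T1", "T2", "T3"),
                    cls = c("Drug", "AdeCue", "Finding"),
                    token_start = 0:2, token_end = 1:3,
                    stringsAsFactors = FALSE))
  c2 <- generate_candidates(nt2)
  expect_equal(nrow(c2), 3L)
  schema <- relation_schema()
  slots <- lapply(seq_len(3L), function(r)
    ademiner:::schema_labels(schema, c2$cls1[r], c2$cls2[r]))
  expect_setequal(vapply(slots, paste, character(1), collapse = "+"),
                  c("AdeCause+NoRelation", "AdeOutcome+NoRelation",
                    "Indication+ADE+NoRelation"))
  expect_true(all(c2$gold_label == "NoRelation"))
})

test_that("candidates equal the naive all-pairs oracle on synthetic notes", {
  corp <- fixture_corpus(20L, 5L)
  for (nt in corp) {
    got <- generate_candidates(nt)
    want <- oracle_candidates(nt)
    got_keys <- paste(got$e1, got$e2)
    expect_setequal(got_keys, want$key)
    expect_identical(got$gold_label[match(want$key, got_keys)],
                     want$gold_label)
  }
})

test_that("render_pair_input marks both entities exactly once and reversibly", {
  nt <- ade_note("r", c("Waran", "gav", "blödning", "."),
                 entities = data.frame(
                   id = c("T1", "T2"), cls = c("Drug", "Finding"),
                   token_start = c(0L, 2L), token_end = c(1L, 3L),
                   stringsAsFactors = FALSE))
  p <- make_passages(nt)
  txt <- render_pair_input(nt, p[1, ], nt$entities[1, ], nt$entities[2, ])
  expect_identical(txt, "[E1] Waran [/E1] gav [E2] blödning [/E2] .")
  for (m in c("[E1]", "[/E1]", "[E2]", "[/E2]")) {
    expect_equal(lengths(regmatches(txt, gregexpr(m, txt, fixed = TRUE))), 1L)
  }
  stripped <- gsub(" ?\\[/?E[12]\\] ?", " ", txt)
  stripped <- trimws(gsub(" +", " ", stripped))
  expect_identical(stripped, paste(nt$tokens$text, collapse = " "))
})

test_that("render_pair_input truncates symmetrically but keeps the pair", {
  words <- c(paste0("w", 1:40), "d1", "t", "f1", paste0("v", 1:40), ".")
  nt <- ade_note("long", words,
                 entities = data.frame(
                   id = c("T1", "T2"), cls = c("Drug", "Finding"),
                   token_start = c(40L, 42L), token_end = c(41L, 43L),
                   stringsAsFactors = FALSE))
  p <- make_passages(nt)
  txt <- render_pair_input(nt, p[1, ], nt$entities[1, ], nt$entities[2, ],
                           max_tokens = 20L)
  toks <- strsplit(txt, " ")[[1]]
  expect_lte(length(toks), 20L)
  expect_true(all(c("[E1]", "d1", "[/E1]", "t", "[E2]", "f1", "[/E2]") %in% toks))
})

test_that("train_re validates inputs", {
  fx <- fixture_models()
  cands <- corpus_candidates(fx$corpus[fx$split$validation])
  expect_error(train_re(cands[0, ], cands, desk_re_config()), "empty")
  mono <- cands[cands$gold_label == "NoRelation", ]
  expect_error(train_re(mono, cands, desk_re_config()), "single label")
})

test_that("the pair classifier overfits a small candidate set", {
  fx <- fixture_models()
  cands <- corpus_candidates(fx$corpus[fx$split$validation])
  sub <- cands[order(cands$gold_label != "NoRelation", decreasing = TRUE), ]
  sub <- sub[1:20, ]
  m <- train_re(sub, sub, desk_re_config(epochs = 200L))
  expect_identical(classify_pairs(m, sub)$labels, sub$gold_label)
})

test_that("training reduces validation loss below initialization", {
  fx <- fixture_models()
  log <- fx$re$net$log
  expect_lt(min(log$val_loss), log$val_loss[1L])
  expect_lt(fx$re$net$best_val_loss, log$val_loss[1L])
})

test_that("classify_pairs returns a normalized, deterministic simplex", {
  fx <- fixture_models()
  cands <- corpus_candidates(fx$corpus[fx$split$test[1:5]])
  out <- classify_pairs(fx$re, cands)
  expect_equal(rowSums(out$scores), rep(1, nrow(cands)), tolerance = 1e-9)
  expect_true(all(out$scores >= 0))
  expect_identical(out$labels,
                   colnames(out$scores)[max.col(out$scores, "first")])
  expect_identical(out, classify_pairs(fx$re, cands))
})

test_that("candidate sets serialize as line-delimited JSON", {
  fx <- fixture_models()
  cands <- corpus_candidates(fx$corpus[fx$split$test[1]])
  f <- withr::local_tempfile()
  write_candidates(cands, f)
  lines <- readLines(f)
  expect_length(lines, nrow(cands))
  row1 <- jsonlite::fromJSON(lines[1])
  expect_identical(row1$gold_label, cands$gold_label[1])
})
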