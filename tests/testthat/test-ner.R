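test_that("chunk_tokens follows the window/stride definition", {
  expect_equal(chunk_tokens(200L, 128L, 96L),
               data.frame(start = c(0L, 96L), end = c(128L, 200L)))
  expect_equal(chunk_tokens(100L, 128L, 96L),
               data.frame(start = 0L, end = 100L))
  expect_error(chunk_tokens(10L, 128L, 0L), "stride")
  expect_error(chunk_tokens(10L, 8L, 16L), "stride")
})

test_that("chunk coverage and overlap hold for random sizes", {
  set.seed(5)
  for (rep in 1:50) {
    w <- sample(4:40, 1L); s <- sample(seq_len(w), 1L); n <- sample(1:200, 1L)
    ch <- chunk_tokens(n, w, s)
    covered <- sort(unique(unlist(Map(function(a, b) (a + 1L):b, ch$start, ch$end))))
    expect_identical(covered, seq_len(n))
    if (nrow(ch) > 1L) {
      expect_true(all(diff(ch$start) == s))
      expect_true(all(ch$end[-nrow(ch)] < n))
    }
    expect_true(all(ch$end - ch$start <= w))
  }
})

test_that("repair_bio applies the stated repairs and is idempotent", {
  expect_equal(repair_bio(c("O", "I-Drug")), c("O", "B-Drug"))
  expect_equal(repair_bio(c("B-Drug", "I-Finding")), c("B-Drug", "B-Finding"))
  expect_equal(repair_bio(c("I-Disorder", "I-Disorder")),
               c("B-Disorder", "I-Disorder"))
  for (s in sample(enumerate_valid_bio(3L), 100L)) {
    expect_identical(repair_bio(s), s)  # valid sequences are untouched
  }
  set.seed(10)
  for (rep in 1:50) {
    raw <- sample(bio_tags(), 8L, replace = TRUE)
    fixed <- repair_bio(raw)
    expect_identical(repair_bio(fixed), fixed)
    expect_silent(bio_to_entities(fixed))
  }
})

test_that("train_ner validates input and reduces loss on separable data", {
  expect_error(train_ner(list(), list(), desk_ner_config()), "empty")
  corp <- fixture_corpus(20L, 17L)
  m <- train_ner(corp, corp, desk_ner_config(epochs = 15L))
  log <- m$net$log
  expect_true(nrow(log) >= 2L)
  expect_lt(log$val_loss[nrow(log)], log$val_loss[1L])
})

test_that("the encoder can overfit a handful of notes to perfect tagging", {
  corp <- fixture_corpus(20L, 17L)[1:5]
  m <- train_ner(corp, corp, desk_ner_config(epochs = 60L))
  for (nt in corp) {
    gold <- entities_to_bio(nt$entities, nrow(nt$tokens))
    expect_identical(predict_note_tags(m, nt), gold)
  }
})

test_that("predict_note_tags yields full-length valid BIO output", {
  fx <- fixture_models()
  nt <- fx$corpus[[fx$split$test[1L]]]
  tags <- predict_note_tags(fx$ner, nt)
  expect_length(tags, nrow(nt$tokens))
  expect_true(all(tags %in% bio_tags()))
  expect_silent(bio_to_entities(tags))
})

test_that("notes shorter than the window are unaffected by chunking", {
  fx <- fixture_models()
  short <- NULL
  for (nt in fx$corpus) if (nrow(nt$tokens) < 128L) { short <- nt; break }
  expect_false(is.null(short))
  m_nochunk <- fx$ner
  m_nochunk$config$window <- 10000L
  m_nochunk$config$stride <- 10000L
  expect_identical(predict_note_tags(fx$ner, short),
                   predict_note_tags(m_nochunk, short))
})

test_that("overlap merging keeps the deepest-context chunk's prediction", {
  fx <- fixture_models()
  long <- NULL
  for (nt in fx$corpus) if (nrow(nt$tokens) > 140L) { long <- nt; break }
  expect_false(is.null(long))
  n <- nrow(long$tokens)
  ch <- chunk_tokens(n, 128L, 96L)
  choice <- ademiner:::merge_chunk_choice(ch, n)
  # expected selection rule, recomputed naively per token
  for (tok in seq_len(n)) {
    margins <- rep(-1L, nrow(ch))
    for (k in seq_len(nrow(ch))) {
      if (tok > ch$start[k] && tok <= ch$end[k])
        margins[k] <- min(tok - 1L - ch$start[k], ch$end[k] - tok)
    }
    expect_equal(choice[tok], which.max(margins))
  }
  # the merged output equals the chosen chunks' raw predictions, repaired
  merged <- predict_note_tags(fx$ner, long)
  words <- long$tokens$text
  expected_raw <- character(n)
  for (k in unique(choice)) {
    idx <- (ch$start[k] + 1L):ch$end[k]
    probs <- ademiner:::predict_softmax_net(fx$ner$net,
                                            ademiner:::ner_chunk_features(words[idx]))
    raw <- fx$ner$net$classes[max.col(probs, ties.method = "first")]
    keep <- which(choice == k)
    expected_raw[keep] <- raw[match(keep, idx)]
  }
  expect_identical(merged, repair_bio(expected_raw))
})

test_that("NER models survive a save/load round trip", {
  fx <- fixture_models()
  d <- withr::local_tempdir()
  save_ner_model(fx$ner, d)
  back <- load_ner_model(d)
  nt <- fx$corpus[[fx$split$test[2L]]]
  expect_identical(predict_note_tags(back, nt), predict_note_tags(fx$ner, nt))
})
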