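test_that("parse_conll_note reconstructs tokens, sentences and entities", {
  nt <- parse_conll_note(c("Waran B-Drug", "", ""), "n1")
  expect_equal(nrow(nt$tokens), 1L)
  expect_equal(nt$entities$cls, "Drug")
  expect_equal(nt$entities$token_start, 0L)
  expect_equal(nt$entities$token_end, 1L)

  nt2 <- parse_conll_note(c("akut B-Disorder", "urtikaria I-Disorder"), "n2")
  expect_equal(nrow(nt2$entities), 1L)
  expect_equal(nt2$entities$cls, "Disorder")
  expect_equal(nt2$entities$token_end - nt2$entities$token_start, 2L)

  multi <- parse_conll_note(c("a O", "b O", "", "c B-Drug"), "n3")
  expect_equal(nrow(multi$sentences), 2L)
  expect_equal(multi$sentences$start, c(0L, 2L))
})

test_that("parse_conll_note rejects malformed input with line context", {
  expect_error(parse_conll_note(c("x B-Medicine"), "n"), "line 1.*B-Medicine")
  expect_error(parse_conll_note(c("ok O", "bad"), "n"), "line 2")
  expect_error(parse_conll_note(c("", ""), "n"), "empty")
})

test_that("bio_to_entities handles the scheme directly and rejects stray I tags", {
  e <- bio_to_entities(c("B-Drug", "I-Drug", "O", "B-Finding"))
  expect_equal(e$cls, c("Drug", "Finding"))
  expect_equal(e$token_start, c(0L, 3L))
  expect_equal(e$token_end, c(2L, 4L))
  expect_equal(nrow(bio_to_entities(c("O", "O"))), 0L)
  expect_error(bio_to_entities(c("O", "I-Drug")), "invalid BIO")
  expect_error(bio_to_entities(c("B-Drug", "I-Finding")), "invalid BIO")
  expect_error(bio_to_entities("B-Medicine"), "unknown")
})

test_that("entities_to_bio inverts bio_to_entities and rejects overlap", {
  ents <- data.frame(id = "T1", cls = "Drug", token_start = 0L, token_end = 2L)
  expect_equal(entities_to_bio(ents, 3L), c("B-Drug", "I-Drug", "O"))
  expect_equal(entities_to_bio(empty_ents <- ents[0, ], 2L), c("O", "O"))
  bad <- data.frame(id = c("a", "b"), cls = "Drug",
                    token_start = c(0L, 1L), token_end = c(2L, 3L))
  expect_error(entities_to_bio(bad, 4L), "overlap")
})

test_that("BIO conversion round-trips on randomized valid sequences", {
  set.seed(91)
  seqs <- enumerate_valid_bio(3L)
  for (s in sample(seqs, 200L)) {
    expect_identical(entities_to_bio(bio_to_entities(s), length(s)), s)
  }
})

test_that("parse_brat attaches standoff entities and relations", {
  base <- ade_note("b1", c("Waran", "gav", "blödning"))
  nt <- parse_brat(c("T1\tDrug 0 5\tWaran",
                     "T2\tFinding 10 18\tblödning",
                     "R1\tADE Arg1:T1 Arg2:T2"), base)
  expect_equal(nrow(nt$entities), 2L)
  expect_equal(nt$entities$token_start, c(0L, 2L))
  expect_equal(nt$relations$label, "ADE")
  expect_error(parse_brat(c("T1\tDrug 0 5\tWaran",
                            "R1\tADE Arg1:T1 Arg2:T9"), base),
               "unknown entity id")
  # char span crossing no token
  expect_error(parse_brat("T1\tDrug 100 104\tnope", base), "covers no token")
  # a span inside token 0 maps to the minimal covering token span
  nt2 <- parse_brat("T1\tDrug 0 3\tWar", base)
  expect_equal(nt2$entities$token_end, 1L)
})

test_that("CoNLL and brat writers round-trip generated notes bit-exactly", {
  corp <- fixture_corpus(20L, 5L)
  d <- withr::local_tempdir()
  for (nt in corp) write_note_files(nt, d)
  back <- read_corpus(d)
  expect_identical(names(back), names(corp))
  for (id in names(corp)) {
    expect_identical(back[[id]]$tokens, corp[[id]]$tokens)
    expect_identical(back[[id]]$sentences, corp[[id]]$sentences)
    a <- corp[[id]]$entities[order(corp[[id]]$entities$id), ]
    b <- back[[id]]$entities[order(back[[id]]$entities$id), ]
    rownames(a) <- rownames(b) <- NULL
    expect_identical(a, b)
    ra <- corp[[id]]$relations[order(corp[[id]]$relations$arg1,
                                     corp[[id]]$relations$arg2), ]
    rb <- back[[id]]$relations[order(back[[id]]$relations$arg1,
                                     back[[id]]$relations$arg2), ]
    rownames(ra) <- rownames(rb) <- NULL
    expect_identical(ra, rb)
  }
})

test_that("split_corpus applies the documented rounding and is seed-stable", {
  ids <- paste0("n", 1:395)
  sp <- split_corpus(ids, seed = 9)
  expect_equal(lengths(unclass(sp))[c("train", "validation", "test")],
               c(train = 276L, validation = 40L, test = 79L))
  sp10 <- split_corpus(paste0("n", 1:10), seed = 9)
  expect_equal(lengths(unclass(sp10)),
               c(train = 7L, validation = 1L, test = 2L))
  expect_identical(split_corpus(ids, seed = 4), split_corpus(ids, seed = 4))
  # partitions are disjoint and exhaustive
  all_ids <- c(sp$train, sp$validation, sp$test)
  expect_setequal(all_ids, ids)
  expect_equal(anyDuplicated(all_ids), 0L)
  expect_error(split_corpus(c("a", "b"), seed = 1), "at least 3")
})
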