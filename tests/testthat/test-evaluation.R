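test_that("fbeta matches its closed form and conventions", {
  expect_equal(fbeta(1, 1, 1), 1)
  expect_equal(fbeta(1, 1, 2), 1)
  expect_equal(fbeta(0, 0, 1), 0)
  expect_equal(fbeta(1.0, 0.5, 2), 5 * 0.5 / 4.5, tolerance = 1e-12)
  expect_error(fbeta(-0.1, 0.5), "\\[0, 1\\]")
  expect_error(fbeta(0.5, 1.2), "\\[0, 1\\]")
  expect_error(fbeta(0.5, 0.5, 0), "positive")
})

test_that("F2 sits above F1 iff recall exceeds precision", {
  grid <- expand.grid(p = seq(0.05, 1, by = 0.05), r = seq(0.05, 1, by = 0.05))
  f1 <- fbeta(grid$p, grid$r, 1)
  f2 <- fbeta(grid$p, grid$r, 2)
  expect_true(all(f2[grid$r > grid$p] > f1[grid$r > grid$p]))
  expect_true(all(f2[grid$r < grid$p] < f1[grid$r < grid$p]))
  expect_equal(f2[grid$r == grid$p], f1[grid$r == grid$p])
})

test_that("match_entities applies strict and relaxed semantics", {
  gold <- data.frame(id = "G1", cls = "Disorder", token_start = 5L,
                     token_end = 7L, stringsAsFactors = FALSE)
  pred <- data.frame(id = "P1", cls = "Disorder", token_start = 6L,
                     token_end = 7L, stringsAsFactors = FALSE)
  strict <- match_entities(gold, pred, "strict")
  expect_equal(nrow(strict$pairs), 0L)
  relaxed <- match_entities(gold, pred, "relaxed")
  expect_equal(nrow(relaxed$pairs), 1L)
  # class must agree in both modes
  pred2 <- transform(pred, cls = "Finding", token_start = 5L)
  expect_equal(nrow(match_entities(gold, pred2, "strict")$pairs), 0L)
  expect_equal(nrow(match_entities(gold, pred2, "relaxed")$pairs), 0L)
})

test_that("greedy matching equals exhaustive optimal assignment on small notes", {
  set.seed(77)
  for (rep in 1:40) {
    gold <- random_entities(30L, sample(2:5, 1L), "G")
    pred <- perturb_entities(gold)
    for (mode in c("strict", "relaxed")) {
      got <- match_entities(gold, pred, mode)
      expect_equal(nrow(got$pairs), oracle_match_size(gold, pred, mode))
      # one-to-one
      expect_equal(anyDuplicated(got$pairs$gold_id), 0L)
      expect_equal(anyDuplicated(got$pairs$pred_id), 0L)
    }
  }
})

test_that("score_ner matches a naive counting oracle on synthetic notes", {
  corp <- fixture_corpus(20L, 5L)
  gold <- lapply(corp, function(nt) entities_to_bio(nt$entities, nrow(nt$tokens)))
  set.seed(12)
  pred <- lapply(gold, function(g) {
    flip <- stats::runif(length(g)) < 0.2
    g[flip] <- sample(bio_tags(), sum(flip), replace = TRUE)
    g
  })
  rep_ <- score_ner(gold, pred)
  gc <- ademiner:::tag_class(unlist(gold))
  pc <- ademiner:::tag_class(unlist(pred))
  counts <- oracle_token_counts(gc, pc, entity_classes())
  for (k in entity_classes()) {
    want <- oracle_prf(counts[k, "tp"], counts[k, "fp"], counts[k, "fn"])
    row <- rep_$per_class[rep_$per_class$class == k, ]
    expect_equal(unlist(row[c("precision", "recall", "f1", "f2")]),
                 want, tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(row$support, sum(gc == k))
  }
  expect_equal(unname(rep_$macro["f1"]),
               mean(vapply(entity_classes(), function(k)
                 oracle_prf(counts[k, "tp"], counts[k, "fp"], counts[k, "fn"])[["f1"]],
                 numeric(1))), tolerance = 1e-12)
  tot <- colSums(counts)
  expect_equal(unname(rep_$micro["f1"]),
               oracle_prf(tot["tp"], tot["fp"], tot["fn"])[["f1"]],
               tolerance = 1e-12)
  # perfect and degenerate extremes
  expect_equal(unname(score_ner(gold, gold)$macro["f1"]), 1)
  allo <- lapply(gold, function(g) rep("O", length(g)))
  expect_equal(unname(score_ner(gold, allo)$macro["recall"]), 0)
  expect_error(score_ner(gold, gold[-1]), "align")
})

test_that("relation scoring distinguishes strict and relaxed modes", {
  gold <- list(list(
    entities = data.frame(id = c("G1", "G2"), cls = c("Drug", "Finding"),
                          token_start = c(0L, 3L), token_end = c(2L, 4L),
                          stringsAsFactors = FALSE),
    relations = data.frame(label = "ADE", arg1 = "G1", arg2 = "G2",
                           stringsAsFactors = FALSE)))
  # identical prediction: perfect in both modes
  perfect <- lapply(gold, function(x) x)
  for (mode in c("strict", "relaxed")) {
    rep_ <- score_relations(gold, perfect, mode)
    expect_equal(rep_$per_class$f1[rep_$per_class$class == "ADE"], 1)
  }
  # drug argument truncated by one token: strict FP+FN, relaxed TP
  trunc <- list(list(
    entities = data.frame(id = c("P1", "P2"), cls = c("Drug", "Finding"),
                          token_start = c(0L, 3L), token_end = c(1L, 4L),
                          stringsAsFactors = FALSE),
    relations = data.frame(label = "ADE", arg1 = "P1", arg2 = "P2",
                           stringsAsFactors = FALSE)))
  s <- score_relations(gold, trunc, "strict")$per_class
  expect_equal(s$f1[s$class == "ADE"], 0)
  r <- score_relations(gold, trunc, "relaxed")$per_class
  expect_equal(r$f1[r$class == "ADE"], 1)
  expect_error(score_relations(gold, list(list(
    entities = gold[[1]]$entities[1, ],
    relations = gold[[1]]$relations)), "strict"), "dangling")
})

test_that("score_notes reproduces direct counting", {
  ids <- paste0("n", 1:10)
  gold <- stats::setNames(rep(c(TRUE, FALSE), each = 5), ids)
  perfect <- score_notes(gold, gold)
  expect_equal(unname(perfect$macro["f1"]), 1)
  alltrue <- stats::setNames(rep(TRUE, 10), ids)
  rep_ <- score_notes(gold, alltrue)
  pc <- rep_$per_class
  expect_equal(pc$precision[pc$class == "ContainingADE"], 0.5)
  expect_equal(pc$recall[pc$class == "ContainingADE"], 1.0)
  expect_equal(pc$recall[pc$class == "NoADE"], 0)
  expect_error(score_notes(gold, alltrue[1:5]), "same note ids")
})

test_that("error_analysis reports cells and top misclassified terms", {
  toks <- c("waran", "gav", "Utslag", "idag")
  gold <- c("B-Drug", "O", "B-Finding", "O")
  perfect <- error_analysis(gold, gold, toks)
  expect_true(all(perfect$confusion[upper.tri(perfect$confusion)] == 0))
  expect_true(all(perfect$confusion[lower.tri(perfect$confusion)] == 0))
  pred <- c("B-Drug", "O", "O", "O")
  ea <- error_analysis(gold, pred, toks)
  expect_equal(ea$confusion["Finding", "Other"], 1L)
  expect_equal(sum(ea$confusion), length(toks))
  top <- ea$terms[ea$terms$gold == "Finding" & ea$terms$pred == "Other", ]
  expect_equal(top$term, "utslag")  # case-folded
  expect_equal(top$count, 1L)
})
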