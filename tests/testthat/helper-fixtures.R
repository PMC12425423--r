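# Shared fixtures, memoized so expensive objects are built once per run.

.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

fixture_corpus <- function(n = 80L, seed = 3L) {
  memo(sprintf("corpus_%d_%d", n, seed),
       generate_corpus(generator_config(n_notes = n, seed = seed)))
}

# desk-scale training schedules for the lightweight encoder: same optimizer,
# regularization and early-stopping machinery as the reference configs, with
# a step budget and learning rate suited to training from random init on CPU
desk_ner_config <- function(seed = 1L, epochs = 40L) {
  ner_config(learning_rate = 0.02, epochs = epochs,
             gradient_accumulation = 1L, dim = 24L, seed = seed)
}

desk_re_config <- function(seed = 1L, epochs = 60L) {
  re_config(learning_rate = 0.1, epochs = epochs, patience_epochs = 15L,
            dim = 32L, seed = seed)
}

# small trained models over an 80-note separable corpus, for unit tests
fixture_models <- function() {
  memo("models_small", {
    corp <- fixture_corpus(80L, 3L)
    sp <- split_corpus(names(corp), seed = 11L)
    cands_tr <- corpus_candidates(corp[sp$train])
    cands_va <- corpus_candidates(corp[sp$validation])
    list(corpus = corp, split = sp,
         ner = train_ner(corp[sp$train], corp[sp$validation], desk_ner_config()),
         re = train_re(cands_tr, cands_va, desk_re_config()))
  })
}

# full study-scale run: 500-note separable corpus, 70/10/20 split, both
# models trained at desk scale, end-to-end predictions on the held-out test
# notes (built once; several acceptance properties are read off it)
acceptance_run <- function() {
  memo("acceptance_run", {
    corp <- generate_corpus(generator_config(n_notes = 500L, seed = 42L))
    sp <- split_corpus(names(corp), seed = 42L)
    cands <- lapply(list(train = corp[sp$train], validation = corp[sp$validation],
                         test = corp[sp$test]), corpus_candidates)
    ner <- train_ner(corp[sp$train], corp[sp$validation],
                     desk_ner_config(epochs = 15L))
    re <- train_re(cands$train, cands$validation, desk_re_config())
    test_notes <- corp[sp$test]
    e2e <- predict_corpus(ner, re, test_notes)
    on_gold <- lapply(test_notes, function(nt)
      run_end_to_end(ner, re, nt, entities = nt$entities))
    list(corpus = corp, split = sp, cands = cands, ner = ner, re = re,
         test_notes = test_notes, e2e = e2e, on_gold = on_gold)
  })
}

# a tiny hand-built note: two sentences, four entities, one ADE relation
fixture_note <- function() {
  ade_note(
    "toy",
    tokens = c("pat", "tar", "Waran", "mot", "ont", ".",
               "fick", "utslag", "av", "Waran", "."),
    sentence_starts = c(0L, 6L),
    entities = data.frame(
      id = c("T1", "T2", "T3"),
      cls = c("Drug", "Finding", "Finding"),
      token_start = c(2L, 4L, 7L), token_end = c(3L, 5L, 8L),
      stringsAsFactors = FALSE),
    relations = data.frame(label = c("Indication", "ADE"),
                           arg1 = c("T2", "T1"), arg2 = c("T1", "T3"),
                           stringsAsFactors = FALSE))
}
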