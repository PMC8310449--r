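make_corpus <- function(kg, n, ambiguity = 0, seed = 1)
  gen_bio_corpus(kg, n, ambiguity_rate = ambiguity, seed = seed)

test_that("training rejects bad input", {
  expect_error(train_tagger(list()), "empty")
  expect_error(train_tagger(list(list(tokens = c("a", "b"), tags = "O"))),
               "unequal")
  expect_error(train_tagger(list(list(tokens = "a", tags = "B-BAD"))),
               "unknown BIO tags")
  expect_error(train_tagger(list(list(tokens = "a", tags = "O")),
                            backend = "nope"), "arg")
})

test_that("separable corpus is tagged perfectly on held-out data", {
  g <- gen_kg(n_drugs = 15L, n_ingredients = 40L, seed = 3)
  lex <- lexicon_from_kg(g$kg)
  cb <- make_corpus(g$kg, 60, ambiguity = 0, seed = 5)
  model <- train_tagger(cb$corpus[1:40], lexicon = lex, seed = 2)
  pred <- lapply(41:60, function(i)
    bio_decode(cb$corpus[[i]]$tokens,
               predict(model, cb$corpus[[i]]$tokens, lex)))
  ev <- evaluate_ner(cb$mentions[41:60], pred)
  expect_equal(ev$macro_f1, 100)
  expect_equal(ev$micro_precision, 100)
})

test_that("training is deterministic given corpus and seed", {
  g <- gen_kg(n_drugs = 8L, n_ingredients = 20L, seed = 4)
  lex <- lexicon_from_kg(g$kg)
  cb <- make_corpus(g$kg, 25, ambiguity = 0.2, seed = 6)
  m1 <- train_tagger(cb$corpus, lexicon = lex, seed = 7)
  m2 <- train_tagger(cb$corpus, lexicon = lex, seed = 7)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$transitions, m2$transitions)
  toks <- cb$corpus[[1]]$tokens
  expect_identical(predict(m1, toks, lex), predict(m2, toks, lex))
  # a different seed is allowed to differ, but predictions stay valid tags
  m3 <- train_tagger(cb$corpus, lexicon = lex, seed = 8)
  expect_true(all(predict(m3, toks, lex) %in%
                    c("O", paste0(rep(c("B-", "I-"), 3),
                                  rep(c("DIS", "SYM", "ZCY"), each = 2)))))
})

test_that("ambiguous corpus yields F1 strictly between 0 and 100", {
  g <- gen_kg(n_drugs = 15L, n_ingredients = 40L, seed = 3)
  lex <- lexicon_from_kg(g$kg)
  cb <- make_corpus(g$kg, 80, ambiguity = 0.3, seed = 5)
  model <- train_tagger(cb$corpus[1:60], lexicon = lex, seed = 2)
  pred <- lapply(61:80, function(i)
    bio_decode(cb$corpus[[i]]$tokens,
               predict(model, cb$corpus[[i]]$tokens, lex)))
  ev <- evaluate_ner(cb$mentions[61:80], pred)
  expect_gt(ev$macro_f1, 0)
  expect_lt(ev$macro_f1, 100)
  # reproducible per seed
  model_b <- train_tagger(cb$corpus[1:60], lexicon = lex, seed = 2)
  pred_b <- lapply(61:80, function(i)
    bio_decode(cb$corpus[[i]]$tokens,
               predict(model_b, cb$corpus[[i]]$tokens, lex)))
  expect_equal(evaluate_ner(cb$mentions[61:80], pred_b)$macro_f1, ev$macro_f1)
})

test_that("tag_text agrees with direct decoding and links empty inputs", {
  g <- gen_kg(n_drugs = 10L, n_ingredients = 25L, seed = 9)
  lex <- lexicon_from_kg(g$kg)
  cb <- make_corpus(g$kg, 30, seed = 10)
  model <- train_tagger(cb$corpus, lexicon = lex, seed = 1)
  expect_equal(nrow(tag_text(model, "", lex)), 0L)
  expect_equal(nrow(tag_text(model, "filler1 filler2 filler3", lex)), 0L)
  set.seed(11)
  for (i in sample(seq_along(cb$corpus), 20)) {
    toks <- cb$corpus[[i]]$tokens
    direct <- bio_decode(toks, predict(model, toks, lex))
    via_text <- tag_text(model, paste(toks, collapse = " "), lex)
    expect_equal(via_text$start, direct$start)
    expect_equal(via_text$end, direct$end)
    expect_equal(via_text$label, direct$label)
  }
})

test_that("model files round-trip and reproduce predictions", {
  g <- gen_kg(n_drugs = 8L, n_ingredients = 20L, seed = 4)
  lex <- lexicon_from_kg(g$kg)
  cb <- make_corpus(g$kg, 20, seed = 6)
  model <- train_tagger(cb$corpus, lexicon = lex, seed = 3)
  p <- withr::local_tempfile(fileext = ".json")
  save_tagger(model, p)
  back <- load_tagger(p)
  toks <- cb$corpus[[1]]$tokens
  expect_identical(predict(back, toks, lex), predict(model, toks, lex))
  expect_equal(back$seed, model$seed)
  # saving twice produces identical bytes
  p2 <- withr::local_tempfile(fileext = ".json")
  save_tagger(model, p2)
  expect_identical(readLines(p), readLines(p2))
})

test_that("plugin backend is honoured through the same contract", {
  backend <- list(
    train = function(corpus, seed) list(tag = "O"),
    predict = function(state, tokens) rep(state$tag, length(tokens)))
  model <- train_tagger(list(list(tokens = "a", tags = "O")),
                        backend = "plugin", backend_config = backend)
  expect_equal(predict(model, c("x", "y")), c("O", "O"))
  expect_error(train_tagger(list(list(tokens = "a", tags = "O")),
                            backend = "plugin", backend_config = list()),
               "train and predict")
})
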