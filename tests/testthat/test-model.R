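# Model assembly, training and prediction.  Training runs here are sized for
# seconds, not accuracy; learning-quality assertions live in the acceptance
# suite.

small_cfg <- function(...) {
  ner_config(d = 16L, n_layers = 1L, n_heads = 2L, max_len = 120L, ...)
}

model_params_of <- function(m) {
  list(enc = m$enc, emb = m$emb, Wout = m$Wout, bout = m$bout,
       crf = if (!is.null(m$crf)) m$crf[c("trans", "start", "end")])
}

cached_quick_model <- function() {
  cached("quick_pred_model", {
    fx <- fixture_corpus(n_docs = 6L, seed = 61L)
    splits <- split_dataset(fx$sentences,
                            c(length(fx$sentences) - 12L, 6L, 6L), seed = 3L)
    bpe <- fixture_bpe(fx$sentences)
    m <- ner_build(ner_config(d = 16L, n_layers = 1L, n_heads = 2L), bpe,
                   seed = 1L)
    m <- ner_train(m, splits$train, splits$valid,
                   train_config(epochs = 3L, batch_size = 15L, lr = 2e-3,
                                seed = 1L))
    list(model = m, test_sentences = splits$test, docs = fx$docs)
  })
}

test_that("model building is deterministic and validates configuration", {
  fx <- fixture_corpus(n_docs = 3L, seed = 41L)
  bpe <- fixture_bpe(fx$sentences, 60L)
  m1 <- ner_build(small_cfg(), bpe, seed = 5L)
  m2 <- ner_build(small_cfg(), bpe, seed = 5L)
  expect_identical(model_params_of(m1), model_params_of(m2))
  expect_gt(attr(m1, "n_parameters"), 0)
  expect_error(ner_config(head = "softmax", crf_bias = TRUE), "requires")
  # crf head carries bias-initialized transitions
  expect_s3_class(m1$crf, "crf_params")
  expect_equal(m1$crf$trans["O", "I-SINTOMA"], -10000)
  # softmax head has no CRF parameters
  ms <- ner_build(small_cfg(head = "softmax", crf_bias = FALSE,
                            bpe_dropout = 0), bpe, seed = 5L)
  expect_null(ms$crf)
})

test_that("a short training run reduces loss and beats the untrained model", {
  fx <- fixture_corpus(n_docs = 10L, seed = 43L)
  splits <- split_dataset(fx$sentences, c(length(fx$sentences) - 20L, 10L, 10L),
                          seed = 3L)
  bpe <- fixture_bpe(fx$sentences)
  model0 <- ner_build(small_cfg(), bpe, seed = 1L)
  f1_untrained <- ner_evaluate(sentences_gold(splits$test),
                               ner_predict(model0, splits$test))$F1
  tc <- train_config(epochs = 8L, batch_size = 15L, lr = 4e-3, seed = 1L)
  model <- cached("quick_crf_model", ner_train(model0, splits$train,
                                               splits$valid, tc))
  losses <- vapply(model$history, `[[`, numeric(1), "train_loss")
  expect_lt(losses[length(losses)], losses[1])
  f1_trained <- ner_evaluate(sentences_gold(splits$test),
                             ner_predict(model, splits$test))$F1
  expect_gt(f1_trained, f1_untrained)
})

test_that("training is reproducible given the seed", {
  fx <- fixture_corpus(n_docs = 4L, seed = 47L)
  splits <- split_dataset(fx$sentences, c(length(fx$sentences) - 10L, 5L, 5L),
                          seed = 3L)
  bpe <- fixture_bpe(fx$sentences, 60L)
  run <- function() {
    m <- ner_build(small_cfg(), bpe, seed = 2L)
    m <- ner_train(m, splits$train, splits$valid,
                   train_config(epochs = 2L, batch_size = 10L, lr = 1e-3,
                                seed = 9L))
    m$history
  }
  expect_identical(run(), run())
})

test_that("zero-epoch training returns the initial model with empty history", {
  fx <- fixture_corpus(n_docs = 3L, seed = 53L)
  bpe <- fixture_bpe(fx$sentences, 60L)
  m0 <- ner_build(small_cfg(head = "softmax", crf_bias = FALSE,
                            bpe_dropout = 0), bpe, seed = 1L)
  m <- ner_train(m0, fx$sentences[1:10], fx$sentences[11:12],
                 train_config(epochs = 0L, lr = 1e-3, seed = 1L))
  expect_length(m$history, 0L)
  expect_identical(model_params_of(m), model_params_of(m0))
  expect_error(ner_train(m0, list(), fx$sentences[1:2]), "empty training")
})

test_that("prediction is deterministic, offset-faithful and empty-safe", {
  model <- cached_quick_model()
  sents <- model$test_sentences
  p1 <- ner_predict(model$model, sents)
  p2 <- ner_predict(model$model, sents)
  expect_identical(p1, p2)
  # every predicted span's text equals the document substring
  docs <- model$docs
  for (i in seq_len(NROW(p1))) {
    d <- docs[[p1$doc_id[i]]]
    expect_identical(substr(d$text, p1$start[i] + 1L, p1$end[i]), p1$text[i])
  }
  # empty sentence yields no spans
  empty_s <- list(doc_id = "d", start = 0L, end = 0L, text = "", spans = NULL)
  expect_equal(NROW(ner_predict(model$model, list(empty_s))), 0L)
})

test_that("checkpoints round-trip bit-identically", {
  model <- cached_quick_model()
  path <- withr::local_tempfile(fileext = ".rds")
  ner_save(model$model, path)
  reloaded <- ner_load(path)
  expect_identical(ner_predict(reloaded, model$test_sentences),
                   ner_predict(model$model, model$test_sentences))
})

test_that("ssw-embedding models train and predict through the same interface", {
  fx <- fixture_corpus(n_docs = 4L, seed = 59L)
  splits <- split_dataset(fx$sentences, c(length(fx$sentences) - 10L, 5L, 5L),
                          seed = 3L)
  bpe <- fixture_bpe(fx$sentences, 60L)
  cfg <- small_cfg(embeddings = "ssw", ssw_K = 300L, ssw_hidden = 24L)
  m <- ner_build(cfg, bpe, seed = 1L)
  m <- ner_train(m, splits$train, splits$valid,
                 train_config(epochs = 2L, batch_size = 10L, lr = 1e-3,
                              seed = 4L))
  pred <- ner_predict(m, splits$test)
  expect_true(is.data.frame(pred))
  expect_length(m$history, 2L)
})

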