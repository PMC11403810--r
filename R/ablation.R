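# Scripted ablation study over head / regularization / embedding choices.
#
# Trains every requested model configuration with several seeds on one
# synthetic corpus, evaluates strict and overlapping F1 on the held-out test
# sentences, majority-votes each configuration's seed models, and emits a
# results table (Mean (SD), Min, Max per configuration).

#' Named ablation configurations
#'
#' The standard axes: a plain softmax head, softmax with BPE-dropout, a CRF
#' head with BPE-dropout, the CRF with BIO-constraint transition bias, and
#' the biased CRF with sub-subword feature embeddings.
#'
#' @return named list of configuration fragments understood by
#'   [ablation_study()].
#' @export
ablation_configs <- function() list(
  softmax = list(head = "softmax", crf_bias = FALSE, bpe_dropout = 0),
  softmax_bped = list(head = "softmax", crf_bias = FALSE, bpe_dropout = 0.1),
  crf_bped = list(head = "crf", crf_bias = FALSE, bpe_dropout = 0.1),
  crf_bped_bias = list(head = "crf", crf_bias = TRUE, bpe_dropout = 0.1),
  crf_bped_bias_sswf = list(head = "crf", crf_bias = TRUE, bpe_dropout = 0.1,
                            embeddings = "ssw"))

#' Run an ablation study on a synthetic corpus
#'
#' @param configs subset of [ablation_configs()] (names or list).
#' @param seeds integer vector of training seeds (one model per seed and
#'   configuration).
#' @param gen a [gen_config()] for the corpus.
#' @param sizes train/valid/test sentence counts; `NULL` keeps roughly
#'   80/10/10.
#' @param epochs,batch_size,lr training hyperparameters.
#' @param d,n_layers encoder geometry.
#' @param num_merges BPE merge operations learned from the training text.
#' @param ssw_K,ssw_hidden sub-subword options for `ssw` configurations.
#' @return list with per-configuration strict F1 vectors (`f1`), overlap F1
#'   (`o_f1`), per-seed invalid-transition counts on the test set
#'   (`invalid`), per-seed test predictions (`predictions`), the ensembled
#'   prediction per configuration (`ensemble`), ensemble F1
#'   (`ensemble_f1`), the gold test spans (`gold`), and a formatted `table`.
#' @export
ablation_study <- function(configs = c("softmax", "crf_bped", "crf_bped_bias"),
                           seeds = 1:3,
                           gen = gen_config(n_docs = 40L,
                                            ambiguity_rate = 0.15,
                                            seed = 11L),
                           sizes = NULL, epochs = 14L, batch_size = 15L,
                           lr = 2e-3, d = 32L, n_layers = 2L,
                           num_merges = 120L, ssw_K = 400L,
                           ssw_hidden = 32L) {
  if (is.character(configs)) configs <- ablation_configs()[configs]
  docs <- generate_corpus(gen)
  sents <- unlist(lapply(docs, segment_sentences), recursive = FALSE)
  n <- length(sents)
  if (is.null(sizes)) {
    nv <- max(1L, round(n * 0.1))
    sizes <- c(n - 2L * nv, nv, nv)
  }
  splits <- split_dataset(sents, sizes, seed = gen$seed)
  bpe <- learn_bpe(vapply(splits$train, `[[`, "", "text"), num_merges)
  gold <- sentences_gold(splits$test)
  out <- list()
  for (nm in names(configs)) {
    cc <- configs[[nm]]
    f1 <- numeric(); o_f1 <- numeric(); invalid <- integer()
    preds <- list()
    for (s in seeds) {
      cfg <- ner_config(head = cc$head, crf_bias = isTRUE(cc$crf_bias),
                        bpe_dropout = cc$bpe_dropout,
                        embeddings = if (!is.null(cc$embeddings))
                          cc$embeddings else "lookup",
                        d = d, n_layers = n_layers,
                        ssw_K = ssw_K, ssw_hidden = ssw_hidden)
      m <- ner_build(cfg, bpe, seed = s)
      m <- ner_train(m, splits$train, splits$valid,
                     train_config(epochs = epochs, batch_size = batch_size,
                                  lr = lr, seed = s))
      pred <- ner_predict(m, splits$test)
      rep <- ner_evaluate(gold, pred)
      f1 <- c(f1, rep$F1); o_f1 <- c(o_f1, rep$o_F1)
      invalid <- c(invalid,
                   sum(vapply(ner_predict_tags(m, splits$test),
                              count_invalid_transitions, integer(1))))
      preds[[as.character(s)]] <- pred
    }
    ens <- majority_vote(unname(preds))
    out[[nm]] <- list(f1 = f1, o_f1 = o_f1, invalid = invalid,
                      predictions = preds, ensemble = ens,
                      ensemble_f1 = ner_evaluate(gold, ens)$F1)
  }
  list(configs = out, gold = gold,
       table = format_run_table(lapply(out, `[[`, "f1")),
       test_sentences = splits$test)
}
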