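# Token-classification model assembly, training loop and span prediction.
#
# Pipeline per sentence: word tokenization -> gold word-level BIO tags ->
# BPE segmentation (deterministic at prediction time, dropout-regularized
# during training) -> subword embeddings (lookup table, or the FTE network
# over sub-subword features) -> tiny transformer encoder -> per-label
# emission scores at word-start subwords -> softmax or linear-chain CRF over
# the word positions -> BIO decode back to character-offset spans.
# Continuation subwords are masked out of the loss; the tag chain runs over
# word-start positions, so predicted spans always align to word boundaries.

#' Model configuration
#'
#' @param head `"crf"` or `"softmax"` output layer.
#' @param crf_bias if `TRUE` (requires `head = "crf"`), transitions are
#'   initialized with the BIO-constraint bias of [crf_init()].
#' @param crf_bias_value bias constant (default -10000).
#' @param crf_bias_mode `"all_invalid"` or `"o_to_i"` (see [crf_init()]).
#' @param crf_freeze_bias if `TRUE`, the biased transition entries are
#'   re-imposed after every optimizer step (frozen); by default they remain
#'   trainable.
#' @param embeddings `"lookup"` (free embedding table) or `"ssw"`
#'   (sub-subword FTE embeddings).
#' @param bpe_dropout merge-veto probability applied to training sentences
#'   only; prediction always uses deterministic encoding.
#' @param labels BIO tag inventory.
#' @param d,n_layers,n_heads,max_len encoder geometry (see [encoder_init()]).
#' @param ssw_n_range,ssw_K,ssw_hidden sub-subword feature options (used when
#'   `embeddings = "ssw"`).
#' @return a `ner_config` list.
#' @export
ner_config <- function(head = c("crf", "softmax"), crf_bias = (head[1] == "crf"),
                       crf_bias_value = -10000,
                       crf_bias_mode = "all_invalid",
                       crf_freeze_bias = FALSE,
                       embeddings = c("lookup", "ssw"), bpe_dropout = 0.1,
                       labels = c("O", "B-SINTOMA", "I-SINTOMA"),
                       d = 64L, n_layers = 2L, n_heads = 2L, max_len = 160L,
                       ssw_n_range = c(1L, 4L), ssw_K = 4096L,
                       ssw_hidden = 64L) {
  head <- match.arg(head)
  embeddings <- match.arg(embeddings)
  if (crf_bias && head != "crf")
    stop("crf_bias requires head = 'crf'")
  if (bpe_dropout < 0 || bpe_dropout > 1) stop("bpe_dropout must be in [0,1]")
  structure(list(head = head, crf_bias = crf_bias,
                 crf_bias_value = crf_bias_value,
                 crf_bias_mode = crf_bias_mode,
                 crf_freeze_bias = crf_freeze_bias,
                 embeddings = embeddings, bpe_dropout = bpe_dropout,
                 labels = labels, d = as.integer(d),
                 n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads), max_len = as.integer(max_len),
                 ssw_n_range = as.integer(ssw_n_range),
                 ssw_K = as.integer(ssw_K),
                 ssw_hidden = as.integer(ssw_hidden)),
            class = "ner_config")
}

#' Training configuration
#'
#' Defaults follow the standard fine-tuning recipe for this task family:
#' 25 epochs, batches of 15 sentences, learning rate 2e-5, AdamW, keeping the
#' best checkpoint by validation strict F1.  From-scratch training of the
#' tiny encoder typically wants a larger learning rate (e.g. 1e-2).
#'
#' @param epochs number of passes over the training data.
#' @param batch_size sentences per optimizer step.
#' @param lr AdamW learning rate.
#' @param weight_decay decoupled weight decay on weight matrices.
#' @param seed master seed for shuffling and BPE-dropout sampling.
#' @param selection `"best"` keeps the epoch with the highest validation
#'   strict F1; `"last"` keeps the final epoch (no validation needed).
#' @param extra_epoch_on_train_plus_valid after selection, train one extra
#'   epoch on the union of training and validation sentences.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 25L, batch_size = 15L, lr = 2e-5,
                         weight_decay = 0.01, seed = 1L,
                         selection = c("best", "last"),
                         extra_epoch_on_train_plus_valid = FALSE) {
  if (epochs < 0L || batch_size < 1L || lr <= 0)
    stop("epochs, batch_size and lr must be positive")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 weight_decay = weight_decay, seed = as.integer(seed),
                 selection = match.arg(selection),
                 extra_epoch_on_train_plus_valid =
                   extra_epoch_on_train_plus_valid),
            class = "train_config")
}

#' Build an (untrained) NER model
#'
#' @param cfg a [ner_config()].
#' @param bpe a `bpe_model` providing the subword vocabulary.
#' @param seed seed for all parameter initialization.
#' @return a `ner_model` holding config, parameters, BPE reference and label
#'   inventory; `n_parameters` attribute reports the trainable size.
#' @export
ner_build <- function(cfg, bpe, seed = 1L) {
  V <- length(bpe$vocab)
  L <- length(cfg$labels)
  enc <- encoder_init(d = cfg$d, n_layers = cfg$n_layers,
                      n_heads = cfg$n_heads, max_len = cfg$max_len,
                      seed = seed)
  if (cfg$embeddings == "lookup") {
    emb <- with_seed(seed + 1L, init_mat(V, cfg$d))
    ssw <- NULL
  } else {
    inventory <- ssw_select_features(bpe$vocab, K = cfg$ssw_K,
                                     n_range = cfg$ssw_n_range)
    emb <- fte_init(inventory$K, cfg$d, hidden = cfg$ssw_hidden,
                    seed = seed + 1L)
    ssw <- list(inventory = inventory,
                Phi = ssw_featurize_vocab(bpe$vocab, inventory))
  }
  out_head <- with_seed(seed + 2L, list(Wout = init_mat(cfg$d, L),
                                        bout = rep(0, L)))
  crf <- if (cfg$head == "crf") {
    if (cfg$crf_bias)
      crf_init(cfg$labels, bias_value = cfg$crf_bias_value,
               mode = cfg$crf_bias_mode, seed = seed + 3L)
    else {
      p <- crf_init(cfg$labels, bias_value = -1, seed = seed + 3L)
      # undo the bias: plain small random transitions
      p$trans[p$trans_bias] <- with_seed(seed + 4L,
        stats::rnorm(sum(p$trans_bias), sd = 0.01))
      p$start[p$start_bias] <- with_seed(seed + 5L,
        stats::rnorm(sum(p$start_bias), sd = 0.01))
      p$trans_bias[] <- FALSE; p$start_bias[] <- FALSE
      p
    }
  } else NULL
  model <- structure(list(cfg = cfg, bpe = bpe, enc = enc, emb = emb,
                          ssw = ssw, Wout = out_head$Wout,
                          bout = out_head$bout, crf = crf,
                          history = list()),
                     class = "ner_model")
  attr(model, "n_parameters") <- n_parameters(model)
  model
}

n_parameters <- function(model) {
  cnt <- function(x) if (is.list(x)) sum(vapply(x, cnt, numeric(1)))
    else length(x)
  n <- cnt(model$enc) + cnt(unclass(model$emb)) + length(model$Wout) +
    length(model$bout)
  if (!is.null(model$crf))
    n <- n + length(model$crf$trans) + 2L * length(model$crf$labels)
  n
}

#' @export
print.ner_model <- function(x, ...) {
  cat("<ner_model> head=", x$cfg$head,
      if (isTRUE(x$cfg$crf_bias)) "+bias" else "",
      " emb=", x$cfg$embeddings,
      " d=", x$cfg$d, " layers=", x$cfg$n_layers,
      "  (", format(attr(x, "n_parameters"), big.mark = ","),
      " parameters)\n", sep = "")
  invisible(x)
}

# --- internal: parameter tree <-> model -------------------------------------

model_params <- function(model) {
  p <- list(enc = model$enc, Wout = model$Wout, bout = model$bout)
  p$emb <- if (model$cfg$embeddings == "lookup") model$emb
    else unclass(model$emb)[c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4")]
  if (!is.null(model$crf))
    p$crf <- list(trans = model$crf$trans, start = model$crf$start,
                  end = model$crf$end)
  p
}

model_set_params <- function(model, p) {
  model$enc <- p$enc
  model$Wout <- p$Wout; model$bout <- p$bout
  if (model$cfg$embeddings == "lookup") model$emb <- p$emb
  else model$emb[c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4")] <-
      p$emb[c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4")]
  if (!is.null(model$crf)) {
    model$crf$trans <- p$crf$trans
    model$crf$start <- p$crf$start
    model$crf$end <- p$crf$end
  }
  model
}

zero_like <- function(p) tree_map(function(x) x * 0, p)

# --- internal: per-sentence forward/backward --------------------------------

# Precompute the parts of a sentence that do not depend on segmentation.
prep_sentence <- function(sentence) {
  words <- word_tokenize(sentence$text)
  tags <- if (NROW(words)) bio_encode(sentence, words)$tag else character()
  list(sentence = sentence, words = words, word_tags = tags)
}

# Embed subword ids; returns X0 plus a cache for the backward pass.
embed_forward <- function(model, ids) {
  if (model$cfg$embeddings == "lookup")
    list(X0 = model$emb[ids, , drop = FALSE], cache = list(ids = ids))
  else {
    X <- model$ssw$Phi[ids, , drop = FALSE]
    cache <- fte_forward_cache(X, model$emb)
    list(X0 = cache$out, cache = c(cache, list(ids = ids)))
  }
}

embed_backward <- function(model, cache, dX0, acc) {
  if (model$cfg$embeddings == "lookup") {
    for (r in seq_along(cache$ids)) {
      i <- cache$ids[r]
      acc$emb[i, ] <- acc$emb[i, ] + dX0[r, ]
    }
  } else {
    g <- fte_backward(cache, dX0, model$emb)
    for (nm in names(g)) acc$emb[[nm]] <- acc$emb[[nm]] + g[[nm]]
  }
  acc
}

# Loss + gradients for one prepared sentence.  Returns NULL for sentences
# with no words.  `p_drop` > 0 samples a BPE-dropout segmentation from the
# current RNG stream.
sentence_grad <- function(model, prep, p_drop = 0) {
  if (!NROW(prep$words)) return(NULL)
  sw <- bpe_encode(prep$sentence$text, model$bpe, p = p_drop)
  if (NROW(sw) > model$cfg$max_len) return(NULL)  # over-long: skip
  ids <- bpe_token_ids(sw, model$bpe)
  ef <- embed_forward(model, ids)
  fwd <- encoder_forward(ef$X0, model$enc)
  ws <- which(sw$word_start)
  Yws <- fwd$Y[ws, , drop = FALSE]
  emis <- sweep(Yws %*% model$Wout, 2L, model$bout, "+")
  y <- match(prep$word_tags, model$cfg$labels)
  if (anyNA(y)) stop("gold tag outside the label inventory")
  if (model$cfg$head == "crf") {
    fb <- crf_forward_backward(emis, y, model$crf)
    loss <- fb$nll
    d_emis <- fb$d_emissions
    d_crf <- list(trans = fb$d_trans, start = fb$d_start, end = fb$d_end)
  } else {
    prob <- softmax_rows(emis)
    loss <- -sum(log(pmax(prob[cbind(seq_along(y), y)], 1e-12)))
    d_emis <- prob
    d_emis[cbind(seq_along(y), y)] <- d_emis[cbind(seq_along(y), y)] - 1
    d_crf <- NULL
  }
  if (!is.finite(loss)) stop("non-finite training loss (diverged)")
  dWout <- crossprod(Yws, d_emis)
  dbout <- colSums(d_emis)
  dY <- matrix(0, NROW(sw), model$cfg$d)
  dY[ws, ] <- d_emis %*% t(model$Wout)
  bwd <- encoder_backward(dY, fwd, model$enc)
  list(loss = loss, enc = bwd$grads, dX0 = bwd$dX0, emb_cache = ef$cache,
       Wout = dWout, bout = dbout, crf = d_crf)
}

#' Train an NER model
#'
#' Mini-batch AdamW training.  BPE-dropout (the model config's
#' `bpe_dropout`) is applied to training sentences only; validation and
#' prediction always use the deterministic segmentation.  After each epoch
#' the model is evaluated on the validation sentences by strict entity-level
#' F1 and, with `selection = "best"`, the best-scoring checkpoint is
#' returned.  Fully deterministic given `tc$seed`.
#'
#' @param model from [ner_build()].
#' @param train_sents,valid_sents lists of sentence objects
#'   (see [segment_sentences()]).
#' @param tc a [train_config()].
#' @return the trained `ner_model`, with `history` (per-epoch mean loss and
#'   validation F1) attached.
#' @export
ner_train <- function(model, train_sents, valid_sents, tc = train_config()) {
  if (!length(train_sents)) stop("empty training set")
  if (tc$selection == "best" && !length(valid_sents))
    stop("selection = 'best' requires a non-empty validation set")
  preps <- lapply(train_sents, prep_sentence)
  preps <- preps[vapply(preps, function(p) NROW(p$words) > 0L, logical(1))]
  params <- model_params(model)
  opt <- adamw_init(params, lr = tc$lr, weight_decay = tc$weight_decay)
  history <- list()
  best <- list(f1 = -Inf, params = params)
  set.seed(tc$seed)
  run_epoch <- function(preps, params, opt) {
    ord <- sample.int(length(preps))
    losses <- numeric()
    for (batch in split(ord, ceiling(seq_along(ord) / tc$batch_size))) {
      model_b <- model_set_params(model, params)
      acc <- zero_like(params)
      bl <- 0
      n_eff <- 0L
      for (i in batch) {
        g <- sentence_grad(model_b, preps[[i]], p_drop = model$cfg$bpe_dropout)
        if (is.null(g)) next
        n_eff <- n_eff + 1L
        bl <- bl + g$loss
        acc$enc <- tree_map2(`+`, acc$enc, g$enc)
        acc$Wout <- acc$Wout + g$Wout
        acc$bout <- acc$bout + g$bout
        acc <- embed_backward(model_b, g$emb_cache, g$dX0, acc)
        if (!is.null(g$crf)) acc$crf <- tree_map2(`+`, acc$crf, g$crf)
      }
      if (!n_eff) next
      acc <- tree_map(function(x) x / n_eff, acc)
      upd <- adamw_step(opt, params, acc)
      params <- upd$params; opt <- upd$opt
      if (isTRUE(model$cfg$crf_freeze_bias) && !is.null(model$crf)) {
        params$crf$trans[model$crf$trans_bias] <- model$cfg$crf_bias_value
        params$crf$start[model$crf$start_bias] <- model$cfg$crf_bias_value
      }
      losses <- c(losses, bl / n_eff)
    }
    list(params = params, opt = opt, loss = mean(losses))
  }
  for (epoch in seq_len(tc$epochs)) {
    ep <- run_epoch(preps, params, opt)
    params <- ep$params; opt <- ep$opt
    valid_f1 <- NA_real_
    if (length(valid_sents)) {
      m_now <- model_set_params(model, params)
      valid_f1 <- evaluate_on(m_now, valid_sents)$F1
    }
    history[[epoch]] <- list(epoch = epoch, train_loss = ep$loss,
                             valid_f1 = valid_f1)
    if (tc$selection == "best" && !is.na(valid_f1) && valid_f1 > best$f1)
      best <- list(f1 = valid_f1, params = params)
  }
  final <- if (tc$selection == "best" && is.finite(best$f1)) best$params
    else params
  if (tc$extra_epoch_on_train_plus_valid) {
    all_preps <- c(preps, lapply(valid_sents, prep_sentence))
    all_preps <- all_preps[vapply(all_preps, function(p) NROW(p$words) > 0L,
                                  logical(1))]
    opt2 <- adamw_init(final, lr = tc$lr, weight_decay = tc$weight_decay)
    ep <- run_epoch(all_preps, final, opt2)
    final <- ep$params
    history[[length(history) + 1L]] <-
      list(epoch = tc$epochs + 1L, train_loss = ep$loss, valid_f1 = NA_real_,
           extra = TRUE)
  }
  model <- model_set_params(model, final)
  model$history <- history
  model
}

#' Collect gold spans of a sentence list in document offsets
#'
#' Re-bases each sentence's local spans by the sentence's document offset,
#' producing the reference span table that [ner_evaluate()] expects.
#'
#' @param sentences list of sentence objects.
#' @return span data.frame in document-level offsets.
#' @export
sentences_gold <- function(sentences) {
  out <- lapply(sentences, function(s) {
    sp <- s$spans
    if (!NROW(sp)) return(NULL)
    sp$start <- sp$start + s$start
    sp$end <- sp$end + s$start
    sp
  })
  as_span_table(do.call(rbind, out))
}

evaluate_on <- function(model, sentences) {
  pred <- ner_predict(model, sentences)
  ner_evaluate(sentences_gold(sentences), pred)
}

#' Predict word-level tag sequences
#'
#' Deterministic BPE encoding, encoder forward pass and either Viterbi
#' decoding (CRF head) or per-position argmax (softmax head), read at
#' word-start subwords.
#'
#' @param model a trained `ner_model`.
#' @param sentences list of sentence objects.
#' @return list of character tag vectors, one per sentence (one tag per
#'   word).
#' @export
ner_predict_tags <- function(model, sentences) {
  lapply(sentences, function(s) {
    words <- word_tokenize(s$text)
    if (!NROW(words)) return(character())
    sw <- bpe_encode(s$text, model$bpe, p = 0)
    ids <- bpe_token_ids(sw, model$bpe)
    ef <- embed_forward(model, ids)
    fwd <- encoder_forward(ef$X0, model$enc)
    ws <- which(sw$word_start)
    emis <- sweep(fwd$Y[ws, , drop = FALSE] %*% model$Wout, 2L,
                  model$bout, "+")
    if (model$cfg$head == "crf") crf_viterbi(emis, model$crf)$tags
    else model$cfg$labels[max.col(emis, ties.method = "first")]
  })
}

#' Predict entity spans
#'
#' @param model a trained `ner_model`.
#' @param sentences list of sentence objects.
#' @return span data.frame in document-level character offsets.
#' @export
ner_predict <- function(model, sentences) {
  tag_seqs <- ner_predict_tags(model, sentences)
  out <- lapply(seq_along(sentences), function(i) {
    s <- sentences[[i]]
    words <- word_tokenize(s$text)
    if (!NROW(words)) return(NULL)
    tags <- data.frame(tag = tag_seqs[[i]], start = words$start,
                       end = words$end, stringsAsFactors = FALSE)
    sp <- bio_decode(tags, s$text, doc_id = s$doc_id)
    if (!NROW(sp)) return(NULL)
    sp$start <- sp$start + s$start
    sp$end <- sp$end + s$start
    sp
  })
  as_span_table(do.call(rbind, out))
}

#' Save / load a model checkpoint
#'
#' The checkpoint is self-describing: it contains the model configuration,
#' all parameters, the BPE model and the label inventory.  A reloaded model
#' predicts bit-identically.
#'
#' @param model a `ner_model`.
#' @param path file path (RDS serialization).
#' @return `path` / the reloaded `ner_model`.
#' @export
ner_save <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname ner_save
#' @export
ner_load <- function(path) readRDS(path)
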