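# Byte-pair-encoding subword model with dropout regularization.
#
# A BPE model is an ordered list of symbol-pair merges over a base alphabet;
# rank 0 is the highest-priority merge.  Encoding greedily applies the
# best-ranked applicable merge, leftmost occurrence first.  Dropout encoding
# vetoes each merge application attempt independently with probability p,
# yielding a different segmentation of the same text on each call; p = 0
# reproduces deterministic encoding and p = 1 yields base symbols.
# Character intervals are tracked through every merge so subword tags can be
# mapped back to exact character offsets.

PAIR_SEP <- "\x1f"  # internal pair-key separator; symbols never contain it

bpe_specials <- function() c("<pad>", "<unk>", "<s>", "</s>")

new_bpe_model <- function(alphabet, merges) {
  merged <- if (NROW(merges)) paste0(merges$left, merges$right) else character()
  vocab <- c(bpe_specials(), alphabet, merged)
  rank_map <- if (NROW(merges)) {
    r <- seq_len(NROW(merges)) - 1L
    names(r) <- paste(merges$left, merges$right, sep = PAIR_SEP)
    r
  } else structure(integer(), names = character())
  structure(list(alphabet = alphabet, merges = merges,
                 specials = bpe_specials(), vocab = vocab,
                 rank_map = rank_map),
            class = "bpe_model")
}

#' @export
print.bpe_model <- function(x, ...) {
  cat("<bpe_model> alphabet ", length(x$alphabet), " symbols, ",
      NROW(x$merges), " merges, vocab ", length(x$vocab), "\n", sep = "")
  invisible(x)
}

#' Learn a BPE merge table from a corpus
#'
#' Standard byte-pair-encoding learning: words are the whitespace/punctuation
#' tokens of the corpus, and at each step the most frequent adjacent symbol
#' pair (ties broken lexicographically, so learning is deterministic given
#' corpus order) is merged into a new symbol.
#'
#' @param corpus character vector of sentences (non-empty).
#' @param num_merges number of merge operations to learn (>= 0).
#' @return a `bpe_model`: base alphabet, ordered merges, reserved specials.
#' @export
learn_bpe <- function(corpus, num_merges) {
  corpus <- corpus[nzchar(corpus)]
  if (!length(corpus)) stop("cannot learn BPE from an empty corpus")
  if (num_merges < 0L) stop("num_merges must be >= 0")
  words <- unlist(lapply(corpus, function(s) word_tokenize(s)$token))
  freq <- table(words)
  word_syms <- lapply(names(freq), function(w) strsplit(w, "")[[1]])
  wfreq <- as.integer(freq)
  alphabet <- sort(unique(unlist(word_syms)))

  merges <- data.frame(left = character(), right = character(),
                       stringsAsFactors = FALSE)
  for (k in seq_len(num_merges)) {
    counts <- new.env(hash = TRUE, parent = emptyenv())
    for (i in seq_along(word_syms)) {
      s <- word_syms[[i]]
      if (length(s) < 2L) next
      keys <- paste(s[-length(s)], s[-1L], sep = PAIR_SEP)
      for (key in unique(keys)) {
        n <- sum(keys == key) * wfreq[i]
        prev <- if (is.null(counts[[key]])) 0L else counts[[key]]
        counts[[key]] <- prev + n
      }
    }
    keys <- ls(counts)
    if (!length(keys)) break
    vals <- vapply(keys, function(k) counts[[k]], integer(1))
    best <- keys[vals == max(vals)]
    best <- sort(best)[1]  # deterministic tie-break
    parts <- strsplit(best, PAIR_SEP, fixed = TRUE)[[1]]
    merges <- rbind(merges, data.frame(left = parts[1], right = parts[2],
                                       stringsAsFactors = FALSE))
    word_syms <- lapply(word_syms, apply_merge, parts[1], parts[2])
  }
  new_bpe_model(alphabet, merges)
}

# Merge all non-overlapping occurrences of (left, right) in a symbol vector,
# left to right.
apply_merge <- function(syms, left, right) {
  i <- 1L
  while (i < length(syms)) {
    if (syms[i] == left && syms[i + 1L] == right) {
      syms[i] <- paste0(left, right)
      syms <- syms[-(i + 1L)]
    } else i <- i + 1L
  }
  syms
}

# Encode one word (given as its surface string with absolute start offset)
# into subwords.  Dropout: each application attempt of a candidate merge is
# vetoed independently with probability p; when every current candidate is
# vetoed the word is left as segmented so far.
encode_word <- function(word, start, model, p = 0) {
  syms <- strsplit(word, "")[[1]]
  starts <- start + seq_along(syms) - 1L
  ends <- starts + 1L
  repeat {
    n <- length(syms)
    if (n < 2L) break
    keys <- paste(syms[-n], syms[-1L], sep = PAIR_SEP)
    ranks <- unname(model$rank_map[keys])
    cand <- which(!is.na(ranks))
    if (!length(cand)) break
    cand <- cand[order(ranks[cand], cand)]
    j <- NA_integer_
    if (p <= 0) {
      j <- cand[1]
    } else {
      for (c0 in cand) if (stats::runif(1) >= p) { j <- c0; break }
      if (is.na(j)) break  # all candidates vetoed this round
    }
    syms[j] <- paste0(syms[j], syms[j + 1L])
    ends[j] <- ends[j + 1L]
    syms <- syms[-(j + 1L)]
    starts <- starts[-(j + 1L)]
    ends <- ends[-(j + 1L)]
  }
  data.frame(token = syms, start = starts, end = ends,
             stringsAsFactors = FALSE)
}

#' Encode text into subwords (deterministic or with BPE-dropout)
#'
#' Text is pre-tokenized into words ([word_tokenize()]), each word is encoded
#' independently, and every subword carries its exact character interval and
#' a word-start flag.  With `p = 0` the encoding is deterministic; with
#' `p > 0` each merge application attempt is independently vetoed with
#' probability `p` (BPE-dropout), so repeated calls sample different
#' segmentations.  Concatenating the subword strings of a word always
#' restores the word, for any `p`.
#'
#' @param text input string.
#' @param model a `bpe_model`.
#' @param p merge-veto probability in \[0, 1\]; default 0 (deterministic).
#' @param seed optional RNG seed for reproducible dropout sampling; if `NULL`
#'   the current RNG stream is used.
#' @return data.frame with columns `token`, `start`, `end`, `word_start`,
#'   `word_index` (0-based character intervals into `text`).
#' @export
bpe_encode <- function(text, model, p = 0, seed = NULL) {
  stopifnot(p >= 0, p <= 1)
  run <- function() {
    words <- word_tokenize(text)
    if (!NROW(words)) {
      return(data.frame(token = character(), start = integer(),
                        end = integer(), word_start = logical(),
                        word_index = integer(), stringsAsFactors = FALSE))
    }
    pieces <- vector("list", NROW(words))
    for (i in seq_len(NROW(words))) {
      sw <- encode_word(words$token[i], words$start[i], model, p)
      sw$word_start <- c(TRUE, rep(FALSE, NROW(sw) - 1L))
      sw$word_index <- i
      pieces[[i]] <- sw
    }
    do.call(rbind, pieces)
  }
  if (!is.null(seed)) with_seed(seed, run()) else run()
}

#' Dropout-regularized encoding (convenience wrapper)
#'
#' @param text input string.
#' @param model a `bpe_model`.
#' @param cfg list with `p` (merge-discard probability) and optional
#'   `rng_seed`.
#' @return as [bpe_encode()].
#' @export
bpe_encode_dropout <- function(text, model, cfg = list(p = 0.1, rng_seed = NULL)) {
  bpe_encode(text, model, p = cfg$p, seed = cfg$rng_seed)
}

#' Map subword surface strings to vocabulary ids
#'
#' Symbols outside the model vocabulary (characters never seen at learning
#' time) map to the `<unk>` id; their surface string and interval are kept in
#' the subword table so text reconstruction is unaffected.
#'
#' @param subwords data.frame from [bpe_encode()].
#' @param model a `bpe_model`.
#' @return integer vector of 1-based indices into `model$vocab`.
#' @export
bpe_token_ids <- function(subwords, model) {
  ids <- match(subwords$token, model$vocab)
  ids[is.na(ids)] <- match("<unk>", model$vocab)
  ids
}

#' Propagate word-level BIO tags to subwords
#'
#' The first subword of each word carries the word's tag and is supervised;
#' continuation subwords carry `I-<label>` inside entities (or `O` outside)
#' and are masked out of the loss by default.  Decoding reads only word-start
#' subwords, so offsets remain exact.
#'
#' @param subwords data.frame from [bpe_encode()].
#' @param word_tags character vector of BIO tags, one per word (in
#'   `word_index` order).
#' @param supervise_continuations if `TRUE`, continuation subwords are also
#'   supervised (mask 1) with their propagated tags.
#' @return `subwords` with added columns `tag` and `mask` (1 = supervised).
#' @export
align_labels <- function(subwords, word_tags, supervise_continuations = FALSE) {
  n_words <- if (NROW(subwords)) max(subwords$word_index) else 0L
  if (n_words != length(word_tags))
    stop("alignment impossible: ", n_words, " words in subword sequence but ",
         length(word_tags), " word tags")
  tag <- character(NROW(subwords))
  for (i in seq_len(NROW(subwords))) {
    wt <- word_tags[subwords$word_index[i]]
    tag[i] <- if (subwords$word_start[i]) wt
      else if (wt == "O") "O" else paste0("I-", substr(wt, 3L, nchar(wt)))
  }
  subwords$tag <- tag
  subwords$mask <- as.integer(subwords$word_start |
                                supervise_continuations)
  subwords
}

#' Write a BPE merge table to a plain-text file
#'
#' One merge per line, `left right`, rank = line number (0-based).  The base
#' alphabet can be stored alongside with `alphabet_path`.
#'
#' @param model a `bpe_model`.
#' @param path merges file path.
#' @param alphabet_path optional path for a one-symbol-per-line alphabet file.
#' @return `path`, invisibly.
#' @export
write_bpe <- function(model, path, alphabet_path = NULL) {
  writeLines(paste(model$merges$left, model$merges$right), path)
  if (!is.null(alphabet_path)) writeLines(model$alphabet, alphabet_path)
  invisible(path)
}

#' Read a BPE merge table from a plain-text file
#'
#' Mirrors [write_bpe()]; this is also the import path for externally trained
#' merge lists.  If no alphabet file is given, the alphabet is inferred from
#' the characters appearing in the merges.
#'
#' @param path merges file path.
#' @param alphabet_path optional alphabet file.
#' @return a `bpe_model`.
#' @export
read_bpe <- function(path, alphabet_path = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines)) {
    parts <- strsplit(lines, " ", fixed = TRUE)
    bad <- vapply(parts, length, integer(1)) != 2L
    if (any(bad)) stop("malformed merge line(s): ", which(bad)[1])
    merges <- data.frame(left = vapply(parts, `[`, "", 1L),
                         right = vapply(parts, `[`, "", 2L),
                         stringsAsFactors = FALSE)
  } else merges <- data.frame(left = character(), right = character(),
                              stringsAsFactors = FALSE)
  alphabet <- if (!is.null(alphabet_path))
    readLines(alphabet_path, encoding = "UTF-8")
  else sort(unique(unlist(strsplit(c(merges$left, merges$right), ""))))
  new_bpe_model(alphabet, merges)
}
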