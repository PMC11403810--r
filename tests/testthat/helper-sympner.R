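# Shared fixtures and independent oracles for the test suite.

# --- CRF enumeration oracle -------------------------------------------------
# Scores every one of the L^T paths explicitly (vectorized), independent of
# the dynamic-programming implementation.

enum_paths <- function(T_, L) as.matrix(expand.grid(rep(list(seq_len(L)), T_)))

enum_path_scores <- function(emissions, params) {
  T_ <- nrow(emissions); L <- ncol(emissions)
  paths <- enum_paths(T_, L)
  sc <- params$start[paths[, 1L]] + params$end[paths[, T_]]
  for (t in seq_len(T_)) sc <- sc + emissions[t, ][paths[, t]]
  if (T_ > 1L) for (t in seq_len(T_ - 1L))
    sc <- sc + params$trans[cbind(paths[, t], paths[, t + 1L])]
  list(paths = paths, scores = unname(sc))
}

enum_log_partition <- function(emissions, params) {
  sc <- enum_path_scores(emissions, params)$scores
  m <- max(sc)
  m + log(sum(exp(sc - m)))
}

enum_viterbi <- function(emissions, params) {
  e <- enum_path_scores(emissions, params)
  e$paths[which.max(e$scores), ]
}

# --- brute-force maximal one-to-one overlap matcher -------------------------
# Exhaustive recursion over gold assignments; feasible for <= 8 spans a side.

brute_max_matching <- function(gold, pred) {
  ng <- NROW(gold); np <- NROW(pred)
  if (!ng || !np) return(0L)
  overlaps <- lapply(seq_len(np), function(i)
    which(pmin(pred$end[i], gold$end) - pmax(pred$start[i], gold$start) > 0))
  best <- 0L
  rec <- function(i, used, count) {
    if (count + (np - i + 1L) <= best) return()
    if (i > np) { best <<- max(best, count); return() }
    for (j in overlaps[[i]]) if (!used[j]) {
      used[j] <- TRUE
      rec(i + 1L, used, count + 1L)
      used[j] <- FALSE
    }
    rec(i + 1L, used, count)
  }
  rec(1L, logical(ng), 0L)
  best
}

# Random span-set instances for evaluation fuzzing: up to `max_spans`
# disjoint spans per side in a single document.
random_span_set <- function(max_spans, doc_len = 60L, doc_id = "d1",
                            label = "SINTOMA") {
  n <- sample(0:max_spans, 1L)
  if (!n) return(empty_spans_df())
  starts <- sort(sample(0:(doc_len - 3L), n))
  out <- NULL
  prev_end <- -1L
  for (s in starts) {
    s <- max(s, prev_end + 1L)
    if (s >= doc_len - 1L) next
    e <- min(s + sample(1:6, 1L), doc_len)
    if (e <= s) next
    out <- rbind(out, data.frame(doc_id = doc_id, label = label, start = s,
                                 end = e, text = strrep("x", e - s),
                                 stringsAsFactors = FALSE))
    prev_end <- e
  }
  if (is.null(out)) empty_spans_df() else out
}

empty_spans_df <- function() data.frame(
  doc_id = character(), label = character(), start = integer(),
  end = integer(), text = character(), stringsAsFactors = FALSE)

# --- shared small corpus fixtures ------------------------------------------

fixture_corpus <- function(n_docs = 12L, ambiguity = 0, seed = 11L) {
  docs <- generate_corpus(gen_config(n_docs = n_docs,
                                     ambiguity_rate = ambiguity, seed = seed))
  sents <- unlist(lapply(docs, segment_sentences), recursive = FALSE)
  list(docs = docs, sentences = sents)
}

fixture_bpe <- function(sentences, num_merges = 120L) {
  learn_bpe(vapply(sentences, `[[`, "", "text"), num_merges)
}

# Cache for expensive trained models shared between test files run in one
# session (each file still works standalone).
.trained_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .trained_cache)) {
    assign(key, force(expr), envir = .trained_cache)
  }
  get(key, envir = .trained_cache)
}
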