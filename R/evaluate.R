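# Entity-level evaluation: strict and overlapping precision/recall/F1.
#
# Strict: a prediction counts iff (doc_id, start, end, label) match a gold
# span exactly.  Overlapping ("o_" scores): a prediction can match a gold
# span of the same document and label whose character interval intersects
# it; matching is one-to-one and *maximal* — a greedy assignment by overlap
# length (ties: earlier prediction start, then earlier gold start) is
# completed to a maximum bipartite matching via augmenting paths, so no
# instance is under-counted.  Every strict match is an overlap match, hence
# o_F1 >= F1 always.

prf <- function(tp, npred, ngold) {
  p <- if (npred > 0) tp / npred else if (ngold == 0) 1 else 0
  r <- if (ngold > 0) tp / ngold else 1
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(P = p, R = r, F1 = f)
}

span_keys <- function(spans)
  paste(spans$doc_id, spans$start, spans$end, spans$label, sep = "\x1f")

# Maximum bipartite matching size between gold and pred spans of one
# (doc, label) group, edges = intersecting intervals.  Greedy seed +
# Kuhn augmenting paths; deterministic orderings throughout.
match_overlaps <- function(gold, pred) {
  ng <- NROW(gold); np <- NROW(pred)
  if (!ng || !np) return(0L)
  ov <- matrix(0L, np, ng)
  for (i in seq_len(np)) for (j in seq_len(ng)) {
    o <- min(pred$end[i], gold$end[j]) - max(pred$start[i], gold$start[j])
    if (o > 0L) ov[i, j] <- o
  }
  edges <- which(ov > 0L, arr.ind = TRUE)
  if (!nrow(edges)) return(0L)
  w <- ov[edges]
  ord <- order(-w, pred$start[edges[, 1L]], gold$start[edges[, 2L]])
  edges <- edges[ord, , drop = FALSE]
  match_p <- integer(np)  # pred -> gold (0 = free)
  match_g <- integer(ng)  # gold -> pred
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1L]; j <- edges[e, 2L]
    if (match_p[i] == 0L && match_g[j] == 0L) {
      match_p[i] <- j; match_g[j] <- i
    }
  }
  adj <- lapply(seq_len(np), function(i) {
    js <- which(ov[i, ] > 0L)
    js[order(-ov[i, js], gold$start[js])]
  })
  try_augment <- function(i, env) {
    for (j in adj[[i]]) {
      if (env$seen[j]) next
      env$seen[j] <- TRUE
      if (match_g[j] == 0L || try_augment(match_g[j], env)) {
        match_g[j] <<- i
        match_p[i] <<- j
        return(TRUE)
      }
    }
    FALSE
  }
  for (i in order(pred$start)) {
    if (match_p[i] == 0L) {
      env <- new.env(parent = emptyenv())
      env$seen <- logical(ng)
      try_augment(i, env)
    }
  }
  sum(match_p > 0L)
}

#' Strict and overlapping entity-level evaluation
#'
#' @param gold,pred span data.frames (`doc_id`, `label`, `start`, `end`,
#'   `text`); duplicated spans are collapsed before scoring.
#' @return an `eval_report`: strict `P`, `R`, `F1`, overlapping `o_P`,
#'   `o_R`, `o_F1`, and the underlying `counts`.  When both sets are empty
#'   all metrics are 1 by convention; with no predictions against non-empty
#'   gold, precision is 0.
#' @export
ner_evaluate <- function(gold, pred) {
  gold <- as_span_table(gold); pred <- as_span_table(pred)
  gold <- gold[!duplicated(span_keys(gold)), , drop = FALSE]
  pred <- pred[!duplicated(span_keys(pred)), , drop = FALSE]
  ng <- NROW(gold); np <- NROW(pred)
  tp_strict <- sum(span_keys(pred) %in% span_keys(gold))
  groups <- unique(rbind(gold[c("doc_id", "label")], pred[c("doc_id", "label")]))
  tp_overlap <- 0L
  for (k in seq_len(NROW(groups))) {
    g <- gold[gold$doc_id == groups$doc_id[k] & gold$label == groups$label[k], ]
    p <- pred[pred$doc_id == groups$doc_id[k] & pred$label == groups$label[k], ]
    tp_overlap <- tp_overlap + match_overlaps(g, p)
  }
  s <- prf(tp_strict, np, ng)
  o <- prf(tp_overlap, np, ng)
  structure(list(P = s[["P"]], R = s[["R"]], F1 = s[["F1"]],
                 o_P = o[["P"]], o_R = o[["R"]], o_F1 = o[["F1"]],
                 counts = list(
                   strict = c(TP = tp_strict, FP = np - tp_strict,
                              FN = ng - tp_strict),
                   overlap = c(TP = tp_overlap, FP = np - tp_overlap,
                               FN = ng - tp_overlap))),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 4, ...) {
  m <- round(c(P = x$P, R = x$R, F1 = x$F1,
               o_P = x$o_P, o_R = x$o_R, o_F1 = x$o_F1), digits)
  print(m)
  invisible(x)
}

#' Aggregate a metric over repeated runs
#'
#' @param values numeric vector of per-run metric values (length >= 1).
#' @return list `mean`, `sd` (sample SD, n-1 denominator; 0 for a single
#'   value), `min`, `max`.
#' @export
aggregate_runs <- function(values) {
  if (!length(values)) stop("no values to aggregate")
  list(mean = mean(values),
       sd = if (length(values) > 1L) stats::sd(values) else 0,
       min = min(values), max = max(values))
}

#' Format run aggregates as a results table
#'
#' One row per configuration, columns `Mean (SD)`, `Min`, `Max` in percent,
#' matching the conventional presentation of multi-seed NER results.
#'
#' @param runs named list: configuration name -> numeric vector of per-seed
#'   F1 values (fractions in \[0, 1\]).
#' @return data.frame with character columns.
#' @export
format_run_table <- function(runs) {
  rows <- lapply(names(runs), function(nm) {
    a <- aggregate_runs(runs[[nm]] * 100)
    data.frame(configuration = nm,
               `Mean (SD)` = sprintf("%.2f ±%.2f", a$mean, a$sd),
               Min = sprintf("%.2f", a$min), Max = sprintf("%.2f", a$max),
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
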