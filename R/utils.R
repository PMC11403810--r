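# Internal numerical helpers shared across modules.

#' Numerically stable log-sum-exp
#'
#' @param x numeric vector.
#' @return `log(sum(exp(x)))` computed without overflow.
#' @keywords internal
#' @noRd
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)  # all -Inf
  m + log(sum(exp(x - m)))
}

# Row-wise softmax of a matrix, stable.
softmax_rows <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

# Deterministic RNG scoping: evaluate `expr` under `seed` without disturbing
# the caller's RNG stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Empty span table with the canonical column layout used everywhere.
empty_spans <- function() {
  data.frame(doc_id = character(), label = character(),
             start = integer(), end = integer(), text = character(),
             stringsAsFactors = FALSE)
}

# Validate and canonicalize a span data.frame (ordering, types).
as_span_table <- function(spans) {
  if (is.null(spans) || NROW(spans) == 0L) return(empty_spans())
  need <- c("doc_id", "label", "start", "end", "text")
  missing_cols <- setdiff(need, names(spans))
  if (length(missing_cols))
    stop("span table lacks columns: ", paste(missing_cols, collapse = ", "))
  spans <- spans[need]
  spans$start <- as.integer(spans$start)
  spans$end <- as.integer(spans$end)
  spans$doc_id <- as.character(spans$doc_id)
  spans$label <- as.character(spans$label)
  spans$text <- as.character(spans$text)
  if (any(spans$start < 0L) || any(spans$end <= spans$start))
    stop("invalid span interval: require 0 <= start < end")
  spans[order(spans$doc_id, spans$start, spans$end, spans$label), , drop = FALSE]
}
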