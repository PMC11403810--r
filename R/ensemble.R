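# Majority-vote ensembling of span predictions.
#
# A span is emitted iff at least `threshold` member models predicted the
# identical span (same document, start, end and label).  The default
# threshold is the strict majority floor(n/2) + 1, which for even pools
# (6, 12 models) means 4-of-6 and 7-of-12.  If emitted spans overlap, the
# higher-vote span wins; vote ties go to the longer span, then to the
# earlier start — deterministic and documented.

#' Majority vote over span predictions
#'
#' @param predictions list of span data.frames, one per member model, all
#'   over the same document set.
#' @param threshold minimum number of votes; default strict majority
#'   `floor(n/2) + 1`.
#' @return span data.frame of the voted, overlap-resolved, offset-sorted
#'   spans, with a `votes` attribute column removed (vote counts are used
#'   only for resolution).
#' @export
majority_vote <- function(predictions, threshold = NULL) {
  n <- length(predictions)
  if (!n) stop("no predictions to ensemble")
  if (is.null(threshold)) threshold <- n %/% 2L + 1L
  if (threshold < 1L || threshold > n)
    stop("threshold must be in [1, ", n, "]")
  tabs <- lapply(predictions, function(p) {
    p <- as_span_table(p)
    p[!duplicated(span_keys(p)), , drop = FALSE]  # one vote per model
  })
  all_spans <- do.call(rbind, tabs)
  if (!NROW(all_spans)) return(empty_spans())
  key <- span_keys(all_spans)
  votes <- table(key)
  keep_keys <- names(votes)[as.integer(votes) >= threshold]
  out <- all_spans[!duplicated(key) & key %in% keep_keys, , drop = FALSE]
  if (!NROW(out)) return(empty_spans())
  out$votes <- as.integer(votes[span_keys(out)])
  # resolve overlaps: higher votes, then longer span, then earlier start
  out <- out[order(out$doc_id, -out$votes, -(out$end - out$start), out$start), ]
  keep <- logical(NROW(out))
  for (d in unique(out$doc_id)) {
    idx <- which(out$doc_id == d)
    taken <- matrix(numeric(0), ncol = 2L)
    for (i in idx) {
      s <- out$start[i]; e <- out$end[i]
      clash <- NROW(taken) && any(taken[, 1L] < e & s < taken[, 2L])
      if (!clash) {
        keep[i] <- TRUE
        taken <- rbind(taken, c(s, e))
      }
    }
  }
  out <- out[keep, setdiff(names(out), "votes"), drop = FALSE]
  as_span_table(out)
}

#' Pool prediction groups into one voter list
#'
#' Flattens groups of member predictions (e.g. the three seeds of two model
#' configurations) into a single list, preserving each model's identity for
#' vote counting.
#'
#' @param ... lists of span data.frames (one list per configuration group).
#' @return a flat list of span data.frames.
#' @export
pool_predictions <- function(...) {
  groups <- list(...)
  if (!length(groups)) stop("need at least one prediction group")
  do.call(c, groups)
}

#' File-level ensembling of standoff predictions
#'
#' Reads several standoff TSV files, votes, and writes the result, so
#' ensembling works on any systems' outputs.
#'
#' @param paths character vector of input standoff TSVs.
#' @param out_path output TSV.
#' @param threshold as in [majority_vote()].
#' @return the voted span data.frame, invisibly.
#' @export
ensemble_files <- function(paths, out_path, threshold = NULL) {
  read_tsv_spans <- function(p) {
    df <- utils::read.delim(p, sep = "\t", quote = "",
                            stringsAsFactors = FALSE, encoding = "UTF-8")
    names(df) <- sub("^start_span$", "start", names(df))
    names(df) <- sub("^end_span$", "end", names(df))
    names(df) <- sub("^filename$", "doc_id", names(df))
    as_span_table(df)
  }
  voted <- majority_vote(lapply(paths, read_tsv_spans), threshold)
  write_standoff(voted, out_path)
  invisible(voted)
}
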