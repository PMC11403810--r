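# Documents, standoff annotations and BIO tag sequences.
#
# Offsets are 0-based and end-exclusive throughout (BRAT-style standoff
# convention): a span [start, end) selects text characters start+1..end in
# R's 1-based substr().

substr0 <- function(text, start, end) substr(text, start + 1L, end)

#' Construct a document with standoff entity spans
#'
#' A document couples an identifier, its full text and a table of entity
#' spans.  Every span must reproduce the document substring it annotates.
#'
#' @param doc_id character scalar identifier.
#' @param text full document text.
#' @param spans a data.frame with columns `doc_id`, `label`, `start`, `end`,
#'   `text`; offsets 0-based, end-exclusive.  May be `NULL` for no entities.
#' @return an object of class `sym_document`.
#' @export
sym_document <- function(doc_id, text, spans = NULL) {
  spans <- as_span_table(spans)
  if (NROW(spans)) {
    if (!all(spans$doc_id == doc_id))
      stop("document '", doc_id, "': spans carry a different doc_id")
    check_span_text(spans, text, doc_id)
  }
  structure(list(doc_id = doc_id, text = text, spans = spans),
            class = "sym_document")
}

check_span_text <- function(spans, text, doc_id) {
  n <- nchar(text)
  for (i in seq_len(NROW(spans))) {
    s <- spans[i, ]
    if (s$end > n)
      stop("document '", doc_id, "' row ", i, ": span [", s$start, ",",
           s$end, ") exceeds document length ", n)
    got <- substr0(text, s$start, s$end)
    if (got != s$text)
      stop("document '", doc_id, "' row ", i, ": span text ", dQuote(s$text),
           " does not match document substring ", dQuote(got))
  }
  invisible(TRUE)
}

#' @export
print.sym_document <- function(x, ...) {
  cat("<sym_document> ", x$doc_id, ": ", nchar(x$text), " chars, ",
      NROW(x$spans), " spans\n", sep = "")
  invisible(x)
}

#' Read standoff annotations over a set of documents
#'
#' Parses a SympTEMIST-style tab-separated annotation table (columns
#' `filename`, `label`, `start_span`, `end_span`, `text`) and attaches each
#' row to its document, verifying the substring invariant.  No silent repair
#' is attempted: any offset or text mismatch is an error naming the document
#' and row.
#'
#' @param ann either a path to a TSV file or a data.frame already holding the
#'   five columns.
#' @param documents named character vector mapping `doc_id` to document text.
#' @return a named list of [sym_document] objects, one per entry of
#'   `documents` (documents without annotations get empty span tables).
#' @export
read_standoff <- function(ann, documents) {
  if (is.character(ann) && length(ann) == 1L) {
    ann <- utils::read.delim(ann, header = TRUE, sep = "\t",
                             quote = "", stringsAsFactors = FALSE,
                             colClasses = "character", encoding = "UTF-8")
  }
  if (NROW(ann)) {
    names(ann) <- sub("^start_span$", "start", names(ann))
    names(ann) <- sub("^end_span$", "end", names(ann))
    names(ann) <- sub("^filename$", "doc_id", names(ann))
    need <- c("doc_id", "label", "start", "end", "text")
    if (!all(need %in% names(ann)))
      stop("annotation table needs columns filename/label/start_span/end_span/text")
    bad <- setdiff(unique(ann$doc_id), names(documents))
    if (length(bad))
      stop("annotations reference unknown documents: ",
           paste(bad, collapse = ", "))
  }
  out <- lapply(names(documents), function(id) {
    spans <- if (NROW(ann)) ann[ann$doc_id == id, , drop = FALSE] else NULL
    sym_document(id, documents[[id]], spans)
  })
  names(out) <- names(documents)
  out
}

#' Write standoff annotations to a TSV file
#'
#' @param docs a list of [sym_document] objects or a span data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_standoff <- function(docs, path) {
  spans <- if (is.data.frame(docs)) as_span_table(docs) else
    as_span_table(do.call(rbind, lapply(docs, `[[`, "spans")))
  out <- data.frame(filename = spans$doc_id, label = spans$label,
                    start_span = spans$start, end_span = spans$end,
                    text = spans$text, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write documents as one UTF-8 .txt file per doc_id
#'
#' @param docs list of [sym_document].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_documents <- function(docs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (d in docs) {
    con <- file(file.path(dir, paste0(d$doc_id, ".txt")), "wb")
    writeBin(charToRaw(enc2utf8(d$text)), con)
    close(con)
  }
  invisible(dir)
}

#' Read a directory of .txt documents
#'
#' @param dir directory holding `<doc_id>.txt` files.
#' @return named character vector doc_id -> text, suitable for
#'   [read_standoff()].
#' @export
read_documents <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  txt <- vapply(files, function(f) {
    raw <- readBin(f, "raw", file.info(f)$size)
    x <- rawToChar(raw); Encoding(x) <- "UTF-8"; x
  }, character(1))
  names(txt) <- sub("\\.txt$", "", basename(files))
  txt
}

#' Rule-based sentence boundary proposer
#'
#' Proposes 0-based offsets at which a new sentence starts: after a run of
#' `.`, `!` or `?` followed by whitespace and an uppercase (or inverted
#' punctuation) character.  A statistical sentence splitter can be swapped in
#' via the `splitter` argument of [segment_sentences()].
#'
#' @param text document text.
#' @return integer vector of candidate boundary offsets (possibly empty).
#' @export
default_splitter <- function(text) {
  m <- gregexpr("[.!?]+\\s+(?=[\\p{Lu}¿¡])", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(integer())
  as.integer(m + attr(m, "match.length") - 1L)  # 0-based offset of next char
}

#' Segment a document into sentences without splitting entities
#'
#' Candidate boundaries proposed by `splitter` that fall strictly inside an
#' entity span are discarded, so no entity ever crosses a sentence boundary.
#' Sentences tile the document exactly: concatenating their texts in order
#' reconstructs the document, and character and entity counts are conserved.
#'
#' @param doc a [sym_document].
#' @param splitter function `text -> integer offsets`; defaults to
#'   [default_splitter()].
#' @return list of sentence objects: `list(doc_id, start, end, text, spans)`
#'   with spans re-based to sentence-local offsets.
#' @export
segment_sentences <- function(doc, splitter = default_splitter) {
  n <- nchar(doc$text)
  bounds <- sort(unique(as.integer(splitter(doc$text))))
  bounds <- bounds[bounds > 0L & bounds < n]
  if (NROW(doc$spans)) {
    inside <- vapply(bounds, function(b)
      any(doc$spans$start < b & b < doc$spans$end), logical(1))
    bounds <- bounds[!inside]
  }
  cuts <- c(0L, bounds, n)
  out <- vector("list", length(cuts) - 1L)
  for (i in seq_along(out)) {
    s <- cuts[i]; e <- cuts[i + 1L]
    spans <- doc$spans
    if (NROW(spans)) {
      spans <- spans[spans$start >= s & spans$end <= e, , drop = FALSE]
      spans$start <- spans$start - s
      spans$end <- spans$end - s
    } else spans <- empty_spans()
    out[[i]] <- structure(
      list(doc_id = doc$doc_id, start = s, end = e,
           text = substr0(doc$text, s, e), spans = spans),
      class = "sym_sentence")
  }
  out
}

#' Word tokenizer with character offsets
#'
#' Splits text into maximal alphanumeric runs and single punctuation
#' characters, skipping whitespace, and reports each token's 0-based
#' end-exclusive character interval.
#'
#' @param text input string.
#' @return data.frame with columns `token`, `start`, `end`.
#' @export
word_tokenize <- function(text) {
  m <- gregexpr("[\\p{L}\\p{N}]+|[^\\p{L}\\p{N}\\s]", text, perl = TRUE)[[1]]
  if (m[1] == -1L)
    return(data.frame(token = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  start <- as.integer(m) - 1L
  end <- start + attr(m, "match.length")
  data.frame(token = substring(text, start + 1L, end),
             start = start, end = end, stringsAsFactors = FALSE)
}

#' BIO-encode a sentence's entity spans over a tokenization
#'
#' The first token overlapping a span receives `B-<label>`, later tokens of
#' the same span `I-<label>`, all others `O`.  Overlapping gold spans and
#' entity boundaries that fall strictly inside a token are rejected: BIO
#' cannot represent either.
#'
#' @param sentence a sentence object from [segment_sentences()] (or any list
#'   with `text` and sentence-local `spans`).
#' @param tokens data.frame with `start`/`end` token intervals
#'   (sentence-local); defaults to [word_tokenize()] of the sentence text.
#' @return data.frame with columns `tag`, `start`, `end` (one row per token).
#' @export
bio_encode <- function(sentence, tokens = word_tokenize(sentence$text)) {
  spans <- sentence$spans
  tags <- rep("O", NROW(tokens))
  if (NROW(spans)) {
    spans <- spans[order(spans$start), , drop = FALSE]
    if (NROW(spans) > 1L &&
        any(spans$start[-1L] < spans$end[-NROW(spans)]))
      stop("overlapping gold spans cannot be BIO-encoded (doc '",
           spans$doc_id[1], "')")
    for (i in seq_len(NROW(spans))) {
      s <- spans[i, ]
      inside_tok <- (tokens$start < s$start & s$start < tokens$end) |
        (tokens$start < s$end & s$end < tokens$end)
      if (any(inside_tok))
        stop("entity boundary [", s$start, ",", s$end,
             ") falls strictly inside a token; tokenization is not ",
             "offset-compatible")
      hit <- which(tokens$start < s$end & tokens$end > s$start)
      if (length(hit)) {
        tags[hit[1]] <- paste0("B-", s$label)
        if (length(hit) > 1L) tags[hit[-1L]] <- paste0("I-", s$label)
      }
    }
  }
  data.frame(tag = tags, start = tokens$start, end = tokens$end,
             stringsAsFactors = FALSE)
}

#' Decode a BIO tag sequence back into entity spans
#'
#' Maximal `B, I...I` runs of one label become spans over the tag alignment
#' intervals.  The decoder tolerates invalid sequences (as emitted by
#' per-position argmax models): an `I` tag with no compatible predecessor is
#' promoted to `B` (orphan repair), which favours recall.
#'
#' @param tags data.frame from [bio_encode()] (columns `tag`, `start`, `end`),
#'   or a character vector with `starts`/`ends` given separately.
#' @param text sentence text used to fill the span surface strings.
#' @param doc_id identifier stamped on the produced spans.
#' @return span data.frame (`doc_id`, `label`, `start`, `end`, `text`) in
#'   sentence-local offsets.
#' @export
bio_decode <- function(tags, text, doc_id = "doc") {
  if (is.character(tags)) stop("pass the data.frame produced by bio_encode()")
  tag <- tags$tag
  out <- list()
  cur_label <- NULL; cur_start <- NULL; cur_end <- NULL
  flush <- function() {
    if (!is.null(cur_label))
      out[[length(out) + 1L]] <<- data.frame(
        doc_id = doc_id, label = cur_label, start = cur_start, end = cur_end,
        text = substr0(text, cur_start, cur_end), stringsAsFactors = FALSE)
    cur_label <<- NULL
  }
  for (i in seq_along(tag)) {
    t <- tag[i]
    if (t == "O") { flush(); next }
    kind <- substr(t, 1L, 1L)
    label <- substr(t, 3L, nchar(t))
    if (kind == "B" || is.null(cur_label) || label != cur_label) {
      flush()  # B starts a span; orphan/label-switching I promoted to B
      cur_label <- label; cur_start <- tags$start[i]
    }
    cur_end <- tags$end[i]
  }
  flush()
  if (!length(out)) return(empty_spans())
  do.call(rbind, out)
}

#' Deterministic train/validation/test split
#'
#' @param sentences list of sentences (or any list).
#' @param sizes integer vector `c(train, valid, test)` summing to
#'   `length(sentences)`.
#' @param seed RNG seed; the same seed always yields the same partition.
#' @return list with elements `train`, `valid`, `test`.
#' @export
split_dataset <- function(sentences, sizes, seed = 1L) {
  n <- length(sentences)
  if (length(sizes) != 3L || sum(sizes) != n)
    stop("sizes must be c(train, valid, test) summing to ", n,
         " (got sum ", sum(sizes), ")")
  perm <- with_seed(seed, sample.int(n))
  idx <- split(perm, rep(c("train", "valid", "test"), times = sizes))
  list(train = sentences[sort(idx$train)],
       valid = sentences[sort(idx$valid)],
       test = sentences[sort(idx$test)])
}

#' Export sentences as CoNLL-style token/tag lines
#'
#' One `token<TAB>tag` line per token, blank line between sentences.
#'
#' @param sentences list of sentence objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_conll <- function(sentences, path) {
  lines <- character()
  for (s in sentences) {
    toks <- word_tokenize(s$text)
    tags <- bio_encode(s, toks)
    lines <- c(lines, paste(toks$token, tags$tag, sep = "\t"), "")
  }
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}
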