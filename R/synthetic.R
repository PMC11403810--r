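# Seeded synthetic corpus generator.
#
# Documents are sequences of sentences assembled from a distractor
# vocabulary, with multi-word symptom-like gazetteer phrases inserted as
# labelled entities at random positions.  There is no grammar model: the NER
# stack only needs offset-consistent structure.  The `ambiguity_rate`
# controls how often single gazetteer *tokens* also appear as unlabelled
# distractor text, which makes context-free memorization harder and creates
# the label ambiguity under which CRF transitions and regularization earn
# their keep.

#' Default symptom-like gazetteer
#'
#' Spanish-flavoured multi-word phrases (accented characters included) so
#' that tokenization and subword segmentation face realistic input; the
#' language itself is cosmetic.
#'
#' @return character vector of phrases.
#' @export
default_gazetteer <- function() c(
  "dolor torácico", "tos seca", "fiebre alta", "cefalea intensa",
  "disnea de esfuerzo", "dolor abdominal difuso", "náuseas matutinas",
  "pérdida de peso", "visión borrosa", "astenia marcada",
  "palpitaciones frecuentes", "edema maleolar")

#' Default distractor vocabulary
#'
#' Function words and neutral clinical filler tokens used to assemble
#' non-entity text.
#'
#' @return character vector of words.
#' @export
default_distractors <- function() c(
  "el", "la", "paciente", "presenta", "refiere", "desde", "hace", "dias",
  "sin", "antecedentes", "de", "interes", "tras", "ingreso", "se", "observa",
  "mejoria", "clinica", "con", "tratamiento", "habitual", "exploracion",
  "normal", "valores", "dentro", "del", "rango", "durante", "consulta",
  "previa", "semana", "control")

#' Synthetic corpus configuration
#'
#' @param n_docs number of documents.
#' @param sentences_per_doc sentences in each document.
#' @param words_range min/max distractor word slots per sentence.
#' @param gazetteer entity phrases (must be non-empty when
#'   `entity_rate > 0`).
#' @param entity_rate probability that a sentence carries one entity.
#' @param distractors non-entity vocabulary.
#' @param ambiguity_rate probability that a distractor slot is filled with a
#'   single gazetteer token emitted as *non-entity* text.
#' @param label entity class name.
#' @param seed RNG seed; generation is byte-identical given the seed.
#' @return a `gen_config` list.
#' @export
gen_config <- function(n_docs = 50L, sentences_per_doc = 10L,
                       words_range = c(6L, 12L),
                       gazetteer = default_gazetteer(), entity_rate = 0.5,
                       distractors = default_distractors(),
                       ambiguity_rate = 0, label = "SINTOMA", seed = 1L) {
  stopifnot(entity_rate >= 0, entity_rate <= 1,
            ambiguity_rate >= 0, ambiguity_rate <= 1)
  if (entity_rate > 0 && !length(gazetteer))
    stop("entity_rate > 0 requires a non-empty gazetteer")
  phrase_len <- if (length(gazetteer))
    max(lengths(strsplit(gazetteer, " "))) else 0L
  if (phrase_len > words_range[2])
    stop("impossible config: longest gazetteer phrase (", phrase_len,
         " words) exceeds the sentence word budget (", words_range[2], ")")
  structure(list(n_docs = as.integer(n_docs),
                 sentences_per_doc = as.integer(sentences_per_doc),
                 words_range = as.integer(words_range),
                 gazetteer = gazetteer, entity_rate = entity_rate,
                 distractors = distractors, ambiguity_rate = ambiguity_rate,
                 label = label, seed = as.integer(seed)),
            class = "gen_config")
}

cap_first <- function(w) {
  paste0(toupper(substr(w, 1L, 1L)), substr(w, 2L, nchar(w)))
}

#' Generate a synthetic annotated corpus
#'
#' Deterministic given `cfg$seed`.  Optionally writes the exact on-disk
#' layout the corpus readers consume: one `.txt` per document plus a
#' standoff TSV.
#'
#' @param cfg a [gen_config()].
#' @param dir if non-NULL, write `<dir>/txt/<doc_id>.txt` files and
#'   `<dir>/gold.tsv`.
#' @return list of [sym_document] objects.
#' @export
generate_corpus <- function(cfg, dir = NULL) {
  gaz_tokens <- unique(unlist(strsplit(cfg$gazetteer, " ")))
  docs <- with_seed(cfg$seed, {
    lapply(seq_len(cfg$n_docs), function(di) {
      doc_id <- sprintf("doc%03d", di)
      text <- ""
      spans <- list()
      for (si in seq_len(cfg$sentences_per_doc)) {
        n_w <- sample(cfg$words_range[1]:cfg$words_range[2], 1L)
        words <- sample(cfg$distractors, n_w, replace = TRUE)
        if (cfg$ambiguity_rate > 0) {
          swap <- stats::runif(n_w) < cfg$ambiguity_rate
          words[swap] <- sample(gaz_tokens, sum(swap), replace = TRUE)
        }
        has_entity <- stats::runif(1) < cfg$entity_rate
        ent_pos <- if (has_entity) sample.int(n_w + 1L, 1L) else NA_integer_
        phrase <- if (has_entity) sample(cfg$gazetteer, 1L) else NULL
        # assemble the sentence, tracking the entity's character interval
        if (nzchar(text)) text <- paste0(text, " ")
        sent_words <- character(); ent_start <- NA_integer_
        slot <- 1L
        for (k in seq_len(n_w + as.integer(has_entity))) {
          is_ent <- has_entity && k == ent_pos
          w <- if (is_ent) phrase else { wd <- words[slot]; slot <- slot + 1L; wd }
          if (k == 1L) w <- cap_first(w)
          prefix_len <- nchar(text) + sum(nchar(sent_words)) +
            length(sent_words)  # separators already emitted
          if (is_ent) ent_start <- prefix_len
          sent_words <- c(sent_words, w)
          if (is_ent) {
            spans[[length(spans) + 1L]] <- data.frame(
              doc_id = doc_id, label = cfg$label, start = ent_start,
              end = ent_start + nchar(w), text = w, stringsAsFactors = FALSE)
          }
        }
        text <- paste0(text, paste(sent_words, collapse = " "), ".")
      }
      spans <- if (length(spans)) do.call(rbind, spans) else NULL
      sym_document(doc_id, text, spans)
    })
  })
  names(docs) <- vapply(docs, `[[`, "", "doc_id")
  if (!is.null(dir)) {
    write_documents(docs, file.path(dir, "txt"))
    write_standoff(docs, file.path(dir, "gold.tsv"))
  }
  docs
}

#' Corrupt gold annotations into pseudo-predictions with known error rates
#'
#' Used to give evaluation tests inputs with known expected precision and
#' recall: each gold span is dropped with probability `drop_rate`; surviving
#' spans are shifted by a non-zero offset of magnitude at most
#' `offset_noise` (always strictly less than the span length, so the shifted
#' span still overlaps the original); spurious spans are added at a rate of
#' `spurious_rate` per gold span.
#'
#' @param docs list of [sym_document] (source of gold spans and text bounds).
#' @param offset_noise maximum absolute character shift (0 = exact offsets).
#' @param drop_rate probability of deleting a gold span.
#' @param spurious_rate expected spurious spans per gold span.
#' @param seed RNG seed.
#' @return span data.frame of corrupted predictions.
#' @export
corrupt_predictions <- function(docs, offset_noise = 0L, drop_rate = 0,
                                spurious_rate = 0, seed = 1L) {
  stopifnot(drop_rate >= 0, drop_rate <= 1, spurious_rate >= 0)
  with_seed(seed, {
    out <- list()
    for (d in docs) {
      n <- nchar(d$text)
      sp <- d$spans
      if (NROW(sp)) {
        keep <- stats::runif(NROW(sp)) >= drop_rate
        sp <- sp[keep, , drop = FALSE]
        for (i in seq_len(NROW(sp))) {
          len <- sp$end[i] - sp$start[i]
          m <- min(offset_noise, len - 1L)
          if (offset_noise > 0L && m >= 1L) {
            delta <- sample(c(-(m:1), 1:m), 1L)
            s2 <- max(0L, min(sp$start[i] + delta, n - len))
            sp$start[i] <- s2
            sp$end[i] <- s2 + len
            sp$text[i] <- substr0(d$text, sp$start[i], sp$end[i])
          }
        }
        n_spur <- stats::rbinom(1L, NROW(d$spans),
                                min(spurious_rate, 1))
        if (n_spur > 0L && n > 12L) {
          for (k in seq_len(n_spur)) {
            len <- sample(4:10, 1L)
            s <- sample.int(n - len, 1L) - 1L
            out[[length(out) + 1L]] <- data.frame(
              doc_id = d$doc_id, label = d$spans$label[1], start = s,
              end = s + len, text = substr0(d$text, s, s + len),
              stringsAsFactors = FALSE)
          }
        }
        if (NROW(sp)) out[[length(out) + 1L]] <- sp
      }
    }
    as_span_table(do.call(rbind, out))
  })
}
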