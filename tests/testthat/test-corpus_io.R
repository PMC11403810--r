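test_that("standoff reading enforces the substring invariant", {
  txt <- c(d1 = "dolor torácico agudo", d2 = "sin hallazgos")
  ann <- data.frame(filename = "d1", label = "SINTOMA", start_span = 0,
                    end_span = 5, text = "dolor", stringsAsFactors = FALSE)
  docs <- read_standoff(ann, txt)
  expect_length(docs, 2L)
  expect_equal(docs$d1$spans$start, 0L)
  expect_equal(docs$d1$spans$end, 5L)
  expect_equal(NROW(docs$d2$spans), 0L)

  # mismatching surface text is an error naming the document, not repaired
  bad <- ann; bad$text <- "tos"
  expect_error(read_standoff(bad, txt), "d1")
  # offsets beyond the document
  far <- ann; far$start_span <- 50; far$end_span <- 55
  expect_error(read_standoff(far, txt), "exceeds")
  # unknown document id
  unk <- ann; unk$filename <- "nope"
  expect_error(read_standoff(unk, txt), "unknown")
})

test_that("standoff writer and reader are inverse on generated corpora", {
  docs <- generate_corpus(gen_config(n_docs = 4L, seed = 5L))
  dir <- withr::local_tempdir()
  write_documents(docs, file.path(dir, "txt"))
  write_standoff(docs, file.path(dir, "gold.tsv"))
  docs2 <- read_standoff(file.path(dir, "gold.tsv"),
                         read_documents(file.path(dir, "txt")))
  expect_equal(names(docs2), names(docs))
  for (id in names(docs)) {
    expect_identical(docs2[[id]]$text, docs[[id]]$text)
    expect_equal(docs2[[id]]$spans, docs[[id]]$spans,
                 ignore_attr = "row.names")
  }
})

test_that("sentence boundaries inside entities are discarded", {
  txt <- paste0("Aaaa bbb. Ccc ddd. Eee fff.")
  # entity crossing the first proposed boundary at offset 10
  sp <- data.frame(doc_id = "d", label = "SINTOMA", start = 5L, end = 13L,
                   text = substr(txt, 6, 13), stringsAsFactors = FALSE)
  doc <- sym_document("d", txt, sp)
  fake_splitter <- function(text) c(10L, 19L)
  sents <- segment_sentences(doc, fake_splitter)
  expect_length(sents, 2L)          # one boundary dropped, one kept
  expect_equal(sents[[2]]$start, 19L)
  # the entity survives intact in the merged first sentence
  expect_equal(NROW(sents[[1]]$spans), 1L)
  expect_equal(sents[[1]]$spans$start, 5L)

  # with no entities both boundaries cut
  doc2 <- sym_document("d", txt)
  expect_length(segment_sentences(doc2, fake_splitter), 3L)
})

test_that("segmentation conserves characters and entities", {
  docs <- generate_corpus(gen_config(n_docs = 6L, seed = 9L))
  for (doc in docs) {
    sents <- segment_sentences(doc)
    expect_identical(paste(vapply(sents, `[[`, "", "text"), collapse = ""),
                     doc$text)
    expect_equal(sum(vapply(sents, function(s) NROW(s$spans), integer(1))),
                 NROW(doc$spans))
    # intervals are disjoint, ordered, and spans re-based correctly
    starts <- vapply(sents, `[[`, integer(1), "start")
    ends <- vapply(sents, `[[`, integer(1), "end")
    expect_true(all(starts[-1L] == ends[-length(ends)]))
    for (s in sents) {
      for (i in seq_len(NROW(s$spans)))
        expect_identical(substr(s$text, s$spans$start[i] + 1L, s$spans$end[i]),
                         s$spans$text[i])
    }
  }
})

test_that("BIO encoding follows the scheme and rejects impossible input", {
  txt <- "tos seca y fiebre"
  sp <- data.frame(doc_id = "d", label = "SINTOMA",
                   start = c(0L, 11L), end = c(8L, 17L),
                   text = c("tos seca", "fiebre"), stringsAsFactors = FALSE)
  s <- list(doc_id = "d", start = 0L, end = nchar(txt), text = txt, spans = sp)
  tags <- bio_encode(s)
  expect_equal(tags$tag, c("B-SINTOMA", "I-SINTOMA", "O", "B-SINTOMA"))

  # two adjacent one-token spans give B, B
  sp2 <- data.frame(doc_id = "d", label = "SINTOMA",
                    start = c(0L, 4L), end = c(3L, 8L),
                    text = c("tos", "seca"), stringsAsFactors = FALSE)
  s2 <- list(doc_id = "d", start = 0L, end = nchar(txt), text = txt, spans = sp2)
  expect_equal(bio_encode(s2)$tag[1:2], c("B-SINTOMA", "B-SINTOMA"))

  # no spans -> all O
  s3 <- list(doc_id = "d", start = 0L, end = nchar(txt), text = txt,
             spans = NULL)
  expect_true(all(bio_encode(s3)$tag == "O"))

  # overlapping gold spans rejected
  spov <- data.frame(doc_id = "d", label = "SINTOMA",
                     start = c(0L, 4L), end = c(8L, 10L),
                     text = c("tos seca", "seca y"), stringsAsFactors = FALSE)
  sov <- list(doc_id = "d", start = 0L, end = nchar(txt), text = txt,
              spans = spov)
  expect_error(bio_encode(sov), "overlapping")

  # entity boundary strictly inside a token rejected
  spin <- data.frame(doc_id = "d", label = "SINTOMA", start = 0L, end = 2L,
                     text = "to", stringsAsFactors = FALSE)
  sin_ <- list(doc_id = "d", start = 0L, end = nchar(txt), text = txt,
               spans = spin)
  expect_error(bio_encode(sin_), "inside a token")
})

test_that("bio_decode inverts bio_encode and repairs orphan I-tags", {
  # round trip on many generated sentences
  fx <- fixture_corpus(n_docs = 6L, seed = 21L)
  for (s in fx$sentences) {
    dec <- bio_decode(bio_encode(s), s$text, s$doc_id)
    expect_equal(dec[c("start", "end", "label", "text")],
                 as.data.frame(s$spans[c("start", "end", "label", "text")]),
                 ignore_attr = "row.names")
  }

  # (B, I, O) over intervals -> one span covering the first two tokens
  tags <- data.frame(tag = c("B-S", "I-S", "O"),
                     start = c(0L, 4L, 9L), end = c(3L, 8L, 12L))
  sp <- bio_decode(tags, "abc defg hij", "d")
  expect_equal(sp$start, 0L); expect_equal(sp$end, 8L)

  # orphan I promoted to B
  tags2 <- data.frame(tag = c("O", "I-S"), start = c(0L, 4L), end = c(3L, 8L))
  sp2 <- bio_decode(tags2, "abc defg", "d")
  expect_equal(NROW(sp2), 1L)
  expect_equal(sp2$start, 4L)

  # all O -> empty
  tags3 <- data.frame(tag = c("O", "O"), start = c(0L, 4L), end = c(3L, 8L))
  expect_equal(NROW(bio_decode(tags3, "abc defg", "d")), 0L)
})

test_that("split_dataset is deterministic, exhaustive and disjoint", {
  sents <- as.list(seq_len(10L))
  a <- split_dataset(sents, c(8L, 1L, 1L), seed = 1L)
  b <- split_dataset(sents, c(8L, 1L, 1L), seed = 1L)
  expect_identical(a, b)
  all_idx <- unlist(c(a$train, a$valid, a$test))
  expect_setequal(all_idx, 1:10)
  expect_equal(lengths(a), c(train = 8L, valid = 1L, test = 1L))

  c_ <- split_dataset(sents, c(0L, 0L, 10L), seed = 2L)
  expect_length(c_$test, 10L)
  expect_error(split_dataset(sents, c(5L, 1L, 1L)), "summing")

  # the canonical corpus partition: 12009 sentences -> 11009/500/500
  big <- split_dataset(as.list(seq_len(12009L)), c(11009L, 500L, 500L),
                       seed = 7L)
  expect_equal(lengths(big), c(train = 11009L, valid = 500L, test = 500L))
  expect_length(unique(unlist(big)), 12009L)
})

test_that("CoNLL export writes token/tag lines with sentence breaks", {
  fx <- fixture_corpus(n_docs = 2L, seed = 31L)
  path <- withr::local_tempfile()
  write_conll(fx$sentences[1:3], path)
  lines <- readLines(path)
  expect_equal(sum(lines == ""), 3L)
  body <- lines[lines != ""]
  expect_true(all(grepl("\t", body)))
  tags <- vapply(strsplit(body, "\t"), `[`, "", 2L)
  expect_true(all(tags %in% c("O", "B-SINTOMA", "I-SINTOMA")))
})
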