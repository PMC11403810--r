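test_that("learn_bpe finds the most frequent pair first and is deterministic", {
  m0 <- learn_bpe(rep("aaaa", 100L), num_merges = 0L)
  expect_equal(NROW(m0$merges), 0L)
  expect_true(all(nchar(bpe_encode("aaaa", m0)$token) == 1L))

  m1 <- learn_bpe(rep("aaaa", 100L), num_merges = 1L)
  expect_equal(unname(unlist(m1$merges[1, ])), c("a", "a"))

  # deterministic given corpus order
  corpus <- c("tos seca", "tos seca", "fiebre alta")
  expect_identical(learn_bpe(corpus, 10L)$merges, learn_bpe(corpus, 10L)$merges)

  # learned model re-applied to its own corpus yields no unknown symbols
  m <- learn_bpe(corpus, 10L)
  for (s in corpus) {
    ids <- bpe_token_ids(bpe_encode(s, m), m)
    expect_false(any(m$vocab[ids] == "<unk>"))
  }
  expect_error(learn_bpe(character(), 5L), "empty")
})

test_that("deterministic encoding restores text and repeats identically", {
  fx <- fixture_corpus(n_docs = 4L, seed = 17L)
  model <- fixture_bpe(fx$sentences)
  for (s in fx$sentences[1:10]) {
    a <- bpe_encode(s$text, model)
    b <- bpe_encode(s$text, model)
    expect_identical(a, b)
    expect_identical(paste(a$token, collapse = ""),
                     gsub("[[:space:]]", "", s$text))
    # intervals point at the right substrings
    expect_identical(substring(s$text, a$start + 1L, a$end), a$token)
  }
  expect_equal(NROW(bpe_encode("", model)), 0L)
})

test_that("dropout limit laws hold exactly", {
  fx <- fixture_corpus(n_docs = 3L, seed = 19L)
  model <- fixture_bpe(fx$sentences)
  txt <- fx$sentences[[1]]$text
  expect_identical(bpe_encode(txt, model, p = 0),
                   bpe_encode(txt, model))
  base <- bpe_encode(txt, model, p = 1)
  expect_true(all(nchar(base$token) == 1L))
  expect_identical(paste(base$token, collapse = ""),
                   gsub("[[:space:]]", "", txt))
})

test_that("dropout is seed-reproducible and perturbs segmentations", {
  fx <- fixture_corpus(n_docs = 3L, seed = 23L)
  model <- fixture_bpe(fx$sentences)
  txt <- fx$sentences[[2]]$text
  a <- bpe_encode(txt, model, p = 0.1, seed = 99L)
  b <- bpe_encode(txt, model, p = 0.1, seed = 99L)
  expect_identical(a, b)
  # across many seeds at least one segmentation differs from deterministic
  det <- bpe_encode(txt, model, p = 0)
  any_diff <- any(vapply(1:20, function(s)
    !identical(bpe_encode(txt, model, p = 0.3, seed = s)$token, det$token),
    logical(1)))
  expect_true(any_diff)
})

test_that("segmentation validity is preserved under fuzzing", {
  fx <- fixture_corpus(n_docs = 4L, seed = 29L)
  model <- fixture_bpe(fx$sentences)
  set.seed(101)
  for (k in 1:200) {
    s <- fx$sentences[[sample.int(length(fx$sentences), 1L)]]
    p <- stats::runif(1)
    sw <- bpe_encode(s$text, model, p = p)
    expect_identical(paste(sw$token, collapse = ""),
                     gsub("[[:space:]]", "", s$text))
    expect_identical(substring(s$text, sw$start + 1L, sw$end), sw$token)
  }
})

test_that("expected token count is non-decreasing in dropout p", {
  fx <- fixture_corpus(n_docs = 4L, seed = 31L)
  model <- fixture_bpe(fx$sentences)
  txts <- vapply(fx$sentences[1:15], `[[`, "", "text")
  mean_tokens <- function(p) {
    mean(vapply(seq_along(txts), function(i)
      NROW(bpe_encode(txts[i], model, p = p, seed = i)), numeric(1)))
  }
  counts <- vapply(c(0, 0.3, 0.7, 1), mean_tokens, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("label alignment propagates tags and masks continuations", {
  model <- learn_bpe(c("taquicardia leve"), 3L)
  sw <- bpe_encode("taquicardia leve", model)
  n_words <- max(sw$word_index)
  word_tags <- c("B-SINTOMA", "O")[seq_len(n_words)]
  al <- align_labels(sw, word_tags)
  # word-start subwords carry the word tag, continuations I-/O, mask 0
  for (w in seq_len(n_words)) {
    rows <- which(al$word_index == w)
    expect_equal(al$tag[rows[1]], word_tags[w])
    expect_equal(al$mask[rows[1]], 1L)
    if (length(rows) > 1L) {
      expected <- if (word_tags[w] == "O") "O" else "I-SINTOMA"
      expect_true(all(al$tag[rows[-1L]] == expected))
      expect_true(all(al$mask[rows[-1L]] == 0L))
    }
  }
  # reading only word-start subwords recovers the word tags
  expect_equal(al$tag[al$word_start], word_tags)
  # supervised-continuation mode flips the mask
  al2 <- align_labels(sw, word_tags, supervise_continuations = TRUE)
  expect_true(all(al2$mask == 1L))
  # word-count mismatch is an error
  expect_error(align_labels(sw, c(word_tags, "O")), "alignment impossible")
})

test_that("merge files round-trip through write_bpe/read_bpe", {
  fx <- fixture_corpus(n_docs = 3L, seed = 37L)
  model <- fixture_bpe(fx$sentences, 60L)
  mp <- withr::local_tempfile(); ap <- withr::local_tempfile()
  write_bpe(model, mp, ap)
  model2 <- read_bpe(mp, ap)
  expect_identical(model2$merges, model$merges)
  expect_identical(model2$alphabet, model$alphabet)
  txt <- fx$sentences[[1]]$text
  expect_identical(bpe_encode(txt, model2), bpe_encode(txt, model))
})
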