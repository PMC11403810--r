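test_that("n-gram extraction enumerates marked-substring features", {
  # "ab" marked as "^ab$": all 1- and 2-grams
  f <- ssw_extract_features("ab", c(1L, 2L))
  expect_setequal(unique(f), c("^", "a", "b", "$", "^a", "ab", "b$"))
  expect_length(f, 7L)

  # single character
  expect_setequal(ssw_extract_features("a", c(1L, 1L)), c("^", "a", "$"))

  # combinatorial identity: a length-L subword gives (L+2) - n + 1 n-grams
  for (word in c("tos", "fiebre", "x")) {
    L <- nchar(word)
    for (n in 1:3) {
      cnt <- sum(nchar(ssw_extract_features(word, c(n, n))) == n)
      expect_equal(cnt, max(0L, L + 2L - n + 1L))
    }
  }
  expect_error(ssw_extract_features(""), "non-empty")
})

test_that("feature selection is deterministic, frequency-ranked and covering", {
  # toy vocabulary: frequency ranking is checkable by hand
  inv <- ssw_select_features(c("aa", "ab"), K = 6L, n_range = c(1L, 2L))
  expect_equal(inv$K, 6L)
  # unigrams ^, a, $ appear in both words; 'a' occurs 3 times total
  expect_true(all(c("^", "a", "$") %in% inv$features))
  expect_identical(inv, ssw_select_features(c("aa", "ab"), 6L, c(1L, 2L)))

  # K = total distinct n-grams -> the full set
  all_grams <- unique(unlist(lapply(c("aa", "ab"), ssw_extract_features,
                                    n_range = c(1L, 2L))))
  inv_full <- ssw_select_features(c("aa", "ab"), K = length(all_grams),
                                  n_range = c(1L, 2L))
  expect_setequal(inv_full$features, all_grams)

  # coverage floor: every subword of a random vocabulary has >= 1 feature
  vocab <- c("dolor", "tora", "cico", "tos", "seca", "x", "qz")
  inv2 <- ssw_select_features(vocab, K = 20L, n_range = c(1L, 3L))
  for (w in vocab) expect_gt(sum(ssw_featurize(w, inv2)), 0)

  expect_error(ssw_select_features(vocab, K = 2L), "coverage floor")
})

test_that("featurize counts occurrences", {
  inv <- ssw_select_features(c("aa"), K = 5L, n_range = c(1L, 1L))
  v <- ssw_featurize("aa", inv)
  expect_equal(v[match("a", inv$features)], 2)
  expect_equal(v[match("^", inv$features)], 1)
  # unknown characters are still covered via boundary markers
  v2 <- ssw_featurize("zz", inv)
  expect_gt(sum(v2), 0)
})

test_that("FTE forward is deterministic, finite and shape-correct", {
  inv <- ssw_select_features(c("tos", "seca"), K = 12L, n_range = c(1L, 2L))
  p1 <- fte_init(inv$K, 8L, hidden = 16L, seed = 5L)
  p2 <- fte_init(inv$K, 8L, hidden = 16L, seed = 5L)
  x <- ssw_featurize("tos", inv)
  expect_identical(fte_forward(x, p1), fte_forward(x, p2))
  expect_length(fte_forward(x, p1), 8L)
  expect_true(all(is.finite(fte_forward(x, p1))))
  # zero weights -> zero vector
  pz <- tree_map_zero <- p1
  for (nm in names(pz)) pz[[nm]][] <- 0
  expect_true(all(fte_forward(x, pz) == 0))
  expect_error(fte_forward(c(1, 2), p1), "does not match")
})

test_that("MSE pre-fit reduces loss and respects feature collisions", {
  vocab <- c("tos", "seca", "alta", "dolor", "fiebre", "leve", "gran",
             "nueva", "roja", "azul")
  inv <- ssw_select_features(vocab, K = 60L, n_range = c(1L, 3L))
  set.seed(42)
  target <- matrix(rnorm(length(vocab) * 8L), length(vocab), 8L)
  fit <- fte_pretrain(inv, vocab, target, steps = 200L, lr = 5e-3,
                      hidden = 32L, seed = 7L)
  expect_lt(fit$loss_history[length(fit$loss_history)], fit$loss_history[1])
  # determinism under seed
  fit2 <- fte_pretrain(inv, vocab, target, steps = 200L, lr = 5e-3,
                       hidden = 32L, seed = 7L)
  expect_identical(fit$loss_history, fit2$loss_history)

  # fixed point: targets equal to current outputs -> immediate ~0 loss
  X <- ssw_featurize_vocab(vocab, inv)
  p0 <- fte_init(inv$K, 8L, hidden = 32L, seed = 7L)
  fix <- fte_pretrain(inv, vocab, fte_forward(X, p0), steps = 1L, lr = 1e-3,
                      hidden = 32L, seed = 7L)
  expect_lt(fix$loss_history[1], 1e-20)

  # colliding subwords ("ab"/"ba" share all unigram features) cannot reach
  # distinct targets: irreducible loss stays positive
  inv1 <- ssw_select_features(c("ab", "ba"), K = 4L, n_range = c(1L, 1L))
  expect_identical(ssw_featurize("ab", inv1), ssw_featurize("ba", inv1))
  t2 <- rbind(rep(1, 4), rep(-1, 4))
  coll <- fte_pretrain(inv1, c("ab", "ba"), t2, steps = 400L, lr = 1e-2,
                       hidden = 16L, seed = 3L)
  final <- coll$loss_history[length(coll$loss_history)]
  expect_gt(final, 0.9)  # analytic floor: mean squared distance to midpoint = 1
})

test_that("pre-fit improves cosine similarity to the targets across seeds", {
  vocab <- c("tos", "seca", "alta", "dolor", "fiebre", "leve")
  inv <- ssw_select_features(vocab, K = 40L, n_range = c(1L, 3L))
  X <- ssw_featurize_vocab(vocab, inv)
  cos_sim <- function(A, B) {
    mean(rowSums(A * B) / (sqrt(rowSums(A^2)) * sqrt(rowSums(B^2))))
  }
  set.seed(9)
  target <- matrix(rnorm(length(vocab) * 6L), length(vocab), 6L)
  gains <- vapply(1:3, function(s) {
    p0 <- fte_init(inv$K, 6L, hidden = 24L, seed = s)
    fit <- fte_pretrain(inv, vocab, target, steps = 300L, lr = 5e-3,
                        hidden = 24L, seed = s)
    cos_sim(fte_forward(X, fit$params), target) -
      cos_sim(fte_forward(X, p0), target)
  }, numeric(1))
  expect_true(mean(gains) > 0)
})
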