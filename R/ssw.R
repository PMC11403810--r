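# Sub-subword (character n-gram) features and the feature-to-embedding (FTE)
# network.
#
# Instead of a free embedding lookup table, each subword's embedding is
# produced by a feed-forward network from a sparse count vector of the
# character n-grams of the boundary-marked subword string ("^subword$").
# The network has 3 hidden layers (default width 3072, configurable down for
# desk-scale experiments) with tanh activations and can be pre-fitted by
# mean squared error to an existing embedding matrix before joint training.

mark_subword <- function(subword) paste0("^", subword, "$")

#' Extract character n-gram features of a subword
#'
#' All character n-grams with lengths in `n_range` of the boundary-marked
#' string `^subword$`.  A marked string of length `M` contributes exactly
#' `M - n + 1` n-grams of order `n` (with multiplicity).
#'
#' @param subword non-empty subword string.
#' @param n_range integer pair `(min_n, max_n)`.
#' @return character vector of n-grams (a multiset: duplicates are kept).
#' @export
ssw_extract_features <- function(subword, n_range = c(1L, 4L)) {
  if (!nzchar(subword)) stop("subword must be non-empty")
  marked <- mark_subword(subword)
  M <- nchar(marked)
  out <- character()
  for (n in seq.int(n_range[1], n_range[2])) {
    if (n > M) break
    starts <- seq_len(M - n + 1L)
    out <- c(out, substring(marked, starts, starts + n - 1L))
  }
  out
}

#' Select an n-gram feature inventory for a vocabulary
#'
#' Frequency-ranked selection: n-grams are counted over the whole vocabulary
#' (with multiplicity) and the `K` most frequent are kept, ties broken by
#' shorter n-gram first, then lexicographically, so selection is
#' deterministic.  All order-1 n-grams occurring in the vocabulary are always
#' included as a coverage floor, guaranteeing every subword maps to at least
#' one feature; `K` below the floor size is an error.
#'
#' @param vocabulary character vector of subword strings.
#' @param K inventory size.
#' @param n_range integer pair `(min_n, max_n)`.
#' @return `ssw_inventory`: ordered `features`, `n_range`, `K`.
#' @export
ssw_select_features <- function(vocabulary, K = 4096L, n_range = c(1L, 4L)) {
  grams <- unlist(lapply(vocabulary, ssw_extract_features, n_range = n_range))
  counts <- table(grams)
  feats <- names(counts)
  ord <- order(-as.integer(counts), nchar(feats), feats)
  feats <- feats[ord]
  is_floor <- nchar(feats) == 1L
  if (K < sum(is_floor))
    stop("K = ", K, " is below the unigram coverage floor of ",
         sum(is_floor), " features")
  if (length(feats) <= K) {
    keep <- feats
  } else {
    others <- feats[!is_floor]
    chosen <- c(feats[is_floor], others[seq_len(K - sum(is_floor))])
    keep <- feats[feats %in% chosen]  # preserve frequency-rank order
  }
  structure(list(features = keep, n_range = as.integer(n_range),
                 K = length(keep)),
            class = "ssw_inventory")
}

#' @export
print.ssw_inventory <- function(x, ...) {
  cat("<ssw_inventory> ", x$K, " features, n in [", x$n_range[1], ",",
      x$n_range[2], "]\n", sep = "")
  invisible(x)
}

#' Feature count vector of one subword
#'
#' @param subword subword string.
#' @param inventory `ssw_inventory`.
#' @return numeric vector of length `K`; position k counts occurrences of
#'   feature k in the marked subword.
#' @export
ssw_featurize <- function(subword, inventory) {
  grams <- ssw_extract_features(subword, inventory$n_range)
  v <- numeric(inventory$K)
  idx <- match(grams, inventory$features)
  idx <- idx[!is.na(idx)]
  if (length(idx)) {
    tab <- table(idx)
    v[as.integer(names(tab))] <- as.numeric(tab)
  }
  v
}

#' Feature matrix of a whole vocabulary
#'
#' @param vocabulary character vector of subwords.
#' @param inventory `ssw_inventory`.
#' @return |vocabulary| x K numeric matrix, rows in vocabulary order.
#' @export
ssw_featurize_vocab <- function(vocabulary, inventory) {
  t(vapply(vocabulary, ssw_featurize, numeric(inventory$K),
           inventory = inventory))
}

#' Initialize an FTE network
#'
#' Three tanh hidden layers mapping a K-dimensional feature vector to the
#' host model's embedding dimension.  Weights use scaled uniform
#' initialization, seeded for determinism.
#'
#' @param input_dim feature inventory size K.
#' @param output_dim embedding dimension of the host model.
#' @param hidden hidden width (default 3072; smaller values are practical for
#'   small-scale experiments).
#' @param seed RNG seed.
#' @return `fte_params`: list of weight matrices/bias vectors `W1..W4`,
#'   `b1..b4`.
#' @export
fte_init <- function(input_dim, output_dim, hidden = 3072L, seed = 1L) {
  dims <- c(input_dim, hidden, hidden, hidden, output_dim)
  with_seed(seed, {
    p <- list()
    for (l in 1:4) {
      r <- sqrt(6 / (dims[l] + dims[l + 1L]))
      p[[paste0("W", l)]] <- matrix(stats::runif(dims[l] * dims[l + 1L], -r, r),
                                    dims[l], dims[l + 1L])
      p[[paste0("b", l)]] <- numeric(dims[l + 1L])
    }
    structure(p, class = "fte_params",
              dims = as.integer(dims))
  })
}

#' FTE forward pass
#'
#' @param x feature vector (length K) or matrix (N x K).
#' @param params `fte_params`.
#' @return embedding vector / matrix (N x output_dim).
#' @export
fte_forward <- function(x, params) {
  if (is.null(dim(x))) x <- matrix(x, 1L)
  if (ncol(x) != nrow(params$W1))
    stop("feature dimension ", ncol(x), " does not match FTE input ",
         nrow(params$W1))
  h <- tanh(sweep(x %*% params$W1, 2L, params$b1, "+"))
  h <- tanh(sweep(h %*% params$W2, 2L, params$b2, "+"))
  h <- tanh(sweep(h %*% params$W3, 2L, params$b3, "+"))
  out <- sweep(h %*% params$W4, 2L, params$b4, "+")
  if (nrow(out) == 1L && is.null(dim(x))) out[1L, ] else out
}

# Forward with caches, for backprop.
fte_forward_cache <- function(X, params) {
  h1 <- tanh(sweep(X %*% params$W1, 2L, params$b1, "+"))
  h2 <- tanh(sweep(h1 %*% params$W2, 2L, params$b2, "+"))
  h3 <- tanh(sweep(h2 %*% params$W3, 2L, params$b3, "+"))
  out <- sweep(h3 %*% params$W4, 2L, params$b4, "+")
  list(X = X, h1 = h1, h2 = h2, h3 = h3, out = out)
}

# Backprop d(out) through the FTE; returns gradient list matching params.
fte_backward <- function(cache, d_out, params) {
  g <- list()
  g$W4 <- crossprod(cache$h3, d_out); g$b4 <- colSums(d_out)
  dh3 <- (d_out %*% t(params$W4)) * (1 - cache$h3^2)
  g$W3 <- crossprod(cache$h2, dh3); g$b3 <- colSums(dh3)
  dh2 <- (dh3 %*% t(params$W3)) * (1 - cache$h2^2)
  g$W2 <- crossprod(cache$h1, dh2); g$b2 <- colSums(dh2)
  dh1 <- (dh2 %*% t(params$W2)) * (1 - cache$h1^2)
  g$W1 <- crossprod(cache$X, dh1); g$b1 <- colSums(dh1)
  g
}

#' Pre-fit an FTE network to a target embedding matrix by MSE
#'
#' Full-batch Adam minimization of the mean squared error between FTE outputs
#' for the vocabulary and the target embedding rows.  Two subwords with
#' identical feature vectors necessarily map to identical embeddings, so
#' distinct targets for such a collision leave an irreducible positive loss.
#'
#' @param inventory `ssw_inventory`.
#' @param vocabulary character vector of subwords.
#' @param target_embeddings |vocabulary| x dim matrix (one row per subword).
#' @param steps optimization steps.
#' @param lr Adam learning rate.
#' @param hidden FTE hidden width.
#' @param seed seed for initialization.
#' @return list with `params` (`fte_params`) and `loss_history` (per-step
#'   MSE, element 1 = loss at initialization).
#' @export
fte_pretrain <- function(inventory, vocabulary, target_embeddings,
                         steps = 200L, lr = 1e-3, hidden = 64L, seed = 1L) {
  if (NROW(target_embeddings) != length(vocabulary))
    stop("need one target embedding row per vocabulary subword")
  X <- ssw_featurize_vocab(vocabulary, inventory)
  Y <- as.matrix(target_embeddings)
  params <- fte_init(inventory$K, ncol(Y), hidden = hidden, seed = seed)
  opt <- adamw_init(params, lr = lr, weight_decay = 0)
  N <- nrow(X)
  loss_history <- numeric(steps + 1L)
  for (step in 0:steps) {
    cache <- fte_forward_cache(X, params)
    resid <- cache$out - Y
    loss <- mean(resid^2)
    if (!is.finite(loss))
      stop("FTE pre-fit diverged (non-finite MSE) at step ", step,
           "; reduce the learning rate")
    loss_history[step + 1L] <- loss
    if (step == steps) break
    d_out <- 2 * resid / length(resid)
    grads <- fte_backward(cache, d_out, params)
    upd <- adamw_step(opt, params, grads)
    params <- upd$params; opt <- upd$opt
  }
  list(params = params, loss_history = loss_history)
}
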