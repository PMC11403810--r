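# Tiny trainable transformer encoder (pre-norm, multi-head self-attention)
# with hand-written backpropagation.
#
# The default geometry (2 layers, width 64, 2 heads) is deliberately small:
# it trains from scratch on a CPU in minutes, which is what the synthetic
# corpora need.  Gradients are verified against finite differences in the
# test suite.

LN_EPS <- 1e-5

ln_fwd <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  sd_ <- sqrt(rowMeans(xc^2) + LN_EPS)
  xhat <- xc / sd_
  Y <- sweep(sweep(xhat, 2L, g, "*"), 2L, b, "+")
  list(Y = Y, xhat = xhat, sd = sd_)
}

ln_bwd <- function(dY, cache, g) {
  dxhat <- sweep(dY, 2L, g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dX <- (dxhat - m1 - cache$xhat * m2) / cache$sd
  list(dX = dX, dg = colSums(dY * cache$xhat), db = colSums(dY))
}

init_mat <- function(nr, nc, sd = 0.02) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

#' Initialize a tiny transformer encoder
#'
#' @param d model width (must be divisible by `n_heads`).
#' @param n_layers number of transformer blocks.
#' @param n_heads attention heads.
#' @param ff_mult feed-forward width multiplier.
#' @param max_len maximum sequence length (learned positional embeddings).
#' @param seed RNG seed for the initialization.
#' @return nested parameter list (`P` positional matrix, `layers`, final
#'   layer-norm gains/biases) with geometry in attributes.
#' @export
encoder_init <- function(d = 64L, n_layers = 2L, n_heads = 2L, ff_mult = 2L,
                         max_len = 160L, seed = 1L) {
  if (d %% n_heads != 0L) stop("width d must be divisible by n_heads")
  f <- d * ff_mult
  with_seed(seed, {
    layers <- lapply(seq_len(n_layers), function(l) list(
      ln1g = rep(1, d), ln1b = rep(0, d),
      Wq = init_mat(d, d), bq = rep(0, d),
      Wk = init_mat(d, d), bk = rep(0, d),
      Wv = init_mat(d, d), bv = rep(0, d),
      Wo = init_mat(d, d), bo = rep(0, d),
      ln2g = rep(1, d), ln2b = rep(0, d),
      W1 = init_mat(d, f), b1 = rep(0, f),
      W2 = init_mat(f, d), b2 = rep(0, d)))
    structure(list(P = init_mat(max_len, d), layers = layers,
                   lnfg = rep(1, d), lnfb = rep(0, d)),
              d = d, n_heads = n_heads, n_layers = n_layers)
  })
}

head_cols <- function(h, dh) ((h - 1L) * dh + 1L):(h * dh)

#' Encoder forward pass
#'
#' @param X0 T x d matrix of input token embeddings.
#' @param params from [encoder_init()].
#' @return list with `Y` (T x d contextual representations) and `cache` for
#'   [encoder_backward()].
#' @export
encoder_forward <- function(X0, params) {
  T_ <- nrow(X0)
  nh <- attr(params, "n_heads")
  d <- attr(params, "d")
  dh <- d %/% nh
  scale <- 1 / sqrt(dh)
  X <- X0 + params$P[seq_len(T_), , drop = FALSE]
  caches <- vector("list", length(params$layers))
  for (li in seq_along(params$layers)) {
    p <- params$layers[[li]]
    l1 <- ln_fwd(X, p$ln1g, p$ln1b)
    Q <- sweep(l1$Y %*% p$Wq, 2L, p$bq, "+")
    K <- sweep(l1$Y %*% p$Wk, 2L, p$bk, "+")
    V <- sweep(l1$Y %*% p$Wv, 2L, p$bv, "+")
    A_list <- vector("list", nh)
    C <- matrix(0, T_, d)
    for (h in seq_len(nh)) {
      cols <- head_cols(h, dh)
      S <- (Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE])) * scale
      A <- softmax_rows(S)
      A_list[[h]] <- A
      C[, cols] <- A %*% V[, cols, drop = FALSE]
    }
    O <- sweep(C %*% p$Wo, 2L, p$bo, "+")
    X_attn <- X + O
    l2 <- ln_fwd(X_attn, p$ln2g, p$ln2b)
    pre <- sweep(l2$Y %*% p$W1, 2L, p$b1, "+")
    Hrelu <- pre * (pre > 0)
    Fout <- sweep(Hrelu %*% p$W2, 2L, p$b2, "+")
    X_new <- X_attn + Fout
    caches[[li]] <- list(l1 = l1, Q = Q, K = K, V = V, A = A_list, C = C,
                         X_attn = X_attn, l2 = l2, pre = pre, Hrelu = Hrelu)
    X <- X_new
  }
  lf <- ln_fwd(X, params$lnfg, params$lnfb)
  list(Y = lf$Y, cache = list(T_ = T_, caches = caches, lf = lf))
}

#' Encoder backward pass
#'
#' @param dY gradient of the loss w.r.t. the encoder output (T x d).
#' @param fwd the list returned by [encoder_forward()].
#' @param params encoder parameters.
#' @return list with `grads` (same shape as `params`) and `dX0` (gradient
#'   w.r.t. the input embeddings).
#' @export
encoder_backward <- function(dY, fwd, params) {
  nh <- attr(params, "n_heads")
  d <- attr(params, "d")
  dh <- d %/% nh
  scale <- 1 / sqrt(dh)
  T_ <- fwd$cache$T_
  lb <- ln_bwd(dY, fwd$cache$lf, params$lnfg)
  dX <- lb$dX
  grads <- list(P = matrix(0, nrow(params$P), d), layers = NULL,
                lnfg = lb$dg, lnfb = lb$db)
  glayers <- vector("list", length(params$layers))
  for (li in rev(seq_along(params$layers))) {
    p <- params$layers[[li]]
    cc <- fwd$cache$caches[[li]]
    # FFN block
    dFout <- dX
    gW2 <- crossprod(cc$Hrelu, dFout); gb2 <- colSums(dFout)
    dH <- dFout %*% t(p$W2)
    dpre <- dH * (cc$pre > 0)
    gW1 <- crossprod(cc$l2$Y, dpre); gb1 <- colSums(dpre)
    dXn2 <- dpre %*% t(p$W1)
    lb2 <- ln_bwd(dXn2, cc$l2, p$ln2g)
    dX_attn <- dX + lb2$dX
    # attention block
    dO <- dX_attn
    gWo <- crossprod(cc$C, dO); gbo <- colSums(dO)
    dC <- dO %*% t(p$Wo)
    dQ <- matrix(0, T_, d); dK <- matrix(0, T_, d); dV <- matrix(0, T_, d)
    for (h in seq_len(nh)) {
      cols <- head_cols(h, dh)
      A <- cc$A[[h]]
      dCh <- dC[, cols, drop = FALSE]
      dA <- dCh %*% t(cc$V[, cols, drop = FALSE])
      dV[, cols] <- crossprod(A, dCh)
      dS <- A * (dA - rowSums(dA * A))
      dQ[, cols] <- (dS %*% cc$K[, cols, drop = FALSE]) * scale
      dK[, cols] <- (crossprod(dS, cc$Q[, cols, drop = FALSE])) * scale
    }
    gWq <- crossprod(cc$l1$Y, dQ); gbq <- colSums(dQ)
    gWk <- crossprod(cc$l1$Y, dK); gbk <- colSums(dK)
    gWv <- crossprod(cc$l1$Y, dV); gbv <- colSums(dV)
    dXn1 <- dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
    lb1 <- ln_bwd(dXn1, cc$l1, p$ln1g)
    glayers[[li]] <- list(ln1g = lb1$dg, ln1b = lb1$db,
                          Wq = gWq, bq = gbq, Wk = gWk, bk = gbk,
                          Wv = gWv, bv = gbv, Wo = gWo, bo = gbo,
                          ln2g = lb2$dg, ln2b = lb2$db,
                          W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
    dX <- dX_attn + lb1$dX
  }
  grads$layers <- glayers
  grads$P[seq_len(T_), ] <- dX
  attributes(grads) <- c(attributes(grads),
                         attributes(params)[c("d", "n_heads", "n_layers")])
  list(grads = grads, dX0 = dX)
}
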