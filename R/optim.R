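# AdamW optimizer over nested parameter lists.
#
# Parameters are arbitrary nested lists whose leaves are numeric vectors or
# matrices; gradients mirror the structure.  Weight decay is decoupled
# (applied directly to the parameter, not through the gradient) and, as is
# conventional, only to matrix-shaped leaves (weights), never to bias or
# gain vectors.

tree_map <- function(f, x) {
  if (is.list(x)) {
    out <- lapply(x, tree_map, f = f)
    attributes(out) <- attributes(x)
    out
  } else f(x)
}

align_names <- function(x, y) {
  if (!is.null(names(x)) && !is.null(names(y)) &&
      setequal(names(x), names(y))) y[names(x)] else y
}

tree_map2 <- function(f, x, y) {
  if (is.list(x)) {
    y <- align_names(x, y)
    out <- mapply(function(a, b) tree_map2(f, a, b), x, y, SIMPLIFY = FALSE)
    attributes(out) <- attributes(x)
    out
  } else f(x, y)
}

tree_map3 <- function(f, x, y, z) {
  if (is.list(x)) {
    y <- align_names(x, y); z <- align_names(x, z)
    out <- mapply(function(a, b, c) tree_map3(f, a, b, c), x, y, z,
                  SIMPLIFY = FALSE)
    attributes(out) <- attributes(x)
    out
  } else f(x, y, z)
}

#' Initialize AdamW state for a parameter tree
#'
#' @param params nested list of numeric leaves.
#' @param lr learning rate.
#' @param beta1,beta2 moment decay rates.
#' @param eps numerical stabilizer.
#' @param weight_decay decoupled weight decay applied to matrix leaves.
#' @return optimizer state list.
#' @export
adamw_init <- function(params, lr = 2e-5, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 0.01) {
  zeros <- tree_map(function(p) p * 0, params)
  list(m = zeros, v = zeros, t = 0L, lr = lr, beta1 = beta1, beta2 = beta2,
       eps = eps, weight_decay = weight_decay)
}

#' One AdamW update
#'
#' @param opt state from [adamw_init()].
#' @param params current parameter tree.
#' @param grads gradient tree of the same shape.
#' @return list with updated `params` and `opt`.
#' @export
adamw_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  opt$m <- tree_map2(function(m, g) opt$beta1 * m + (1 - opt$beta1) * g,
                     opt$m, grads)
  opt$v <- tree_map2(function(v, g) opt$beta2 * v + (1 - opt$beta2) * g^2,
                     opt$v, grads)
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  params <- tree_map3(function(p, m, v) {
    step <- (m / bc1) / (sqrt(v / bc2) + opt$eps)
    wd <- if (!is.null(dim(p))) opt$weight_decay else 0
    p - opt$lr * (step + wd * p)
  }, params, opt$m, opt$v)
  list(params = params, opt = opt)
}
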