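# Linear-chain CRF output layer.
#
# A tag path y_1..y_T over emissions E (T x L) is scored
#   score(y) = start[y_1] + sum_t E[t, y_t] + sum_t trans[y_{t-1}, y_t] + end[y_T]
# and the model is trained by maximizing score(y) - log Z, with Z the sum of
# exp(score) over all L^T paths (forward algorithm).  All dynamic programming
# is in log space with a stable log-sum-exp.

col_logsumexp <- function(M) apply(M, 2L, logsumexp)

# Which label strings are I-tags, and of which label.
i_label_of <- function(labels) {
  ifelse(startsWith(labels, "I-"), substring(labels, 3L), NA_character_)
}
bi_label_of <- function(labels) {
  ifelse(startsWith(labels, "B-") | startsWith(labels, "I-"),
         substring(labels, 3L), NA_character_)
}

#' Initialize CRF parameters with a BIO-constraint bias
#'
#' Transition scores are drawn from a small seeded normal initialization,
#' except that invalid BIO transitions are set to a large negative
#' `bias_value` so that decoding effectively never selects them.  With
#' `mode = "all_invalid"` (default) the biased entries are `O -> I-<any>`,
#' `start -> I-<any>` and `B/I-<x> -> I-<y != x>`; `mode = "o_to_i"` biases
#' only `O -> I-<any>`.  Biased entries remain trainable unless callers use
#' the stored masks to freeze them.
#'
#' @param labels ordered tag inventory, e.g. `c("O", "B-SINTOMA", "I-SINTOMA")`.
#' @param bias_value large negative constant (default -10000: behaves as
#'   -Inf at float precision without producing NaN in log-sum-exp).
#' @param mode `"all_invalid"` or `"o_to_i"`.
#' @param seed seed for the small random initialization.
#' @param init_sd standard deviation of the unbiased entries.
#' @return `crf_params`: `labels`, `trans` (L x L), `start`, `end`, plus
#'   logical masks `trans_bias`, `start_bias` marking the biased entries.
#' @export
crf_init <- function(labels, bias_value = -10000, mode = c("all_invalid", "o_to_i"),
                     seed = 1L, init_sd = 0.01) {
  mode <- match.arg(mode)
  L <- length(labels)
  if (L == 0L) stop("empty label inventory")
  if (bias_value >= 0) stop("bias_value must be strongly negative")
  params <- with_seed(seed, {
    list(trans = matrix(stats::rnorm(L * L, sd = init_sd), L, L,
                        dimnames = list(labels, labels)),
         start = stats::setNames(stats::rnorm(L, sd = init_sd), labels),
         end = stats::setNames(stats::rnorm(L, sd = init_sd), labels))
  })
  i_of <- i_label_of(labels)
  bi_of <- bi_label_of(labels)
  trans_bias <- matrix(FALSE, L, L, dimnames = list(labels, labels))
  start_bias <- stats::setNames(rep(FALSE, L), labels)
  is_i <- !is.na(i_of)
  if (any(labels == "O")) trans_bias["O", is_i] <- TRUE
  if (mode == "all_invalid") {
    start_bias[is_i] <- TRUE
    for (a in seq_len(L)) {
      if (is.na(bi_of[a])) next
      for (b in which(is_i))
        if (i_of[b] != bi_of[a]) trans_bias[a, b] <- TRUE
    }
  }
  params$trans[trans_bias] <- bias_value
  params$start[start_bias] <- bias_value
  structure(c(params, list(labels = labels, trans_bias = trans_bias,
                           start_bias = start_bias, bias_value = bias_value,
                           mode = mode)),
            class = "crf_params")
}

check_emissions <- function(emissions, params) {
  if (!is.matrix(emissions) || nrow(emissions) < 1L)
    stop("emissions must be a T x L matrix with T >= 1")
  if (ncol(emissions) != length(params$labels))
    stop("emissions have ", ncol(emissions), " columns but the label ",
         "inventory has ", length(params$labels))
  if (any(!is.finite(emissions))) stop("non-finite emission scores")
  invisible(TRUE)
}

#' Log-partition function of a linear-chain CRF
#'
#' Forward algorithm: returns `log` of the sum of exponentiated path scores
#' over all label paths of length `nrow(emissions)`.
#'
#' @param emissions T x L matrix of per-position label scores.
#' @param params `crf_params`.
#' @return scalar log-partition value.
#' @export
crf_log_partition <- function(emissions, params) {
  check_emissions(emissions, params)
  T_ <- nrow(emissions)
  alpha <- params$start + emissions[1L, ]
  if (T_ > 1L) for (t in 2:T_) {
    alpha <- col_logsumexp(alpha + params$trans) + emissions[t, ]
  }
  logsumexp(alpha + params$end)
}

tags_to_indices <- function(tags, params) {
  if (is.character(tags)) {
    idx <- match(tags, params$labels)
    if (any(is.na(idx)))
      stop("tag(s) outside the label inventory: ",
           paste(unique(tags[is.na(idx)]), collapse = ", "))
    idx
  } else as.integer(tags)
}

#' Score of one tag path
#'
#' @param emissions T x L matrix.
#' @param tags length-T character vector of labels (or 1-based indices).
#' @param params `crf_params`.
#' @return scalar path score (emissions + transitions + boundary scores).
#' @export
crf_sequence_score <- function(emissions, tags, params) {
  check_emissions(emissions, params)
  y <- tags_to_indices(tags, params)
  T_ <- nrow(emissions)
  if (length(y) != T_) stop("tag sequence length != number of positions")
  s <- params$start[y[1L]] + params$end[y[T_]] +
    sum(emissions[cbind(seq_len(T_), y)])
  if (T_ > 1L) s <- s + sum(params$trans[cbind(y[-T_], y[-1L])])
  unname(s)
}

#' Path log-likelihood under the CRF
#'
#' `crf_sequence_score(...) - crf_log_partition(...)`; always <= 0.
#'
#' @inheritParams crf_sequence_score
#' @return scalar log-likelihood.
#' @export
crf_log_likelihood <- function(emissions, tags, params) {
  crf_sequence_score(emissions, tags, params) -
    crf_log_partition(emissions, params)
}

#' Viterbi decoding
#'
#' Returns an argmax-scoring tag path.  Ties are broken deterministically in
#' favour of the lowest label index at every backtracking step.
#'
#' @param emissions T x L matrix.
#' @param params `crf_params`.
#' @return list with `tags` (character), `indices` and `score`.
#' @export
crf_viterbi <- function(emissions, params) {
  check_emissions(emissions, params)
  T_ <- nrow(emissions); L <- length(params$labels)
  delta <- params$start + emissions[1L, ]
  back <- matrix(0L, T_, L)
  if (T_ > 1L) for (t in 2:T_) {
    scores <- delta + params$trans        # [prev, next]
    best_prev <- apply(scores, 2L, which.max)  # lowest index wins ties
    back[t, ] <- best_prev
    delta <- scores[cbind(best_prev, seq_len(L))] + emissions[t, ]
  }
  final <- delta + params$end
  y <- integer(T_)
  y[T_] <- which.max(final)
  if (T_ > 1L) for (t in T_:2) y[t - 1L] <- back[t, y[t]]
  list(tags = params$labels[y], indices = y, score = unname(max(final)))
}

#' Forward-backward gradients of the negative log-likelihood
#'
#' Computes the marginal statistics needed to train the CRF: the gradient of
#' `-log p(tags | emissions)` with respect to emissions, transitions and
#' boundary scores (expected counts minus observed counts).
#'
#' @inheritParams crf_sequence_score
#' @return list with `nll`, `d_emissions` (T x L), `d_trans` (L x L),
#'   `d_start`, `d_end`.
#' @export
crf_forward_backward <- function(emissions, tags, params) {
  check_emissions(emissions, params)
  y <- tags_to_indices(tags, params)
  T_ <- nrow(emissions); L <- length(params$labels)
  alpha <- matrix(0, T_, L); beta <- matrix(0, T_, L)
  alpha[1L, ] <- params$start + emissions[1L, ]
  if (T_ > 1L) for (t in 2:T_)
    alpha[t, ] <- col_logsumexp(alpha[t - 1L, ] + params$trans) + emissions[t, ]
  logZ <- logsumexp(alpha[T_, ] + params$end)
  beta[T_, ] <- params$end
  if (T_ > 1L) for (t in (T_ - 1L):1L)
    beta[t, ] <- col_logsumexp(t(params$trans) +
                                 (emissions[t + 1L, ] + beta[t + 1L, ]))
  marg <- exp(alpha + beta - logZ)           # unary marginals
  d_emis <- marg
  d_emis[cbind(seq_len(T_), y)] <- d_emis[cbind(seq_len(T_), y)] - 1
  d_trans <- matrix(0, L, L)
  if (T_ > 1L) for (t in 1:(T_ - 1L)) {
    pair <- exp(outer(alpha[t, ], emissions[t + 1L, ] + beta[t + 1L, ], "+") +
                  params$trans - logZ)
    d_trans <- d_trans + pair
    d_trans[y[t], y[t + 1L]] <- d_trans[y[t], y[t + 1L]] - 1
  }
  d_start <- marg[1L, ]; d_start[y[1L]] <- d_start[y[1L]] - 1
  d_end <- marg[T_, ]; d_end[y[T_]] <- d_end[y[T_]] - 1
  nll <- logZ - crf_sequence_score(emissions, y, params)
  list(nll = unname(nll), d_emissions = d_emis, d_trans = d_trans,
       d_start = unname(d_start), d_end = unname(d_end))
}

#' Count invalid BIO transitions in a tag sequence
#'
#' Invalid transitions are `I-<x>` at sequence start, `O -> I-<x>` and
#' `B/I-<y> -> I-<x>` with `y != x` — i.e. every `I` tag without a compatible
#' predecessor.
#'
#' @param tags character vector of BIO tags.
#' @return integer count of invalid transitions.
#' @export
count_invalid_transitions <- function(tags) {
  if (!length(tags)) return(0L)
  bad <- 0L
  prev <- NA_character_
  for (t in tags) {
    if (startsWith(t, "I-")) {
      lab <- substring(t, 3L)
      ok <- !is.na(prev) &&
        (identical(prev, paste0("B-", lab)) || identical(prev, paste0("I-", lab)))
      if (!ok) bad <- bad + 1L
    }
    prev <- t
  }
  bad
}
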