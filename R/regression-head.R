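#' Split the fused sequence into tokens and the weight column
#'
#' Exact inverse of [concat_weights()]: the last feature channel is the
#' per-patch weight column, the remaining channels are the tokens.
#'
#' @param fused B x J x (D+1) numeric array.
#' @return list with `tokens` (B x J x D array) and `weights` (B x J
#'   matrix, the extracted weight column).
#' @export
remove_weights <- function(fused) {
  d <- dim(fused)
  if (length(d) != 3L || d[3L] < 2L) {
    stop("remove_weights: fused sequence must be B x J x (D+1) with D >= 1")
  }
  list(tokens = fused[, , seq_len(d[3L] - 1L), drop = FALSE],
       weights = matrix(fused[, , d[3L]], d[1L], d[2L]))
}

#' Weight-modulated global average pooling
#'
#' `feature[b, ] = sum_j w[b, j] * tokens[b, j, ] / norm`, with
#' `norm = J` (`pool_norm = "count"`, the default: linear in the weights
#' and exactly plain global average pooling when all weights are 1) or
#' `norm = sum_j w[b, j]` (`pool_norm = "weight_sum"`).
#'
#' @param tokens B x J x D numeric array.
#' @param weights B x J matrix (or length-J vector recycled over the
#'   batch).
#' @param pool_norm `"count"` or `"weight_sum"`.
#' @return B x D matrix of pooled features.
#' @export
weighted_pool <- function(tokens, weights, pool_norm = c("count", "weight_sum")) {
  pool_norm <- match.arg(pool_norm)
  d <- dim(tokens)
  if (is.vector(weights)) weights <- matrix(weights, d[1L], d[2L], byrow = TRUE)
  if (!all(dim(weights) == d[1:2])) {
    stop("weighted_pool: weight shape does not match tokens")
  }
  feat <- matrix(0, d[1L], d[3L])
  for (b in seq_len(d[1L])) {
    wt <- weights[b, ]
    norm <- if (pool_norm == "count") d[2L] else sum(wt)
    feat[b, ] <- colSums(matrix(tokens[b, , ], d[2L], d[3L]) * wt) / norm
  }
  feat
}

#' Initialize the regression MLP
#'
#' Two layers, `D -> hidden -> 2`, SiLU between; weights Normal with
#' fan-in scaling (sd = 1/sqrt(fan_in)). The output bias defaults to the
#' frame center so that initial predictions start unbiased for the
#' coordinate range (center-anchored initialization); pass
#' `center = c(0, 0)` for zero-bias init.
#'
#' @param D input feature width.
#' @param hidden hidden width, default `max(2, D %/% 2)`.
#' @param center length-2 numeric, initial output bias (x, y).
#' @param seed optional integer seed.
#' @return list with `W1`, `b1`, `W2`, `b2`.
#' @export
init_mlp_head <- function(D, hidden = max(2L, D %/% 2L), center = c(0, 0),
                          seed = NULL) {
  with_seed(seed, list(
    W1 = matrix(rnorm(D * hidden, sd = 1 / sqrt(D)), D, hidden),
    b1 = numeric(hidden),
    W2 = matrix(rnorm(hidden * 2, sd = 1 / sqrt(hidden)), hidden, 2),
    b2 = as.numeric(center)
  ))
}

#' Regression MLP head
#'
#' `D -> hidden` linear, SiLU, `hidden -> 2` linear; outputs the predicted
#' pupil center (x, y) in pixels of the model frame, with no output
#' activation and no clamping.
#'
#' @param feature B x D matrix of pooled features.
#' @param params list from [init_mlp_head()].
#' @return B x 2 matrix of predictions (columns x, y).
#' @export
mlp_head <- function(feature, params) {
  feature <- as.matrix(feature)
  h <- feature %*% params$W1 + rep(params$b1, each = nrow(feature))
  silu(h) %*% params$W2 + rep(params$b2, each = nrow(feature))
}
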