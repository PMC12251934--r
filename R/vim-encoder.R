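#' SiLU activation
#'
#' `f(x) = x * sigmoid(x)`, elementwise; used for the encoder gates and the
#' regression MLP.
#'
#' @param x numeric vector/matrix/array.
#' @return same shape as `x`.
#' @export
silu <- function(x) {
  x * plogis(x)
}

silu_grad <- function(x) {
  s <- plogis(x)
  s * (1 + x * (1 - s))
}

#' Feature-wise layer normalization
#'
#' Normalizes each token across its feature axis to mean 0 / variance 1,
#' then applies a learnable gain and bias.
#'
#' @param tokens B x J x M numeric array.
#' @param gain,bias length-M affine parameters (defaults: ones / zeros).
#' @param eps variance floor.
#' @return B x J x M numeric array.
#' @export
layer_norm <- function(tokens, gain = NULL, bias = NULL, eps = 1e-5) {
  d <- dim(tokens)
  M <- d[3L]
  if (is.null(gain)) gain <- rep(1, M)
  if (is.null(bias)) bias <- numeric(M)
  m <- arr3_to_mat(tokens)
  out <- ln_fwd(m, gain, bias, eps)$y
  mat_to_arr3(out, d[1L], d[2L])
}

ln_fwd <- function(x, gain, bias, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- xhat * rep(gain, each = nrow(x)) + rep(bias, each = nrow(x))
  list(y = y, cache = list(xhat = xhat, inv = inv, gain = gain))
}

ln_bwd <- function(dy, cache) {
  xhat <- cache$xhat
  dxhat <- dy * rep(cache$gain, each = nrow(dy))
  dx <- cache$inv *
    (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dgain = colSums(dy * xhat), dbias = colSums(dy))
}

# ---- Selective SSM -------------------------------------------------------

#' Initialize selective state-space parameters
#'
#' The continuous transition matrix is log-parameterized and strictly
#' negative, `A = -exp(A_log)` (initialized so state s decays at rate s),
#' which guarantees `0 < Ad < 1` for every finite input: the zero-input
#' state always decays. The per-timestep discretization is input-dependent
#' (selective): `delta_t = softplus(x_t W_d + b_d)` per channel,
#' `B_t = x_t W_B + b_B` and `C_t = x_t W_C + b_C` per state, giving
#' `Ad_t = exp(delta_t A)` and input contribution `delta_t x_t B_t`.
#'
#' @param H channel width of the scanned sequence.
#' @param S state size per channel.
#' @param seed optional integer seed.
#' @return list with `A_log` (H x S), `Wd`, `bd`, `WB`, `bB`, `WC`, `bC`.
#' @export
init_ssm_params <- function(H, S, seed = NULL) {
  with_seed(seed, {
    dt <- exp(runif(H, log(0.001), log(0.1)))
    sdv <- 1 / sqrt(H)
    list(
      A_log = matrix(log(seq_len(S)), H, S, byrow = TRUE),
      Wd = matrix(rnorm(H * H, sd = sdv), H, H),
      bd = log(expm1(dt)),  # softplus(bd) ~ dt at zero input
      WB = matrix(rnorm(H * S, sd = sdv), H, S), bB = numeric(S),
      WC = matrix(rnorm(H * S, sd = sdv), H, S), bC = numeric(S)
    )
  })
}

#' Selective state-space scan
#'
#' Runs the linear recurrence `h_t = Ad_t * h_{t-1} + Bd_t x_t`,
#' `y_t = <C_t, h_t>` (output read from the post-update state, so `y_1`
#' depends on `x_1`) independently for every batch element and channel,
#' with the input-dependent discrete matrices of [init_ssm_params()].
#' `method = "reference"` is the normative plain-R sequential loop;
#' `method = "compiled"` is the compiled scan, which must (and does,
#' see the test suite) match the reference to floating tolerance.
#'
#' @param x B x J x H numeric array.
#' @param params parameter list from [init_ssm_params()].
#' @param method `"compiled"` (default) or `"reference"`.
#' @return B x J x H numeric array.
#' @export
ssm_scan <- function(x, params, method = c("compiled", "reference")) {
  method <- match.arg(method)
  d <- dim(x)
  if (length(d) != 3L) stop("ssm_scan: x must be a B x J x H array")
  m <- arr3_to_mat(x)
  if (!all(is.finite(m))) stop("ssm_scan: non-finite input")
  if (method == "compiled") {
    y <- ssm_fwd(m, params, d[1L], d[2L], want_cache = FALSE)$y
    return(mat_to_arr3(y, d[1L], d[2L]))
  }
  ssm_scan_reference(x, params)
}

# Normative sequential reference: explicit loops, one timestep at a time.
ssm_scan_reference <- function(x, params) {
  d <- dim(x)
  B <- d[1L]; J <- d[2L]; H <- d[3L]
  S <- ncol(params$A_log)
  A <- -exp(params$A_log)
  y <- array(0, dim = d)
  for (b in seq_len(B)) {
    hst <- matrix(0, H, S)
    for (t in seq_len(J)) {
      xt <- x[b, t, ]
      delta <- softplus(drop(xt %*% params$Wd) + params$bd)
      Bt <- drop(xt %*% params$WB) + params$bB
      Ct <- drop(xt %*% params$WC) + params$bC
      for (h in seq_len(H)) {
        if (!all(is.finite(delta[h]))) {
          stop(sprintf("ssm_scan: non-finite parameters at timestep %d", t))
        }
        Ad <- exp(delta[h] * A[h, ])
        hst[h, ] <- Ad * hst[h, ] + delta[h] * xt[h] * Bt
        y[b, t, h] <- sum(Ct * hst[h, ])
      }
    }
  }
  y
}

#' Low-level discrete scan with explicit per-timestep matrices
#'
#' Runs `h_t = Ad_t * h_{t-1} + Bd_t * x_t`, `y_t = <Cd_t, h_t>` for one
#' sequence with the discrete matrices supplied directly (no generators);
#' useful for hand-checkable cases. Scalars are broadcast.
#'
#' @param Ad J x H x S array (or scalar) of discrete transitions.
#' @param Bd J x H x S array (or scalar) of discrete input weights.
#' @param Cd J x S matrix (or scalar) of output weights.
#' @param x J x H matrix (or length-J vector for H = 1) of inputs.
#' @return J x H matrix of outputs (dropped to a vector when H = 1).
#' @export
#' @examples
#' ssm_scan_core(Ad = 0.5, Bd = 1, Cd = 1, x = c(1, 1, 1))  # 1, 1.5, 1.75
ssm_scan_core <- function(Ad, Bd, Cd, x) {
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  J <- nrow(x); H <- ncol(x)
  expand3 <- function(a, S) {
    if (length(a) == 1L) array(a, dim = c(J, H, S)) else a
  }
  S <- if (length(Cd) == 1L) {
    if (length(Ad) > 1L) dim(Ad)[3L] else 1L
  } else ncol(Cd)
  Ad <- expand3(Ad, S); Bd <- expand3(Bd, S)
  if (length(Cd) == 1L) Cd <- matrix(Cd, J, S)
  y <- matrix(0, J, H)
  hst <- matrix(0, H, S)
  for (t in seq_len(J)) {
    for (h in seq_len(H)) {
      hst[h, ] <- Ad[t, h, ] * hst[h, ] + Bd[t, h, ] * x[t, h]
      y[t, h] <- sum(Cd[t, ] * hst[h, ])
    }
  }
  drop(y)
}

# Internal flat-matrix SSM forward using the compiled kernel; x is (B*J) x H
# with sequence position fastest within each batch block, which is exactly
# the (J, B, channel) column-major layout the kernel indexes.
ssm_fwd <- function(x, sp, B, J, want_cache = FALSE) {
  H <- ncol(x)
  S <- ncol(sp$A_log)
  A <- -exp(sp$A_log)
  n <- nrow(x)
  delta_pre <- x %*% sp$Wd + rep(sp$bd, each = n)
  BtT <- crossprod(sp$WB, t(x)) + as.vector(sp$bB)  # S x n, state fastest
  CtT <- crossprod(sp$WC, t(x)) + as.vector(sp$bC)
  res <- ssm_scan_fwd_cpp(delta_pre, x, BtT, CtT, A, J, H, S, B)
  out <- list(y = res$y)
  if (want_cache) {
    out$cache <- list(x = x, delta_pre = delta_pre, delta = res$delta,
                      BtT = BtT, CtT = CtT, u = res$u, A = A,
                      h_hist = res$h_hist, Ad_hist = res$Ad_hist,
                      B = B, J = J, H = H, S = S)
  }
  out
}

ssm_bwd <- function(dy, sp, cache) {
  res <- ssm_scan_bwd_cpp(dy, cache$delta_pre, cache$delta, cache$u, cache$x,
                          cache$BtT, cache$CtT, cache$A,
                          cache$h_hist, cache$Ad_hist,
                          cache$J, cache$H, cache$S, cache$B)
  x <- cache$x
  dx <- res$dx_part + res$d_delta_pre %*% t(sp$Wd) +
    crossprod(res$dBT, t(sp$WB)) + crossprod(res$dCT, t(sp$WC))
  list(dx = dx,
       grads = list(A_log = res$dA * cache$A,
                    Wd = crossprod(x, res$d_delta_pre),
                    bd = colSums(res$d_delta_pre),
                    WB = t(res$dBT %*% x), bB = rowSums(res$dBT),
                    WC = t(res$dCT %*% x), bC = rowSums(res$dCT)))
}

# ---- Direction path and encoder block ------------------------------------

#' Initialize one direction path (attention + SSM)
#'
#' @param H channel width.
#' @param S state size.
#' @param seed optional integer seed.
#' @return list with `msa` and `ssm` parameter lists.
#' @export
init_direction_params <- function(H, S, seed = NULL) {
  with_seed(seed, list(msa = init_msa_params(H), ssm = init_ssm_params(H, S)))
}

#' One direction of the bidirectional sequence mixer
#'
#' `forward`: attention, SiLU, selective scan, in sequence order.
#' `backward`: the same pipeline (with this path's own parameters) applied
#' to the sequence reversed along the patch axis; the result is reversed
#' back so position t of the output aligns with position t of the forward
#' path.
#'
#' @param x B x J x H numeric array.
#' @param direction `"forward"` or `"backward"`.
#' @param path_params list from [init_direction_params()].
#' @param n_heads attention heads.
#' @param scale_mode,impl attention options, see [multi_head_attention()].
#' @return B x J x H numeric array.
#' @export
direction_path <- function(x, direction = c("forward", "backward"),
                           path_params, n_heads = 12,
                           scale_mode = "sqrt_head_dim", impl = "dense") {
  direction <- match.arg(direction)
  d <- dim(x)
  m <- arr3_to_mat(x)
  y <- dir_path_fwd(m, direction, path_params, d[1L], d[2L], n_heads,
                    scale_mode, impl, want_cache = FALSE)$y
  mat_to_arr3(y, d[1L], d[2L])
}

dir_path_fwd <- function(x, direction, pp, B, J, n_heads, scale_mode, impl,
                         want_cache = FALSE) {
  rev_idx <- if (direction == "backward") rev_seq_index(B, J) else NULL
  xin <- if (is.null(rev_idx)) x else x[rev_idx, , drop = FALSE]
  msa <- msa_forward(xin, pp$msa, B, J, n_heads, scale_mode, impl, want_cache)
  act <- silu(msa$y)
  ssm <- ssm_fwd(act, pp$ssm, B, J, want_cache)
  y <- if (is.null(rev_idx)) ssm$y else ssm$y[rev_idx, , drop = FALSE]
  out <- list(y = y)
  if (want_cache) {
    out$cache <- list(rev_idx = rev_idx, msa = msa$cache, a = msa$y,
                      ssm = ssm$cache)
  }
  out
}

dir_path_bwd <- function(dy, pp, cache) {
  if (!is.null(cache$rev_idx)) dy <- dy[cache$rev_idx, , drop = FALSE]
  sb <- ssm_bwd(dy, pp$ssm, cache$ssm)
  da <- sb$dx * silu_grad(cache$a)
  mb <- msa_backward(da, pp$msa, cache$msa)
  dx <- mb$dx
  if (!is.null(cache$rev_idx)) dx <- dx[cache$rev_idx, , drop = FALSE]
  list(dx = dx, grads = list(msa = mb$grads, ssm = sb$grads))
}

#' Initialize one encoder block
#'
#' @param M model width (token features, = D + 1).
#' @param H internal hidden width; must be divisible by `n_heads`.
#' @param S state size.
#' @param n_heads attention heads.
#' @param seed optional integer seed.
#' @return parameter list for [encoder_block()].
#' @export
init_encoder_block_params <- function(M, H, S, n_heads = 12, seed = NULL) {
  if (H %% n_heads != 0L) {
    stop(sprintf("init_encoder_block_params: H = %d not divisible by n_heads = %d",
                 H, n_heads))
  }
  with_seed(seed, list(
    ln_g = rep(1, M), ln_b = numeric(M),
    Wx = matrix(rnorm(M * H, sd = 1 / sqrt(M)), M, H), bx = numeric(H),
    Wz = matrix(rnorm(M * H, sd = 1 / sqrt(M)), M, H), bz = numeric(H),
    f = init_direction_params(H, S),
    b = init_direction_params(H, S),
    Wo = matrix(rnorm(H * M, sd = 1 / sqrt(H)), H, M), bo = numeric(M)
  ))
}

#' One bidirectional encoder block
#'
#' Normalize, expand to width H twice (`x` and gate branch `z`), run the
#' forward and backward direction paths on `x`, gate both with `silu(z)`,
#' sum, project back to width M, and add the skip connection:
#'
#' `out = Linear_out(silu(z) * (yf + yb)) + tokens`.
#'
#' With all weights zero the block is exactly the identity.
#'
#' @param tokens B x J x M numeric array.
#' @param block_params list from [init_encoder_block_params()].
#' @param n_heads attention heads.
#' @param scale_mode,impl attention options.
#' @return B x J x M numeric array.
#' @export
encoder_block <- function(tokens, block_params, n_heads = 12,
                          scale_mode = "sqrt_head_dim", impl = "dense") {
  d <- dim(tokens)
  m <- arr3_to_mat(tokens)
  y <- enc_block_fwd(m, block_params, d[1L], d[2L], n_heads, scale_mode, impl,
                     want_cache = FALSE)$y
  mat_to_arr3(y, d[1L], d[2L])
}

enc_block_fwd <- function(tok, bp, B, J, n_heads, scale_mode, impl,
                          want_cache = FALSE) {
  n <- nrow(tok)
  ln <- ln_fwd(tok, bp$ln_g, bp$ln_b)
  H <- ncol(bp$Wx)
  xz <- ln$y %*% cbind(bp$Wx, bp$Wz) + rep(c(bp$bx, bp$bz), each = n)
  x <- xz[, seq_len(H), drop = FALSE]
  z <- xz[, H + seq_len(H), drop = FALSE]
  f <- dir_path_fwd(x, "forward", bp$f, B, J, n_heads, scale_mode, impl, want_cache)
  bwd <- dir_path_fwd(x, "backward", bp$b, B, J, n_heads, scale_mode, impl, want_cache)
  g <- silu(z)
  comb <- g * (f$y + bwd$y)
  y <- comb %*% bp$Wo + rep(bp$bo, each = n) + tok
  out <- list(y = y)
  if (want_cache) {
    out$cache <- list(ln = ln$cache, u = ln$y, z = z, g = g,
                      f = f, bwd = bwd, comb = comb)
  }
  out
}

enc_block_bwd <- function(dy, bp, cache) {
  dcomb <- dy %*% t(bp$Wo)
  dWo <- crossprod(cache$comb, dy)
  dbo <- colSums(dy)
  ysum <- cache$f$y + cache$bwd$y
  dg <- dcomb * ysum
  dyf <- dcomb * cache$g
  dz <- dg * silu_grad(cache$z)
  fb <- dir_path_bwd(dyf, bp$f, cache$f$cache)
  bb <- dir_path_bwd(dyf, bp$b, cache$bwd$cache)
  dx <- fb$dx + bb$dx
  du <- dx %*% t(bp$Wx) + dz %*% t(bp$Wz)
  lnb <- ln_bwd(du, cache$ln)
  dtok <- lnb$dx + dy  # skip connection
  list(dx = dtok,
       grads = list(ln_g = lnb$dgain, ln_b = lnb$dbias,
                    Wx = crossprod(cache$u, dx), bx = colSums(dx),
                    Wz = crossprod(cache$u, dz), bz = colSums(dz),
                    f = fb$grads, b = bb$grads,
                    Wo = dWo, bo = dbo))
}

#' Stacked encoder
#'
#' Applies `length(layers)` encoder blocks sequentially (independent
#' parameters per layer); an empty layer list is the identity.
#'
#' @param tokens B x J x M numeric array.
#' @param layers list of block-parameter lists.
#' @param n_heads attention heads.
#' @param scale_mode,impl attention options.
#' @return B x J x M numeric array.
#' @export
encoder_forward <- function(tokens, layers, n_heads = 12,
                            scale_mode = "sqrt_head_dim", impl = "dense") {
  out <- tokens
  for (bp in layers) {
    out <- encoder_block(out, bp, n_heads, scale_mode, impl)
  }
  out
}
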