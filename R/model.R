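#' Model configuration
#'
#' Architecture and evaluation options of the pupil-center detector.
#' Defaults follow the selected full-scale configuration (16 x 16 patches,
#' 12 attention heads, gaussian patch-weight initialization, 320 x 240
#' frame); the embedding width D, hidden width H, state size S and layer
#' count are free choices exposed here. H defaults to twice the token
#' width M = D + 1, rounded up to the next multiple of `n_heads` so the
#' head split is exact.
#'
#' @param image_width,image_height model input frame, pixels.
#' @param patch_size patch side length p; must divide both frame sides.
#' @param embed_dim token embedding width D.
#' @param n_layers number of encoder blocks.
#' @param n_heads attention heads.
#' @param hidden_width internal width H (NULL = `2 * (D + 1)` rounded up
#'   to a multiple of `n_heads`).
#' @param state_size SSM state size S per channel.
#' @param weight_init patch-weight scheme, see [init_patch_weights()].
#' @param sigma_s,sigma_n gaussian-scheme scales, see
#'   [init_patch_weights()].
#' @param scale_mode attention score scale, see [multi_head_attention()].
#' @param attention_impl `"fft"` (normative inference route) or `"dense"`;
#'   training always differentiates through the dense product, which is
#'   numerically equivalent (see the test suite).
#' @param pool_norm pooling normalization, see [weighted_pool()].
#' @param head_hidden MLP hidden width (NULL = D / 2).
#' @return list of class `vimsa_config`.
#' @export
vimsa_config <- function(image_width = 320, image_height = 240,
                         patch_size = 16, embed_dim = 192,
                         n_layers = 4, n_heads = 12, hidden_width = NULL,
                         state_size = 16,
                         weight_init = c("gaussian", "fixed", "random"),
                         sigma_s = 15, sigma_n = 0.1,
                         scale_mode = c("sqrt_head_dim", "sqrt_num_heads"),
                         attention_impl = c("fft", "dense"),
                         pool_norm = c("count", "weight_sum"),
                         head_hidden = NULL) {
  weight_init <- match.arg(weight_init)
  scale_mode <- match.arg(scale_mode)
  attention_impl <- match.arg(attention_impl)
  pool_norm <- match.arg(pool_norm)
  if (image_width %% patch_size != 0 || image_height %% patch_size != 0) {
    stop(sprintf("vimsa_config: frame %d x %d not divisible by patch_size %d",
                 image_width, image_height, patch_size))
  }
  M <- embed_dim + 1L
  if (is.null(hidden_width)) {
    hidden_width <- as.integer(ceiling(2 * M / n_heads) * n_heads)
  }
  if (hidden_width %% n_heads != 0) {
    stop(sprintf("vimsa_config: hidden_width %d not divisible by n_heads %d",
                 hidden_width, n_heads))
  }
  if (is.null(head_hidden)) head_hidden <- max(2L, embed_dim %/% 2L)
  grid_rows <- image_height %/% patch_size
  grid_cols <- image_width %/% patch_size
  structure(list(
    image_width = image_width, image_height = image_height,
    patch_size = patch_size, embed_dim = embed_dim,
    model_width = M, n_layers = n_layers, n_heads = n_heads,
    hidden_width = hidden_width, state_size = state_size,
    grid_rows = grid_rows, grid_cols = grid_cols,
    n_patches = grid_rows * grid_cols,
    weight_init = weight_init, sigma_s = sigma_s, sigma_n = sigma_n,
    scale_mode = scale_mode, attention_impl = attention_impl,
    pool_norm = pool_norm, head_hidden = head_hidden
  ), class = "vimsa_config")
}

#' Initialize the positional-embedding table
#'
#' Learnable J x D table. The first two feature channels are seeded with
#' the normalized patch-center coordinates (x/width - 1/2, y/height - 1/2)
#' so position is available to the encoder from the first step — the
#' coordinate-regression analogue of anchor features; the remaining
#' channels start Normal(0, 0.02). All entries remain trainable.
#'
#' @param config a [vimsa_config()].
#' @param seed optional integer seed.
#' @return J x D numeric matrix, patches in row-major grid order.
#' @export
init_pos_embedding <- function(config, seed = NULL) {
  with_seed(seed, {
    J <- config$n_patches
    D <- config$embed_dim
    p <- config$patch_size
    pos <- matrix(rnorm(J * D, sd = 0.02), J, D)
    cx <- (rep(seq_len(config$grid_cols), times = config$grid_rows) - 0.5) * p - 0.5
    cy <- (rep(seq_len(config$grid_rows), each = config$grid_cols) - 0.5) * p - 0.5
    pos[, 1L] <- cx / config$image_width - 0.5
    pos[, 2L] <- cy / config$image_height - 0.5
    pos
  })
}

#' Initialize a detector model
#'
#' Draws all parameters (patch projection, positional embedding table,
#' patch weights, encoder blocks, regression head) from seeded Gaussian /
#' scheme-specific initializers. Pixel intensities are scaled to \[0, 1\]
#' inside the forward pass; predictions are in pixels of the model frame.
#'
#' @param config a [vimsa_config()].
#' @param seed optional integer seed; the model is a pure function of
#'   (config, seed).
#' @return object of class `vimsa_model`: list with `config` and `params`.
#' @export
vimsa_model <- function(config, seed = NULL) {
  with_seed(seed, {
    p <- config$patch_size
    D <- config$embed_dim
    J <- config$n_patches
    params <- list(
      Wproj = matrix(rnorm(p * p * D, sd = 1 / p), p * p, D),
      bproj = numeric(D),
      pos = init_pos_embedding(config),
      pw = as.numeric(init_patch_weights(
        config$grid_rows, config$grid_cols, p, scheme = config$weight_init,
        sigma_s = config$sigma_s, sigma_n = config$sigma_n)),
      blocks = lapply(seq_len(config$n_layers), function(l) {
        init_encoder_block_params(config$model_width, config$hidden_width,
                                  config$state_size, config$n_heads)
      }),
      head = init_mlp_head(D, hidden = config$head_hidden,
                           center = c(config$image_width / 2,
                                      config$image_height / 2))
    )
    structure(list(config = config, params = params), class = "vimsa_model")
  })
}

#' Full forward pass
#'
#' Patch extraction, linear embedding + positional table, weight-channel
#' concatenation, the stacked bidirectional encoder, weight removal,
#' weight-modulated pooling, and the regression MLP.
#'
#' @param model a `vimsa_model`.
#' @param images list of height x width pixel matrices (gray levels
#'   0-255), all matching the configured frame.
#' @param impl attention route override (default: the model's configured
#'   `attention_impl`).
#' @return B x 2 matrix of predicted centers (x, y), pixels.
#' @export
vimsa_forward <- function(model, images, impl = NULL) {
  if (is.null(impl)) impl <- model$config$attention_impl
  fw <- model_fwd(model$params, model$config, images, impl, want_cache = FALSE)
  fw$pred
}

# Internal forward; images is a list of h x w matrices. P may carry the
# precomputed (B*J) x p^2 patch matrix (intensities already in [0, 1]) so
# the training loop tiles each image only once.
model_fwd <- function(params, cfg, images, impl, want_cache = FALSE, P = NULL) {
  B <- if (is.null(P)) length(images) else nrow(P) %/% cfg$n_patches
  J <- cfg$n_patches
  D <- cfg$embed_dim
  if (is.null(P)) {
    patches <- extract_patches(images, cfg$patch_size)
    P <- arr3_to_mat(patches$values) / 255  # (B*J) x p^2, in [0,1]
  }
  tok <- P %*% params$Wproj + rep(params$bproj, each = B * J)
  tok <- tok + params$pos[rep(seq_len(J), times = B), , drop = FALSE]
  fused <- cbind(tok, rep(params$pw, times = B))
  caches <- if (want_cache) vector("list", length(params$blocks)) else NULL
  h <- fused
  for (l in seq_along(params$blocks)) {
    r <- enc_block_fwd(h, params$blocks[[l]], B, J, cfg$n_heads,
                       cfg$scale_mode, impl, want_cache)
    h <- r$y
    if (want_cache) caches[[l]] <- r$cache
  }
  tk <- h[, seq_len(D), drop = FALSE]
  wc <- h[, D + 1L]
  # Pooling: feature[b, ] = sum_j wc * tk / norm over each batch block.
  grp <- rep(seq_len(B), each = J)
  wtk <- tk * wc
  norm <- if (cfg$pool_norm == "count") rep(J, B) else
    as.numeric(rowsum(wc, grp))
  feat <- rowsum(wtk, grp) / norm
  h1 <- feat %*% params$head$W1 + rep(params$head$b1, each = B)
  a1 <- silu(h1)
  pred <- a1 %*% params$head$W2 + rep(params$head$b2, each = B)
  out <- list(pred = pred)
  if (want_cache) {
    out$cache <- list(P = P, fused = fused, enc = caches, enc_out = h,
                      tk = tk, wc = wc, feat = feat, h1 = h1, a1 = a1,
                      norm = norm, B = B, J = J)
  }
  out
}

# Backward pass; dpred is B x 2. Returns the full gradient tree.
model_bwd <- function(params, cfg, cache, dpred) {
  B <- cache$B; J <- cache$J; D <- cfg$embed_dim
  g <- list()
  da1 <- dpred %*% t(params$head$W2)
  g$head <- list(
    W1 = NULL, b1 = NULL,
    W2 = crossprod(cache$a1, dpred), b2 = colSums(dpred)
  )
  dh1 <- da1 * silu_grad(cache$h1)
  g$head$W1 <- crossprod(cache$feat, dh1)
  g$head$b1 <- colSums(dh1)
  dfeat <- dh1 %*% t(params$head$W1)
  # Pooling backward (count normalization: norm is constant in w).
  dwtk <- dfeat[rep(seq_len(B), each = J), , drop = FALSE] / cache$norm[rep(seq_len(B), each = J)]
  if (cfg$pool_norm == "weight_sum") {
    # d norm term: feat = s / n with n = sum(wc); dL/dwc gets -feat . dfeat / n
    extra <- rowSums(dfeat * cache$feat) / cache$norm
    dwc_norm <- -extra[rep(seq_len(B), each = J)]
  } else {
    dwc_norm <- 0
  }
  dtk <- dwtk * cache$wc
  dwc <- rowSums(dwtk * cache$tk) + dwc_norm
  denc <- cbind(dtk, dwc)
  for (l in rev(seq_along(params$blocks))) {
    r <- enc_block_bwd(denc, params$blocks[[l]], cache$enc[[l]])
    denc <- r$dx
    if (is.null(g$blocks)) g$blocks <- vector("list", length(params$blocks))
    g$blocks[[l]] <- r$grads
  }
  dtok <- denc[, seq_len(D), drop = FALSE]
  dwcol <- denc[, D + 1L]
  jgrp <- rep(seq_len(J), times = B)
  g$pw <- as.numeric(rowsum(matrix(dwcol), jgrp))
  g$pos <- rowsum(dtok, jgrp)
  g$Wproj <- crossprod(cache$P, dtok)
  g$bproj <- colSums(dtok)
  g[c("Wproj", "bproj", "pos", "pw", "blocks", "head")]
}

# Loss + gradient for one mini-batch: RMSE over Euclidean center errors.
model_loss_grad <- function(params, cfg, images, truths, P = NULL) {
  fw <- model_fwd(params, cfg, images, impl = "dense", want_cache = TRUE, P = P)
  d <- fw$pred - truths
  mse <- mean(rowSums(d * d))
  loss <- sqrt(mse)
  dpred <- if (loss > 0) d / (nrow(d) * loss) else d * 0
  list(loss = loss, pred = fw$pred,
       grads = model_bwd(params, cfg, fw$cache, dpred))
}

# ---- Parameter-tree utilities (used by the optimizers) -------------------

tree_map <- function(f, tree) {
  if (is.list(tree)) lapply(tree, function(t) tree_map(f, t)) else f(tree)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else {
    f(a, b)
  }
}

tree_map3 <- function(f, a, b, c) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map3(f, a[[i]], b[[i]], c[[i]])
    out
  } else {
    f(a, b, c)
  }
}

tree_zero <- function(tree) tree_map(function(x) x * 0, tree)

# ---- Model persistence (plain-text checkpoint) ---------------------------

#' Save a model checkpoint
#'
#' Single YAML file with the config and all parameters (flattened, full
#' double precision via base-R `dput`-style text); text-only on purpose.
#'
#' @param model a `vimsa_model`.
#' @param path output file.
#' @export
save_vimsa <- function(model, path) {
  flat <- list()
  walk <- function(tree, prefix) {
    if (is.list(tree)) {
      nm <- names(tree)
      if (is.null(nm)) nm <- as.character(seq_along(tree))
      for (i in seq_along(tree)) walk(tree[[i]], paste0(prefix, "/", nm[i]))
    } else {
      flat[[prefix]] <<- list(dim = dim(tree) %||% length(tree),
                              data = sprintf("%.17g", as.numeric(tree)))
    }
  }
  walk(model$params, "params")
  yaml::write_yaml(list(config = unclass(model$config), params = flat), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a model checkpoint written by [save_vimsa()]
#'
#' @param path checkpoint file.
#' @return a `vimsa_model`.
#' @export
load_vimsa <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- raw$config
  class(cfg) <- "vimsa_config"
  model <- vimsa_model(cfg, seed = 1)  # structure template; values replaced
  for (key in names(raw$params)) {
    parts <- strsplit(sub("^params/", "", key), "/", fixed = TRUE)[[1L]]
    val <- as.numeric(raw$params[[key]]$data)
    dm <- raw$params[[key]]$dim
    if (length(dm) > 1L) dim(val) <- unlist(dm)
    model$params <- assign_path(model$params, parts, val)
  }
  model
}

assign_path <- function(tree, parts, val) {
  p <- parts[[1L]]
  idx <- suppressWarnings(as.integer(p))
  key <- if (!is.na(idx)) idx else p
  if (length(parts) == 1L) {
    tree[[key]] <- val
  } else {
    tree[[key]] <- assign_path(tree[[key]], parts[-1L], val)
  }
  tree
}
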