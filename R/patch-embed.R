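#' Extract non-overlapping patches from an image batch
#'
#' Tiles each h x w image into J = (h/p)(w/p) square patches of side `p`,
#' ordered row-major over the patch grid (left to right, top to bottom),
#' each patch flattened in row-major pixel order. The tiling is lossless:
#' [patches_to_image()] reassembles the input bit-exactly.
#'
#' @param images a single h x w matrix, a list of such matrices, or a
#'   B x h x w array.
#' @param p patch side length; must divide both h and w.
#' @return object of class `patch_sequence`: list with `values`
#'   (B x J x p^2 array), `p`, `grid_rows`, `grid_cols`.
#' @export
#' @examples
#' ps <- extract_patches(matrix(1:16, 4, 4, byrow = TRUE), p = 2)
#' ps$grid_rows * ps$grid_cols  # J = 4
extract_patches <- function(images, p) {
  if (is.matrix(images)) images <- list(images)
  if (is.array(images) && length(dim(images)) == 3L) {
    images <- lapply(seq_len(dim(images)[1L]), function(b) images[b, , ])
  }
  h <- nrow(images[[1L]]); w <- ncol(images[[1L]])
  if (h %% p != 0 || w %% p != 0) {
    stop(sprintf("extract_patches: image %d x %d not divisible by patch size %d",
                 h, w, p))
  }
  gr <- h %/% p; gc <- w %/% p
  J <- gr * gc
  B <- length(images)
  vals <- array(0, dim = c(B, J, p * p))
  for (b in seq_len(B)) {
    img <- images[[b]]
    for (gy in seq_len(gr)) {
      for (gx in seq_len(gc)) {
        j <- (gy - 1L) * gc + gx
        block <- img[((gy - 1L) * p + 1L):(gy * p),
                     ((gx - 1L) * p + 1L):(gx * p), drop = FALSE]
        vals[b, j, ] <- as.vector(t(block))  # row-major pixel order
      }
    }
  }
  structure(list(values = vals, p = p, grid_rows = gr, grid_cols = gc),
            class = "patch_sequence")
}

#' Reassemble images from a patch sequence
#'
#' Inverse of [extract_patches()].
#'
#' @param patches a `patch_sequence`.
#' @return list of h x w matrices, one per batch element.
#' @export
patches_to_image <- function(patches) {
  v <- patches$values
  p <- patches$p; gr <- patches$grid_rows; gc <- patches$grid_cols
  B <- dim(v)[1L]
  lapply(seq_len(B), function(b) {
    img <- matrix(0, gr * p, gc * p)
    for (gy in seq_len(gr)) {
      for (gx in seq_len(gc)) {
        j <- (gy - 1L) * gc + gx
        img[((gy - 1L) * p + 1L):(gy * p), ((gx - 1L) * p + 1L):(gx * p)] <-
          matrix(v[b, j, ], p, p, byrow = TRUE)
      }
    }
    img
  })
}

#' Linearly project patches and add positional embeddings
#'
#' `tokens[b, j, ] = patches[b, j, ] %*% W + bias + pos[j, ]`.
#'
#' @param patches a `patch_sequence` (or B x J x p^2 array).
#' @param projection list with `W` (p^2 x D matrix) and optional `b`
#'   (length-D bias).
#' @param pos J x D positional-embedding matrix (or NULL for none).
#' @return B x J x D numeric array of tokens.
#' @export
embed_patches <- function(patches, projection, pos = NULL) {
  v <- if (inherits(patches, "patch_sequence")) patches$values else patches
  d <- dim(v)
  W <- projection$W
  if (nrow(W) != d[3L]) {
    stop(sprintf("embed_patches: projection maps %d inputs but patches have %d",
                 nrow(W), d[3L]))
  }
  D <- ncol(W)
  bvec <- if (is.null(projection$b)) numeric(D) else projection$b
  m <- arr3_to_mat(v) %*% W + rep(bvec, each = d[1L] * d[2L])
  if (!is.null(pos)) {
    if (nrow(pos) != d[2L] || ncol(pos) != D) {
      stop("embed_patches: positional embedding shape mismatch")
    }
    m <- m + pos[rep(seq_len(d[2L]), times = d[1L]), , drop = FALSE]
  }
  mat_to_arr3(m, d[1L], d[2L])
}

#' Initialize the learnable per-patch weight vector
#'
#' Three schemes for the weight channel of the weighted feature fusion:
#' \describe{
#'   \item{fixed}{all weights exactly 1.}
#'   \item{random}{i.i.d. uniform on \[1e-5, 1\].}
#'   \item{gaussian}{`G(d_j) + eps_j`, where `d_j` is the distance in
#'     pixels from patch j's center to the image center, `G` is an
#'     isotropic Gaussian bump with peak 1 and spatial scale `sigma_s`
#'     (default 15 px, so the 30 x 30 central pixel region spans about
#'     one sigma), and `eps_j ~ Normal(0, sigma_n)` breaks ties between
#'     patches (default `sigma_n` 0.1).}
#' }
#' The gaussian scheme biases the initial weights toward the image center,
#' where the pupil usually sits, while the noise term gives each patch a
#' distinct starting weight.
#'
#' @param grid_rows,grid_cols patch-grid shape.
#' @param p patch side length in pixels.
#' @param scheme one of `"fixed"`, `"random"`, `"gaussian"`.
#' @param sigma_s spatial scale of the gaussian bump, pixels.
#' @param sigma_n standard deviation of the additive gaussian noise.
#' @param seed optional integer seed.
#' @return numeric vector of length `grid_rows * grid_cols`, patches in
#'   row-major grid order, with attribute `init_scheme`.
#' @export
init_patch_weights <- function(grid_rows, grid_cols, p,
                               scheme = c("gaussian", "fixed", "random"),
                               sigma_s = 15, sigma_n = 0.1, seed = NULL) {
  scheme <- match.arg(scheme)
  if (!is_count(grid_rows) || !is_count(grid_cols) || !is_count(p)) {
    stop("init_patch_weights: grid_rows, grid_cols and p must be positive integers")
  }
  J <- grid_rows * grid_cols
  w <- with_seed(seed, switch(
    scheme,
    fixed = rep(1, J),
    random = runif(J, 1e-5, 1),
    gaussian = {
      # Patch centers in pixel coordinates, row-major grid order.
      cx <- (rep(seq_len(grid_cols), times = grid_rows) - 0.5) * p - 0.5
      cy <- (rep(seq_len(grid_rows), each = grid_cols) - 0.5) * p - 0.5
      icx <- (grid_cols * p - 1) / 2
      icy <- (grid_rows * p - 1) / 2
      d2 <- (cx - icx)^2 + (cy - icy)^2
      exp(-d2 / (2 * sigma_s^2)) + rnorm(J, 0, sigma_n)
    }
  ))
  attr(w, "init_scheme") <- scheme
  w
}

#' Concatenate the patch-weight channel onto a token sequence
#'
#' Appends one weight per patch as the last feature channel, shared across
#' the batch, giving the fused sequence of width D + 1 that flows through
#' the encoder. [remove_weights()] is the exact inverse.
#'
#' @param tokens B x J x D numeric array.
#' @param weights length-J numeric weight vector.
#' @return B x J x (D+1) numeric array.
#' @export
concat_weights <- function(tokens, weights) {
  d <- dim(tokens)
  if (length(d) != 3L) stop("concat_weights: tokens must be a B x J x D array")
  if (length(weights) != d[2L]) {
    stop(sprintf("concat_weights: %d weights for %d patches",
                 length(weights), d[2L]))
  }
  out <- array(0, dim = c(d[1L], d[2L], d[3L] + 1L))
  out[, , seq_len(d[3L])] <- tokens
  out[, , d[3L] + 1L] <- matrix(weights, d[1L], d[2L], byrow = TRUE)
  out
}
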