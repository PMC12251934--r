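# Internal helpers shared across modules.

# Batch-of-sequences layout: a B x J x F array is stored internally as a
# (B*J) x F matrix whose rows are grouped by batch element (rows
# (b-1)*J + 1 ... b*J hold sequence b, in order).

arr3_to_mat <- function(a) {
  d <- dim(a)
  stopifnot(length(d) == 3L)
  m <- array(aperm(a, c(2L, 1L, 3L)), dim = c(d[1L] * d[2L], d[3L]))
  m
}

mat_to_arr3 <- function(m, B, J) {
  F <- ncol(m)
  aperm(array(m, dim = c(J, B, F)), c(2L, 1L, 3L))
}

# Reverse each batch block of J rows (sequence reversal along the patch axis).
rev_seq_index <- function(B, J) {
  B <- as.integer(B); J <- as.integer(J)
  as.vector(vapply(seq_len(B), function(b) (b - 1L) * J + J:1L, integer(J)))
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)
}

next_pow2 <- function(n) {
  stopifnot(n >= 1)
  p <- 1L
  while (p < n) p <- p * 2L
  p
}

is_pow2 <- function(n) {
  n >= 1 && bitwAnd(as.integer(n), as.integer(n) - 1L) == 0L
}

# Numerically stable softplus; branch cut matches the compiled kernel
# exactly so the reference and compiled scans agree to the last ulp.
softplus <- function(x) {
  out <- log1p(exp(pmin(x, 30)))
  big <- x > 30
  if (any(big)) out[big] <- x[big]
  out
}

# Local RNG scope: run expr with a fresh seed without clobbering the
# caller's RNG stream; seed = NULL uses (and advances) the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.null(seed) && (!is.numeric(seed) || length(seed) != 1L)) {
    stop("seed must be a single integer or NULL")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
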