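# Fourier primitives, the outer-product/FFT matrix product, and attention.

test_that("naive DFT reproduces impulse, constant, and library-oracle spectra", {
  expect_equal(dft_naive(c(1, 0, 0, 0)), as.complex(rep(1, 4)))
  expect_equal(dft_naive(c(1, 1, 1, 1)), as.complex(c(4, 0, 0, 0)))
  set.seed(4)
  x <- complex(real = rnorm(16), imaginary = rnorm(16))
  expect_lt(max(Mod(dft_naive(x) - stats::fft(x))) / sqrt(sum(Mod(x)^2)),
            1e-10)
  expect_error(dft_naive(numeric(0)), "length")
})

test_that("radix-2 FFT pads, records the input length, and matches the naive oracle", {
  imp <- fft_radix2(c(1, rep(0, 7)))
  expect_equal(as.complex(imp), as.complex(rep(1, 8)), ignore_attr = TRUE)
  set.seed(5)
  x5 <- rnorm(5)  # padded to 8
  X <- fft_radix2(x5)
  expect_length(X, 8)
  expect_equal(attr(X, "n_input"), 5)
  expect_equal(as.complex(X), dft_naive(c(x5, 0, 0, 0)), ignore_attr = TRUE)
})

test_that("FFT equals naive DFT and satisfies Parseval on power-of-two lengths", {
  set.seed(6)
  for (n in 2^(0:7)) {
    x <- rnorm(n)
    X <- fft_radix2(x)
    nrm <- sqrt(sum(x^2))
    expect_lt(max(Mod(as.complex(X) - dft_naive(x))), 1e-9 * max(nrm, 1))
    expect_lt(abs(sum(x^2) - sum(Mod(X)^2) / n), 1e-9 * max(nrm^2, 1))
  }
})

test_that("inverse FFT inverts, maps the impulse spectrum to ones, and is linear", {
  set.seed(7)
  x <- rnorm(32)
  expect_lt(max(Mod(ifft_radix2(fft_radix2(x)) - x)), 1e-9)
  expect_equal(Re(ifft_radix2(complex(real = c(8, rep(0, 7))))), rep(1, 8))
  X <- fft_radix2(rnorm(16)); Y <- fft_radix2(rnorm(16))
  lhs <- ifft_radix2(2 * X - 3 * Y)
  rhs <- 2 * ifft_radix2(X) - 3 * ifft_radix2(Y)
  expect_lt(max(Mod(lhs - rhs)), 1e-12)
})

test_that("outer product matches its definition and has rank at most one", {
  expect_equal(outer_product(c(1, 0), c(0, 1)),
               matrix(c(0, 0, 1, 0), 2, 2))
  set.seed(8)
  a <- rnorm(5); b <- rnorm(3)
  M <- outer_product(a, b)
  for (i in 1:5) for (j in 1:3) expect_equal(M[i, j], a[i] * b[j])
  expect_lte(qr(M)$rank, 1)
})

test_that("outer-product/FFT matmul reproduces hand and direct products", {
  A <- matrix(c(1, 3, 2, 4), 2, 2)
  B <- matrix(c(5, 7, 6, 8), 2, 2)
  expect_equal(matmul_outer_fft(A, B),
               matrix(c(19, 43, 22, 50), 2, 2), tolerance = 1e-10)
  set.seed(9)
  I4 <- diag(4); R4 <- matrix(rnorm(16), 4, 4)
  expect_lt(max(abs(matmul_outer_fft(I4, R4) - R4)), 1e-8)
  expect_error(matmul_outer_fft(matrix(0, 2, 3), matrix(0, 2, 2)), "dimensions")
})

test_that("FFT matmul stays within 1e-6 relative of the direct product on random rectangles", {
  set.seed(10)
  for (i in 1:25) {
    m <- sample(1:64, 1); n <- sample(1:64, 1); p <- sample(1:64, 1)
    A <- matrix(rnorm(m * n), m, n)
    B <- matrix(rnorm(n * p), n, p)
    err <- max(abs(matmul_outer_fft(A, B) - A %*% B))
    expect_lt(err, 1e-6 * max(1, norm(A, "F") * norm(B, "F")))
  }
})

test_that("scaled attention handles degenerate cases exactly", {
  # J = 1: softmax of a scalar is 1, output is V
  V1 <- matrix(c(3, -2), 1, 2)
  expect_equal(scaled_dot_product_attention(matrix(1, 1, 2), matrix(2, 1, 2),
                                            V1, impl = "dense"), V1)
  expect_equal(scaled_dot_product_attention(matrix(1, 1, 2), matrix(2, 1, 2),
                                            V1, impl = "fft"), V1,
               tolerance = 1e-10)
  # identical K rows: uniform weights, output = column means of V
  set.seed(11)
  Q <- matrix(rnorm(12), 4, 3)
  K <- matrix(rep(rnorm(3), each = 4), 4, 3)
  V <- matrix(rnorm(12), 4, 3)
  out <- scaled_dot_product_attention(Q, K, V, impl = "dense")
  expect_equal(out, matrix(rep(colMeans(V), each = 4), 4, 3))
  expect_error(scaled_dot_product_attention(Q * NA, K, V), "finite")
})

test_that("attention matches the independent loop oracle on both routes", {
  set.seed(12)
  Q <- matrix(rnorm(32), 8, 4); K <- matrix(rnorm(32), 8, 4)
  V <- matrix(rnorm(32), 8, 4)
  want <- dense_attention_oracle(Q, K, V, 1 / sqrt(4))
  expect_lt(max(abs(scaled_dot_product_attention(Q, K, V, impl = "dense") - want)), 1e-6)
  expect_lt(max(abs(scaled_dot_product_attention(Q, K, V, impl = "fft") - want)), 1e-6)
})

test_that("multi-head attention preserves shape, batch independence, and equivariance", {
  set.seed(13)
  tok <- rand_tokens(3, 10, 8, seed = 13)
  mp <- init_msa_params(8, seed = 14)
  out <- multi_head_attention(tok, mp, n_heads = 4)
  expect_equal(dim(out), dim(tok))
  # permuting batch elements permutes outputs identically
  perm <- c(2, 3, 1)
  out_p <- multi_head_attention(tok[perm, , , drop = FALSE], mp, n_heads = 4)
  expect_equal(out_p, out[perm, , , drop = FALSE])
  # permuting token positions permutes outputs identically (no positions here)
  jp <- sample(10)
  out_j <- multi_head_attention(tok[, jp, , drop = FALSE], mp, n_heads = 4)
  expect_equal(out_j, out[, jp, , drop = FALSE], tolerance = 1e-12)
  expect_error(multi_head_attention(tok, mp, n_heads = 3), "divisible")
})

test_that("single-head attention equals the dense per-matrix computation", {
  set.seed(15)
  tok <- rand_tokens(2, 6, 4, seed = 15)
  mp <- init_msa_params(4, seed = 16)
  out <- multi_head_attention(tok, mp, n_heads = 1)
  for (b in 1:2) {
    x <- matrix(tok[b, , ], 6, 4)
    Q <- x %*% mp$Wq + rep(mp$bq, each = 6)
    K <- x %*% mp$Wk + rep(mp$bk, each = 6)
    V <- x %*% mp$Wv + rep(mp$bv, each = 6)
    want <- dense_attention_oracle(Q, K, V, 0.5) %*% mp$Wo +
      rep(mp$bo, each = 6)
    expect_equal(matrix(out[b, , ], 6, 4), want, tolerance = 1e-10)
  }
})

test_that("attention softmax rows sum to one in the workspace", {
  set.seed(17)
  x <- matrix(rnorm(12 * 8), 12, 8)
  fw <- vimsa:::msa_forward(x, init_msa_params(8, seed = 18), B = 2, J = 6,
                            n_heads = 2, scale_mode = "sqrt_head_dim",
                            impl = "dense", want_cache = TRUE)
  for (P in fw$cache$P) {
    expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-9)
  }
})

test_that("operation-count report evaluates the printed formulas", {
  r8 <- count_operations(8)
  expect_equal(r8$direct_mults, 512)
  expect_equal(r8$direct_adds, 448)
  expect_equal(r8$paper_claim_mults, 88)
  expect_equal(r8$paper_claim_adds, 24)
  r1 <- count_operations(1)
  expect_equal(r1$paper_claim_adds, 0)
  expect_error(count_operations(12), "power of two")
  rm <- count_operations(8, measure = TRUE)
  # the construction's measured cost exceeds the printed claim
  expect_gt(rm$measured_mults, rm$paper_claim_mults)
})
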