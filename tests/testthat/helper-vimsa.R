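# Shared fixtures: everything is generated in code at test time.

# Nuisance-free generator config on a small frame; exact renders make
# centroid oracles sharp. Pupil size scales with the frame.
easy_eye_config <- function(w = 64, h = 48) {
  if (min(w, h) >= 40) {
    rr <- c(4, 9); mg <- 10
  } else {
    rr <- c(2, 3); mg <- 5
  }
  eye_config(image_width = w, image_height = h,
             pupil_radius_range = rr, margin = mg,
             glint_probability = 0, occluder_probability = 0,
             illumination_gradient_amplitude = 0, noise_std = 0,
             glint_radius = 1)
}

# Small encoder configuration used across structural tests.
tiny_model_config <- function(n_layers = 1, ...) {
  vimsa_config(image_width = 16, image_height = 16, patch_size = 8,
               embed_dim = 6, n_layers = n_layers, n_heads = 2,
               hidden_width = 8, state_size = 3, ...)
}

# Random token batch as a B x J x F array.
rand_tokens <- function(B, J, F, seed = 1) {
  set.seed(seed)
  array(rnorm(B * J * F), dim = c(B, J, F))
}

# Straight-line dense attention written independently of the package
# internals (loop oracle).
dense_attention_oracle <- function(Q, K, V, scale) {
  J <- nrow(Q)
  S <- matrix(0, J, nrow(K))
  for (i in seq_len(J)) for (j in seq_len(nrow(K))) {
    S[i, j] <- sum(Q[i, ] * K[j, ]) * scale
  }
  P <- matrix(0, J, nrow(K))
  for (i in seq_len(J)) {
    e <- exp(S[i, ] - max(S[i, ]))
    P[i, ] <- e / sum(e)
  }
  P %*% V
}
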