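# Shared fixtures: tiny configurations and generated sequences so tests
# stay fast and fully in-code.

tiny_config <- function(L_in = 32L, d_model = 16L, n_layer = 2L, seed = 42L, ...) {
  hyena_config(
    L_in = L_in, d_model = d_model, n_layer = n_layer,
    filter_mlp_hidden = 8L, pos_feat_dim = 5L, seed = seed, ...
  )
}

random_dna <- function(n, seed = 1L) {
  genolm:::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                 collapse = ""))
}

random_window <- function(L = 32L, seed = 1L, sample_id = "s", chrom_id = "chr1") {
  g <- genome_sequence(sample_id, chrom_id, random_dna(L, seed))
  segment_all(g, L)[[1]]
}

# brute-force causal convolution: multiply by the lower-triangular
# Toeplitz matrix of each channel's filter
toeplitz_conv <- function(u, h) {
  L <- nrow(u)
  out <- matrix(0, L, ncol(u))
  for (cc in seq_len(ncol(u))) {
    for (t in seq_len(L)) {
      acc <- 0
      for (s in seq_len(t)) acc <- acc + h[t - s + 1, cc] * u[s, cc]
      out[t, cc] <- acc
    }
  }
  out
}
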