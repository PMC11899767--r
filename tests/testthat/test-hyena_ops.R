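test_that("FFT causal convolution matches the Toeplitz oracle", {
  set.seed(11)
  for (L in c(1L, 2L, 3L, 5L, 17L, 64L)) {
    u <- matrix(rnorm(L * 3), L, 3)
    h <- matrix(rnorm(L * 3), L, 3)
    y <- fft_causal_conv(u, h)
    yo <- toeplitz_conv(u, h)
    expect_lt(max(abs(y - yo)) / max(abs(yo)), 1e-10)
  }
  expect_error(fft_causal_conv(matrix(0, 3, 2), matrix(0, 4, 2)), "shape")
})

test_that("impulse filters act as identity and shift", {
  set.seed(12)
  L <- 16L
  u <- matrix(rnorm(L * 2), L, 2)
  h0 <- matrix(0, L, 2); h0[1, ] <- 1
  expect_equal(fft_causal_conv(u, h0), u, tolerance = 1e-12)
  h1 <- matrix(0, L, 2); h1[2, ] <- 1
  y <- fft_causal_conv(u, h1)
  expect_equal(y[1, ], c(0, 0), tolerance = 1e-12)
  expect_equal(y[2:L, ], u[1:(L - 1), ], tolerance = 1e-12)
})

test_that("positional features are deterministic, boundary-correct functions of t", {
  z1 <- positional_features(1L, 5L)
  expect_identical(dim(z1), c(1L, 5L))
  expect_identical(z1[1, 1], 0)
  expect_identical(positional_features(64L, 9L), positional_features(64L, 9L))
  # with a fixed scale, row t depends only on t, not on L
  a <- positional_features(8L, 7L, scale = 128)
  b <- positional_features(16L, 7L, scale = 128)
  expect_equal(a, b[1:8, , drop = FALSE], tolerance = 1e-15)
})

test_that("implicit filters extend across lengths and keep a fixed parameter count", {
  cfg <- tiny_config()
  m <- init_hyena(cfg)
  fp <- m$params$blocks[[1]]$filter
  h8 <- implicit_filter(fp, 8L, scale = cfg$L_in)
  h16 <- implicit_filter(fp, 16L, scale = cfg$L_in)
  expect_equal(h8, h16[1:8, , drop = FALSE], tolerance = 1e-15)
  # strong decay sends late filter taps to zero
  fp2 <- fp
  fp2$log_alpha <- rep(log(2), cfg$d_model)
  h <- implicit_filter(fp2, 64L, scale = cfg$L_in)
  expect_lt(max(abs(h[64, ])), 1e-20)
})

test_that("the Hyena operator gates and annihilates as its algebra dictates", {
  cfg <- tiny_config(n_layer = 1L)
  m <- init_hyena(cfg)
  blk <- m$params$blocks[[1]]
  d <- cfg$d_model
  set.seed(13)
  u <- matrix(rnorm(20 * d, sd = 0.5), 20, d)
  # zeroing the x1 projection (first d output columns) kills the output
  blk0 <- blk
  blk0$W_in[, 1:d] <- 0
  blk0$b_in[1:d] <- 0
  expect_equal(max(abs(hyena_operator(u, blk0, cfg))), 0)
  # lag-0 impulse filter with unit x2 gate reduces to x1 * v
  blk1 <- blk
  blk1$filter$Wf1[] <- 0; blk1$filter$bf1[] <- 0
  blk1$filter$Wf2[] <- 0; blk1$filter$bf2[] <- 1
  blk1$filter$log_alpha <- rep(log(1e8), d)  # envelope ~ impulse at t = 0
  # make x2 identically one: zero its projection and shift bias, kill its short conv lags
  blk1$W_in[, d + 1:d] <- 0
  blk1$b_in[d + 1:d] <- 1
  blk1$K[2:nrow(blk1$K), d + 1:d] <- 0
  blk1$K[1, d + 1:d] <- 1
  y <- hyena_operator(u, blk1, cfg)
  P3 <- genolm:::addb(u %*% blk1$W_in, blk1$b_in)
  S <- genolm:::shortconv_fwd(P3, blk1$K, 20L, 1L)$y
  expect_equal(y, S[, 1:d] * S[, 2 * d + 1:d], tolerance = 1e-10)
})

test_that("compiled forward/backward agree with the pure-R reference and finite differences", {
  cfg <- tiny_config(L_in = 24L, d_model = 8L, seed = 21L)
  m <- init_hyena(cfg)
  set.seed(22)
  tok <- matrix(sample(0:6, 3L * 24L, replace = TRUE), 3, 24)
  rR <- genolm:::lm_loss_r(m, tok, with_grad = TRUE)
  rC <- genolm:::lm_loss(m, tok, with_grad = TRUE)
  expect_equal(rC$loss, rR$loss, tolerance = 1e-12)
  gR <- unlist(rR$grads, use.names = FALSE)
  gC <- unlist(rC$grads, use.names = FALSE)
  expect_equal(gC, gR, tolerance = 1e-10)
  # finite-difference check on a random subset of coordinates
  theta <- unlist(m$params, use.names = FALSE)
  idx <- sort(sample(length(theta), 25))
  eps <- 1e-6
  for (i in idx) {
    mp <- m; tp <- theta; tp[i] <- tp[i] + eps
    mp$params <- utils::relist(tp, m$params)
    mm <- m; tm <- theta; tm[i] <- tm[i] - eps
    mm$params <- utils::relist(tm, m$params)
    num <- (genolm:::lm_loss(mp, tok)$loss - genolm:::lm_loss(mm, tok)$loss) / (2 * eps)
    expect_lt(abs(num - gC[i]), 1e-4 * max(1, abs(num)))
  }
})
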