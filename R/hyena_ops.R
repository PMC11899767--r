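# Low-level numerical building blocks for the Hyena operator stack.
#
# Activations live in "matrix form": a [L*B x d] matrix whose rows are
# (position t, window b) pairs with t varying fastest, so position-wise ops
# are plain matrix products and the per-window time axis can be recovered by
# a free dim<- reinterpretation (c(L, B*d)) for FFT work.

addb <- function(M, b) M + rep(b, each = nrow(M))

#' Deterministic positional features
#'
#' Row `t` (0-based) holds the normalized index `t/scale` followed by
#' sine/cosine pairs at geometrically spaced periods between 2 and
#' `2*scale` bases. The implicit-filter network consumes these features, so
#' filters are a smooth function of position with a parameter count
#' independent of sequence length.
#'
#' @param L Number of positions (>= 1).
#' @param pos_feat_dim Odd feature count `1 + 2K` (index + K sin/cos pairs).
#' @param scale Normalization length; defaults to `L`. Passing the model's
#'   maximum context here makes row `t` depend only on the absolute index
#'   `t`, so filters extend consistently across window lengths.
#' @return Numeric matrix `[L x pos_feat_dim]`.
#' @export
positional_features <- function(L, pos_feat_dim = 17L, scale = L) {
  stopifnot(L >= 1, pos_feat_dim >= 3, pos_feat_dim %% 2 == 1)
  t0 <- seq_len(L) - 1
  K <- (pos_feat_dim - 1L) %/% 2L
  periods <- 2 * (max(scale, 2) / 1)^(seq(0, 1, length.out = K))  # 2 .. 2*scale
  ang <- outer(t0, 2 * pi / periods)
  cbind(t0 / scale, sin(ang), cos(ang), deparse.level = 0)
}

# parameters of one implicit filter: a two-layer MLP with sine activation
# mapping positional features to d_model filter values per position, plus an
# optional per-channel exponential decay envelope exp(-alpha * t).
init_filter_params <- function(d_model, pos_feat_dim, hidden, L_max, use_decay) {
  # decay lengths spread geometrically so some channels stay long-range
  decay_len <- L_max * 10^(seq(log10(0.05), log10(1.5), length.out = d_model))
  fp <- list(
    Wf1 = matrix(stats::rnorm(pos_feat_dim * hidden, sd = 1), pos_feat_dim, hidden),
    bf1 = stats::runif(hidden, -pi, pi),
    Wf2 = matrix(stats::rnorm(hidden * d_model, sd = 0.02), hidden, d_model),
    bf2 = stats::rnorm(d_model, sd = 0.02)
  )
  if (use_decay) fp$log_alpha <- log(1 / decay_len)
  fp
}

#' Generate an implicit long-convolution filter
#'
#' Evaluates the filter MLP at positions `0..L-1`: `h[t, ] =
#' MLP(features(t))`, optionally modulated by a per-channel exponential
#' decay `exp(-alpha_c t)` with `alpha_c >= 0`. The number of parameters is
#' fixed by the MLP widths and does not grow with `L`.
#'
#' @param filter_params Filter parameter list from a model block (fields
#'   `Wf1`, `bf1`, `Wf2`, `bf2`, optional `log_alpha`).
#' @param L Filter length to materialize.
#' @param scale Positional normalization length (the model's `L_in`).
#' @param use_decay Apply the decay envelope (default: whether the
#'   parameters carry one).
#' @return Numeric matrix `[L x d_model]`.
#' @export
implicit_filter <- function(filter_params, L, scale,
                            use_decay = !is.null(filter_params$log_alpha)) {
  implicit_filter_fwd(filter_params, L, scale, use_decay)$h
}

implicit_filter_fwd <- function(fp, L, scale, use_decay = !is.null(fp$log_alpha)) {
  Z <- positional_features(L, nrow(fp$Wf1), scale = scale)
  H1 <- addb(Z %*% fp$Wf1, fp$bf1)
  A1 <- sin(H1)
  h_raw <- addb(A1 %*% fp$Wf2, fp$bf2)
  if (use_decay && !is.null(fp$log_alpha)) {
    alpha <- exp(fp$log_alpha)
    D <- exp(outer(seq_len(L) - 1, alpha, function(t, a) -t * a))
    h <- h_raw * D
  } else {
    D <- NULL
    h <- h_raw
  }
  list(h = h, Z = Z, H1 = H1, A1 = A1, h_raw = h_raw, D = D)
}

implicit_filter_bwd <- function(fp, cache, dh) {
  if (!is.null(cache$D)) {
    dh_raw <- dh * cache$D
    t0 <- seq_len(nrow(dh)) - 1
    # d/dalpha of exp(-alpha t) = -t exp(-alpha t)
    dalpha <- colSums(dh * cache$h_raw * cache$D * (-t0))
    dlog_alpha <- dalpha * exp(fp$log_alpha)
  } else {
    dh_raw <- dh
    dlog_alpha <- NULL
  }
  dA1 <- dh_raw %*% t(fp$Wf2)
  dH1 <- dA1 * cos(cache$H1)
  g <- list(
    Wf1 = crossprod(cache$Z, dH1),
    bf1 = colSums(dH1),
    Wf2 = crossprod(cache$A1, dh_raw),
    bf2 = colSums(dh_raw)
  )
  if (!is.null(dlog_alpha)) g$log_alpha <- dlog_alpha
  g
}

#' Causal convolution of channel signals via the FFT
#'
#' Per channel `c`, computes `y[t, c] = sum_{s=0}^{t} h[t-s, c] u[s, c]`,
#' i.e. multiplication by the lower-triangular Toeplitz matrix of the
#' filter, realized as a zero-padded circular convolution of length
#' `>= 2L - 1` so no wrap-around occurs.
#'
#' @param u Input matrix `[L x d]`.
#' @param h Filter matrix `[L x d]`.
#' @return Matrix `[L x d]` of causally filtered signals.
#' @export
fft_causal_conv <- function(u, h) {
  u <- as.matrix(u); h <- as.matrix(h)
  if (!all(dim(u) == dim(h))) stop("fft_causal_conv(): u and h must share a shape")
  L <- nrow(u)
  nfft <- stats::nextn(max(2L * L - 1L, 1L), 2)
  P <- matrix(0, nfft, ncol(u)); P[seq_len(L), ] <- u
  Q <- matrix(0, nfft, ncol(h)); Q[seq_len(L), ] <- h
  Y <- stats::mvfft(stats::mvfft(P) * stats::mvfft(Q), inverse = TRUE)
  Re(Y[seq_len(L), , drop = FALSE]) / nfft
}

# ---- batched FFT machinery -------------------------------------------------

# matrix-form [LB x d] -> complex spectrum [nfft x B*d] (column c-major over
# channels: columns 1..B are channel 1, etc.)
fft_pad <- function(M, L, B, d, nfft) {
  dim(M) <- c(L, B * d)
  P <- matrix(0, nfft, B * d)
  P[seq_len(L), ] <- M
  stats::mvfft(P)
}

ifft_take <- function(S, L, B, d, nfft) {
  Y <- Re(stats::mvfft(S, inverse = TRUE))[seq_len(L), , drop = FALSE] / nfft
  dim(Y) <- c(L * B, d)
  Y
}

# expand per-channel filter spectrum [nfft x d] across the batch columns
expand_hf <- function(Hf, B, d) Hf[, rep(seq_len(d), each = B), drop = FALSE]

# sum a [L x B*d] slab over the batch axis -> [L x d]
batch_sum <- function(Y, L, B, d) {
  dim(Y) <- c(L, B, d)
  colSums(aperm(Y, c(2, 1, 3)))
}

# causal conv forward for matrix-form activations; returns output and the
# spectra reused by the backward pass
fft_conv_batch <- function(a, Hf, L, B, d, nfft) {
  Af <- fft_pad(a, L, B, d, nfft)
  y <- ifft_take(Af * expand_hf(Hf, B, d), L, B, d, nfft)
  list(y = y, Af = Af)
}

# gradients of the causal conv: da is an anti-causal correlation with h,
# dh a cross-correlation of dy with the input, summed over the batch
fft_conv_batch_bwd <- function(dy, Af, Hf, L, B, d, nfft) {
  Df <- fft_pad(dy, L, B, d, nfft)
  da <- ifft_take(Df * Conj(expand_hf(Hf, B, d)), L, B, d, nfft)
  slab <- Re(stats::mvfft(Df * Conj(Af), inverse = TRUE))[seq_len(L), , drop = FALSE] / nfft
  dh <- batch_sum(slab, L, B, d)
  list(da = da, dh = dh)
}

# ---- layer norm ------------------------------------------------------------

layernorm_fwd <- function(M, g, b, eps = 1e-5) {
  mu <- rowMeans(M)
  xc <- M - mu
  istd <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * istd
  list(y = addb(xhat * rep(g, each = nrow(M)), b), xhat = xhat, istd = istd)
}

layernorm_bwd <- function(dy, cache, g) {
  n <- nrow(dy)
  dg <- colSums(dy * cache$xhat)
  db <- colSums(dy)
  dxh <- dy * rep(g, each = n)
  dx <- cache$istd * (dxh - rowMeans(dxh) - cache$xhat * rowMeans(dxh * cache$xhat))
  list(dx = dx, dg = dg, db = db)
}

# ---- causal depthwise short convolution ------------------------------------

# shift matrix-form activations down j steps within each window block
shift_down <- function(M, j, L, B) {
  if (j == 0L) return(M)
  n <- nrow(M)
  out <- matrix(0, n, ncol(M))
  ridx <- seq_len(n)
  valid <- ((ridx - 1L) %% L) >= j
  out[valid, ] <- M[ridx[valid] - j, , drop = FALSE]
  out
}

shift_up <- function(M, j, L, B) {
  if (j == 0L) return(M)
  n <- nrow(M)
  out <- matrix(0, n, ncol(M))
  ridx <- seq_len(n)
  valid <- ((ridx - 1L) %% L) < (L - j)
  out[valid, ] <- M[ridx[valid] + j, , drop = FALSE]
  out
}

# kernel K: [w x C]; y[t] = sum_j K[j+1, ] * x[t - j]
shortconv_fwd <- function(M, K, L, B) {
  w <- nrow(K)
  Y <- matrix(0, nrow(M), ncol(M))
  shifts <- vector("list", w)
  for (j in seq_len(w)) {
    shifts[[j]] <- shift_down(M, j - 1L, L, B)
    Y <- Y + shifts[[j]] * rep(K[j, ], each = nrow(M))
  }
  list(y = Y, shifts = shifts)
}

shortconv_bwd <- function(dY, K, shifts, L, B) {
  w <- nrow(K)
  dM <- matrix(0, nrow(dY), ncol(dY))
  dK <- matrix(0, w, ncol(K))
  for (j in seq_len(w)) {
    dK[j, ] <- colSums(shifts[[j]] * dY)
    dM <- dM + shift_up(dY * rep(K[j, ], each = nrow(dY)), j - 1L, L, B)
  }
  list(dM = dM, dK = dK)
}

# ---- GELU ------------------------------------------------------------------

gelu_fwd <- function(x) {
  c0 <- sqrt(2 / pi)
  inner <- c0 * (x + 0.044715 * x^3)
  th <- tanh(inner)
  list(y = 0.5 * x * (1 + th), th = th, x = x)
}

gelu_bwd <- function(dy, cache) {
  c0 <- sqrt(2 / pi)
  x <- cache$x; th <- cache$th
  dinner <- c0 * (1 + 3 * 0.044715 * x^2)
  dy * (0.5 * (1 + th) + 0.5 * x * (1 - th^2) * dinner)
}
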