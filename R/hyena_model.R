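#' Configuration of the Hyena DNA language model
#'
#' Defaults are the package's reference settings for fine-tuning compact
#' genomic Hyena models: batch size 16, learning rate 6e-4, 6 epochs, 2
#' layers, model width 256, with the context window `L_in` usually chosen
#' from the sweep set 512..32768; anything up to 32768 tokens is accepted.
#'
#' @param L_in Maximum context window length in nucleotides (>= 2,
#'   <= 32768).
#' @param d_model Hidden width.
#' @param n_layer Number of Hyena blocks.
#' @param vocab_size Token vocabulary size (7: A/T/C/G + PAD/SEP/UNK).
#' @param order Number of multiplicative gates (2: `x1`, `x2`, plus the
#'   value path `v`).
#' @param short_conv_width Causal depthwise kernel length applied to each
#'   projection before gating.
#' @param filter_mlp_hidden Hidden width of the implicit-filter MLP.
#' @param pos_feat_dim Positional feature count fed to the filter MLP
#'   (odd: index + sin/cos pairs).
#' @param use_decay Modulate implicit filters by a learnable per-channel
#'   exponential decay envelope.
#' @param learning_rate,batch_size,max_epochs Optimization settings.
#' @param seed Seed governing initialization and batch shuffling.
#' @return An object of class `hyena_config`.
#' @examples
#' cfg <- hyena_config(L_in = 256, d_model = 64)
#' @export
hyena_config <- function(L_in = 512L, d_model = 256L, n_layer = 2L,
                         vocab_size = 7L, order = 2L,
                         short_conv_width = 3L, filter_mlp_hidden = 32L,
                         pos_feat_dim = 17L, use_decay = TRUE,
                         learning_rate = 6e-4, batch_size = 16L,
                         max_epochs = 6L, seed = 1000L) {
  stopifnot(
    L_in >= 2, L_in <= 32768, d_model >= 1, n_layer >= 1,
    vocab_size == 7L, order == 2L, short_conv_width >= 1,
    pos_feat_dim %% 2 == 1, learning_rate > 0, batch_size >= 1,
    max_epochs >= 1
  )
  structure(
    list(
      L_in = as.integer(L_in), d_model = as.integer(d_model),
      n_layer = as.integer(n_layer), vocab_size = as.integer(vocab_size),
      order = as.integer(order),
      short_conv_width = as.integer(short_conv_width),
      filter_mlp_hidden = as.integer(filter_mlp_hidden),
      pos_feat_dim = as.integer(pos_feat_dim), use_decay = use_decay,
      learning_rate = learning_rate, batch_size = as.integer(batch_size),
      max_epochs = as.integer(max_epochs), seed = as.integer(seed)
    ),
    class = "hyena_config"
  )
}

#' @export
print.hyena_config <- function(x, ...) {
  cat(sprintf(
    "<hyena_config> L_in=%d d_model=%d n_layer=%d lr=%g batch=%d epochs=%d seed=%d\n",
    x$L_in, x$d_model, x$n_layer, x$learning_rate, x$batch_size,
    x$max_epochs, x$seed
  ))
  invisible(x)
}

# run code under a temporary RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Initialize a Hyena language model
#'
#' Builds the decoder-only stack: token embedding, `n_layer` blocks (each
#' pre-layer-norm, three projections with causal depthwise short
#' convolutions, an implicit long convolution with multiplicative gating,
#' an output projection and a position-wise feed-forward sublayer, both
#' residual) and a vocabulary head. Weights are drawn from the config's
#' seed, so initialization is reproducible.
#'
#' @param config A [hyena_config()].
#' @return An object of class `hyena_model` (untrained).
#' @export
init_hyena <- function(config) {
  stopifnot(inherits(config, "hyena_config"))
  d <- config$d_model
  with_seed(config$seed, {
    blocks <- lapply(seq_len(config$n_layer), function(i) {
      list(
        ln1_g = rep(1, d), ln1_b = rep(0, d),
        W_in = matrix(stats::rnorm(d * 3 * d, sd = 0.02), d, 3 * d),
        b_in = rep(0, 3 * d),
        # short conv initialized to pass-through (identity at lag 0)
        K = rbind(
          matrix(1, 1, 3 * d),
          matrix(stats::rnorm((config$short_conv_width - 1) * 3 * d, sd = 0.02),
                 config$short_conv_width - 1, 3 * d)
        ),
        filter = init_filter_params(
          d, config$pos_feat_dim, config$filter_mlp_hidden,
          config$L_in, config$use_decay
        ),
        W_out = matrix(stats::rnorm(d * d, sd = 0.02), d, d),
        b_out = rep(0, d),
        ln2_g = rep(1, d), ln2_b = rep(0, d),
        Wff1 = matrix(stats::rnorm(d * 2 * d, sd = 0.02), d, 2 * d),
        bff1 = rep(0, 2 * d),
        Wff2 = matrix(stats::rnorm(2 * d * d, sd = 0.02), 2 * d, d),
        bff2 = rep(0, d)
      )
    })
    structure(
      list(
        config = config,
        params = list(
          tok_emb = matrix(stats::rnorm(config$vocab_size * d, sd = 0.02),
                           config$vocab_size, d),
          blocks = blocks,
          ln_f_g = rep(1, d), ln_f_b = rep(0, d),
          W_head = matrix(stats::rnorm(d * config$vocab_size, sd = 0.02),
                          d, config$vocab_size),
          b_head = rep(0, config$vocab_size)
        ),
        training_log = data.frame(
          epoch = integer(0), split = character(0), loss = numeric(0)
        )
      ),
      class = "hyena_model"
    )
  })
}

#' @export
print.hyena_model <- function(x, ...) {
  cat(sprintf(
    "<hyena_model> L_in=%d d_model=%d n_layer=%d params=%d trained_epochs=%d\n",
    x$config$L_in, x$config$d_model, x$config$n_layer, count_params(x),
    if (nrow(x$training_log)) max(x$training_log$epoch) else 0L
  ))
  invisible(x)
}

#' Count trainable parameters
#'
#' Implicit filters make the count independent of the context window
#' `L_in`: filters are generated by a fixed-size MLP rather than stored
#' per position.
#'
#' @param model A [hyena_model()][init_hyena].
#' @return Integer scalar.
#' @export
count_params <- function(model) {
  length(unlist(model$params, use.names = FALSE))
}

#' Apply one Hyena operator
#'
#' The operator forms three projections of the input (`x1`, `x2`, `v`),
#' each passed through a causal depthwise short convolution, then gates a
#' causal long convolution: `y = x2 * conv_h(x1 * v)` where the filter `h`
#' comes from the block's implicit-filter MLP. Exposed for inspection and
#' testing; [forward_lm()] runs full blocks with normalization, output
#' projection and feed-forward sublayers.
#'
#' @param u Input matrix `[L x d_model]`.
#' @param block One element of `model$params$blocks`.
#' @param config The model's [hyena_config()].
#' @return Matrix `[L x d_model]`.
#' @export
hyena_operator <- function(u, block, config) {
  u <- as.matrix(u)
  L <- nrow(u)
  if (L > config$L_in) stop("hyena_operator(): input longer than L_in")
  d <- config$d_model
  stopifnot(ncol(u) == d)
  P3 <- addb(u %*% block$W_in, block$b_in)
  S <- shortconv_fwd(P3, block$K, L, 1L)$y
  x1 <- S[, seq_len(d), drop = FALSE]
  x2 <- S[, d + seq_len(d), drop = FALSE]
  v <- S[, 2 * d + seq_len(d), drop = FALSE]
  h <- implicit_filter(block$filter, L, scale = config$L_in,
                       use_decay = config$use_decay)
  x2 * fft_causal_conv(x1 * v, h)
}

# full batched forward pass; tok is an integer matrix [B x L] of 0-based
# token ids. Returns logits and final hidden states in matrix form
# ([L*B x .], rows ordered position-fastest), plus caches when requested.
hyena_forward <- function(model, tok, keep_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  d <- cfg$d_model
  B <- nrow(tok); L <- ncol(tok)
  if (L > cfg$L_in) stop("hyena_forward(): window longer than L_in")
  nfft <- stats::nextn(max(2L * L - 1L, 1L), 2)
  ids <- as.vector(t(tok)) + 1L
  X <- p$tok_emb[ids, , drop = FALSE]
  caches <- if (keep_cache) vector("list", cfg$n_layer) else NULL
  for (li in seq_len(cfg$n_layer)) {
    blk <- p$blocks[[li]]
    ln1 <- layernorm_fwd(X, blk$ln1_g, blk$ln1_b)
    P3 <- addb(ln1$y %*% blk$W_in, blk$b_in)
    sc <- shortconv_fwd(P3, blk$K, L, B)
    S <- sc$y
    x1 <- S[, seq_len(d), drop = FALSE]
    x2 <- S[, d + seq_len(d), drop = FALSE]
    v <- S[, 2 * d + seq_len(d), drop = FALSE]
    a <- x1 * v
    filt <- implicit_filter_fwd(blk$filter, L, scale = cfg$L_in,
                                use_decay = cfg$use_decay)
    Hf <- stats::mvfft(rbind(filt$h, matrix(0, nfft - L, d)))
    cv <- fft_conv_batch(a, Hf, L, B, d, nfft)
    g <- x2 * cv$y
    out <- addb(g %*% blk$W_out, blk$b_out)
    U2 <- X + out
    ln2 <- layernorm_fwd(U2, blk$ln2_g, blk$ln2_b)
    ff_pre <- addb(ln2$y %*% blk$Wff1, blk$bff1)
    ge <- gelu_fwd(ff_pre)
    F2 <- addb(ge$y %*% blk$Wff2, blk$bff2)
    X_new <- U2 + F2
    if (keep_cache) {
      caches[[li]] <- list(
        X_in = X, ln1 = ln1, sc_shifts = sc$shifts, x1 = x1, x2 = x2, v = v,
        a = a, filt = filt, Hf = Hf, Af = cv$Af, yconv = cv$y, g = g,
        U2 = U2, ln2 = ln2, ge = ge
      )
    }
    X <- X_new
  }
  lnf <- layernorm_fwd(X, p$ln_f_g, p$ln_f_b)
  logits <- addb(lnf$y %*% p$W_head, p$b_head)
  list(
    logits = logits, hidden = lnf$y, L = L, B = B, nfft = nfft, ids = ids,
    caches = caches, lnf = lnf, X_last = X
  )
}

# backward pass matching hyena_forward(keep_cache = TRUE); dlogits is in
# matrix form. Returns a gradient tree shaped like model$params.
hyena_backward <- function(model, fwd, dlogits) {
  cfg <- model$config
  p <- model$params
  d <- cfg$d_model
  L <- fwd$L; B <- fwd$B; nfft <- fwd$nfft
  gW_head <- crossprod(fwd$lnf$y, dlogits)
  gb_head <- colSums(dlogits)
  dH <- dlogits %*% t(p$W_head)
  lnf_b <- layernorm_bwd(dH, fwd$lnf, p$ln_f_g)
  dX <- lnf_b$dx
  g_lnf_g <- lnf_b$dg
  g_lnf_b <- lnf_b$db
  gblocks <- vector("list", cfg$n_layer)
  for (li in rev(seq_len(cfg$n_layer))) {
    blk <- p$blocks[[li]]
    cc <- fwd$caches[[li]]
    # feed-forward sublayer
    dF2 <- dX
    gWff2 <- crossprod(cc$ge$y, dF2)
    gbff2 <- colSums(dF2)
    dge <- dF2 %*% t(blk$Wff2)
    dff_pre <- gelu_bwd(dge, cc$ge)
    gWff1 <- crossprod(cc$ln2$y, dff_pre)
    gbff1 <- colSums(dff_pre)
    dZ2 <- dff_pre %*% t(blk$Wff1)
    ln2_b <- layernorm_bwd(dZ2, cc$ln2, blk$ln2_g)
    dU2 <- dX + ln2_b$dx
    # output projection and gating
    dout <- dU2
    gW_out <- crossprod(cc$g, dout)
    gb_out <- colSums(dout)
    dg <- dout %*% t(blk$W_out)
    dx2 <- dg * cc$yconv
    dyconv <- dg * cc$x2
    cb <- fft_conv_batch_bwd(dyconv, cc$Af, cc$Hf, L, B, d, nfft)
    da <- cb$da
    gfilter <- implicit_filter_bwd(blk$filter, cc$filt, cb$dh)
    dx1 <- da * cc$v
    dv <- da * cc$x1
    dS <- cbind(dx1, dx2, dv)
    scb <- shortconv_bwd(dS, blk$K, cc$sc_shifts, L, B)
    dP3 <- scb$dM
    gW_in <- crossprod(cc$ln1$y, dP3)
    gb_in <- colSums(dP3)
    dZ1 <- dP3 %*% t(blk$W_in)
    ln1_b <- layernorm_bwd(dZ1, cc$ln1, blk$ln1_g)
    gblocks[[li]] <- list(
      ln1_g = ln1_b$dg, ln1_b = ln1_b$db,
      W_in = gW_in, b_in = gb_in, K = scb$dK, filter = gfilter,
      W_out = gW_out, b_out = gb_out,
      ln2_g = ln2_b$dg, ln2_b = ln2_b$db,
      Wff1 = gWff1, bff1 = gbff1, Wff2 = gWff2, bff2 = gbff2
    )
    dX <- dU2 + ln1_b$dx
  }
  gemb <- matrix(0, cfg$vocab_size, d)
  # scatter-add token-embedding gradients
  agg <- rowsum(dX, group = fwd$ids)
  gemb[as.integer(rownames(agg)), ] <- agg
  list(
    tok_emb = gemb, blocks = gblocks,
    ln_f_g = g_lnf_g, ln_f_b = g_lnf_b,
    W_head = gW_head, b_head = gb_head
  )
}

#' Run the language model over one window
#'
#' Embeds the window's tokens, applies the block stack and projects to
#' vocabulary logits. The computation is strictly causal: logits at
#' position `t` depend only on tokens at positions `<= t`.
#'
#' @param model A [hyena_model()][init_hyena].
#' @param window A [genome_window()] (tokenized with the model's
#'   vocabulary; at most `L_in` tokens).
#' @return Numeric matrix `[L x vocab_size]` of logits.
#' @export
forward_lm <- function(model, window) {
  stopifnot(inherits(model, "hyena_model"), inherits(window, "genome_window"))
  tok <- matrix(as.integer(window$token_ids), nrow = 1)
  .cpp_forward(model$params, unclass(model$config), tok)$logits
}

#' Embed one window as a fixed-length vector
#'
#' Mean of the final-layer hidden states over unpadded positions
#' (pad-mask-weighted pooling). Padding tokens therefore never contribute:
#' extending a window with PAD leaves its embedding unchanged.
#'
#' @param model A trained [hyena_model()][init_hyena].
#' @param window A [genome_window()] with at least one real base.
#' @return Numeric vector of length `d_model`.
#' @export
embed_window <- function(model, window) {
  if (!any(window$pad_mask)) {
    stop("embed_window(): all-PAD window has no real bases to pool")
  }
  embed_windows(model, list(window))[1, ]
}

#' Embed many windows in batches
#'
#' @param model A trained [hyena_model()][init_hyena].
#' @param windows List of [genome_window()] of equal length.
#' @param batch_size Windows per forward pass.
#' @return Numeric matrix `[n_windows x d_model]`.
#' @export
embed_windows <- function(model, windows, batch_size = 32L) {
  stopifnot(length(windows) > 0L)
  L <- length(windows[[1]]$token_ids)
  n <- length(windows)
  d <- model$config$d_model
  out <- matrix(0, n, d)
  for (b0 in seq(1L, n, by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1L, n)
    tok <- t(vapply(windows[idx], `[[`, integer(L), "token_ids"))
    if (length(idx) == 1L) tok <- matrix(windows[[idx]]$token_ids, nrow = 1)
    fwd <- .cpp_forward(model$params, unclass(model$config), tok)
    H <- fwd$hidden  # [L*Bc x d], position-fastest
    for (k in seq_along(idx)) {
      m <- windows[[idx[k]]]$pad_mask
      if (!any(m)) stop("embed_windows(): all-PAD window at index ", idx[k])
      rows <- (k - 1L) * L + which(m)
      out[idx[k], ] <- colMeans(H[rows, , drop = FALSE])
    }
  }
  out
}

#' Save a model checkpoint
#'
#' Single-file archive holding the configuration, all parameter arrays,
#' the training log and the vocabulary hash; [load_checkpoint()] restores
#' it bit-exactly.
#'
#' @param model A [hyena_model()][init_hyena].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(
    format = "genolm-checkpoint-v1",
    vocab_hash = vocab_hash(token_vocab()),
    config = unclass(model$config),
    params = model$params,
    training_log = model$training_log
  )
  saveRDS(obj, path, version = 3)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path File written by [save_checkpoint()].
#' @return A [hyena_model()][init_hyena].
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "genolm-checkpoint-v1")) {
    stop("load_checkpoint(): not a genolm checkpoint: ", path)
  }
  if (!identical(obj$vocab_hash, vocab_hash(token_vocab()))) {
    stop("load_checkpoint(): vocabulary hash mismatch")
  }
  structure(
    list(
      config = do.call(hyena_config, obj$config),
      params = obj$params,
      training_log = obj$training_log
    ),
    class = "hyena_model"
  )
}
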