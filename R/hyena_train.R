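# Training loop for the Hyena language model: next-nucleotide
# cross-entropy, Adam with global-norm gradient clipping, seeded epoch
# shuffling for bit-reproducible single-device runs.

# target ids in matrix form (position-fastest vector): target at (t, b) is
# token (t+1, b); NA when there is no next token or the target is a
# special token (PAD/SEP/UNK) — the objective covers nucleotides only.
lm_targets <- function(tok) {
  B <- nrow(tok); L <- ncol(tok)
  tt <- t(tok)  # [L x B]
  tgt <- rbind(tt[-1, , drop = FALSE], matrix(NA_integer_, 1, B))
  tv <- as.vector(tgt)
  tv[!(tv %in% 0:3)] <- NA_integer_
  tv
}

# mean cross-entropy (nats/token) and, optionally, parameter gradients;
# production path runs the compiled kernels
lm_loss <- function(model, tok, with_grad = FALSE) {
  res <- .cpp_loss_grad(model$params, unclass(model$config),
                        matrix(as.integer(tok), nrow(tok), ncol(tok)),
                        with_grad)
  res
}

# pure-R reference implementation of the same loss/gradient computation;
# kept as the oracle the compiled path is tested against
lm_loss_r <- function(model, tok, with_grad = FALSE) {
  fwd <- hyena_forward(model, tok, keep_cache = with_grad)
  tv <- lm_targets(tok)
  valid <- which(!is.na(tv))
  if (length(valid) == 0L) stop("lm_loss(): no scorable positions in batch")
  logits <- fwd$logits
  m <- logits[cbind(seq_len(nrow(logits)), max.col(logits, ties.method = "first"))]
  lse <- m + log(rowSums(exp(logits - m)))
  picked <- logits[cbind(valid, tv[valid] + 1L)]
  loss <- mean(lse[valid] - picked)
  out <- list(loss = loss, n_tok = length(valid))
  if (with_grad) {
    probs <- exp(logits - lse)
    dlogits <- matrix(0, nrow(logits), ncol(logits))
    dlogits[valid, ] <- probs[valid, , drop = FALSE] / length(valid)
    dlogits[cbind(valid, tv[valid] + 1L)] <-
      dlogits[cbind(valid, tv[valid] + 1L)] - 1 / length(valid)
    out$grads <- hyena_backward(model, fwd, dlogits)
  }
  out
}

adam_init <- function(theta) {
  list(m = numeric(length(theta)), v = numeric(length(theta)), t = 0L)
}

adam_step <- function(theta, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip = 1.0) {
  gn <- sqrt(sum(grad^2))
  if (is.finite(gn) && gn > clip) grad <- grad * (clip / gn)
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  theta <- theta - lr * mhat / (sqrt(vhat) + eps)
  list(theta = theta, state = state)
}

windows_to_tok <- function(windows) {
  L <- length(windows[[1]]$token_ids)
  tok <- t(vapply(windows, `[[`, integer(L), "token_ids"))
  if (length(windows) == 1L) tok <- matrix(windows[[1]]$token_ids, nrow = 1)
  tok
}

#' Train the language model with a next-nucleotide objective
#'
#' Minimizes the average cross-entropy of predicting each window position's
#' next nucleotide from its prefix. Positions whose target is a special
#' token (PAD/SEP/UNK) are excluded from the loss. Optimization is Adam at
#' the configured learning rate with gradient clipping at global norm 1;
#' batches are reshuffled every epoch from the config seed, so a fixed seed
#' gives a bit-reproducible run on one device.
#'
#' @param corpus Non-empty list of [genome_window()] of equal length.
#' @param config A [hyena_config()].
#' @param model Optional existing model to continue training; by default a
#'   fresh model is initialized from `config`.
#' @param eval_corpus Optional held-out windows; their cross-entropy is
#'   logged once per epoch under split `"eval"`.
#' @param verbose Print per-epoch losses.
#' @return A trained [hyena_model()][init_hyena] whose `training_log` holds
#'   per-epoch mean loss (nats/token).
#' @export
train_lm <- function(corpus, config, model = NULL, eval_corpus = NULL,
                     verbose = FALSE) {
  if (length(corpus) == 0L) stop("train_lm(): empty corpus")
  stopifnot(inherits(config, "hyena_config"))
  if (is.null(model)) model <- init_hyena(config)
  tok_all <- windows_to_tok(corpus)
  skeleton <- model$params
  theta <- unlist(skeleton, use.names = FALSE)
  opt <- adam_init(theta)
  n <- nrow(tok_all)
  bs <- config$batch_size
  with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      tot_loss <- 0
      tot_tok <- 0
      for (b0 in seq(1L, n, by = bs)) {
        idx <- ord[b0:min(b0 + bs - 1L, n)]
        res <- lm_loss(model, tok_all[idx, , drop = FALSE], with_grad = TRUE)
        grad <- unlist(res$grads, use.names = FALSE)
        upd <- adam_step(theta, grad, opt, lr = config$learning_rate)
        theta <- upd$theta
        opt <- upd$state
        model$params <- utils::relist(theta, skeleton)
        tot_loss <- tot_loss + res$loss * res$n_tok
        tot_tok <- tot_tok + res$n_tok
      }
      epoch_loss <- tot_loss / tot_tok
      model$training_log <- rbind(
        model$training_log,
        data.frame(epoch = epoch, split = "train", loss = epoch_loss)
      )
      if (!is.null(eval_corpus)) {
        ev <- evaluate_lm(model, eval_corpus)
        model$training_log <- rbind(
          model$training_log,
          data.frame(epoch = epoch, split = "eval", loss = ev)
        )
        if (verbose) {
          message(sprintf("epoch %d: train %.4f eval %.4f", epoch, epoch_loss, ev))
        }
      } else if (verbose) {
        message(sprintf("epoch %d: train %.4f", epoch, epoch_loss))
      }
    }
  })
  model
}

#' Held-out cross-entropy of the language model
#'
#' @param model A [hyena_model()][init_hyena].
#' @param windows List of [genome_window()].
#' @param batch_size Windows per forward pass.
#' @return Mean next-nucleotide cross-entropy in nats/token.
#' @export
evaluate_lm <- function(model, windows, batch_size = 32L) {
  tok_all <- windows_to_tok(windows)
  tot <- 0; ntk <- 0
  for (b0 in seq(1L, nrow(tok_all), by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1L, nrow(tok_all))
    res <- lm_loss(model, tok_all[idx, , drop = FALSE])
    tot <- tot + res$loss * res$n_tok
    ntk <- ntk + res$n_tok
  }
  tot / ntk
}
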