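#' Single-nucleotide token vocabulary
#'
#' The model reads DNA one nucleotide per token. The vocabulary holds the
#' four bases plus three special tokens: `PAD` (window padding), `SEP`
#' (reserved separator, never emitted inside windows) and `UNK` (any
#' non-ACGT letter, e.g. `N` or IUPAC ambiguity codes). Ids are fixed so
#' that serialized models and window files are stable across runs:
#' A=0, T=1, C=2, G=3, PAD=4, SEP=5, UNK=6.
#'
#' @return An object of class `token_vocab`: a list with `base_tokens`
#'   (named integer vector for A/T/C/G), `special_tokens` (named integer
#'   vector for PAD/SEP/UNK) and `size` (7).
#' @examples
#' v <- token_vocab()
#' v$base_tokens[["A"]]
#' @export
token_vocab <- function() {
  structure(
    list(
      base_tokens = c(A = 0L, T = 1L, C = 2L, G = 3L),
      special_tokens = c(PAD = 4L, SEP = 5L, UNK = 6L),
      size = 7L
    ),
    class = "token_vocab"
  )
}

#' @export
print.token_vocab <- function(x, ...) {
  cat("<token_vocab> size", x$size, "\n")
  cat("  bases:  ", paste(names(x$base_tokens), x$base_tokens, sep = "=", collapse = " "), "\n")
  cat("  special:", paste(names(x$special_tokens), x$special_tokens, sep = "=", collapse = " "), "\n")
  invisible(x)
}

# lookup table mapping raw characters to ids; built once per call site
vocab_lookup <- function(vocab) {
  lut <- rep(vocab$special_tokens[["UNK"]], 256L)
  for (b in names(vocab$base_tokens)) {
    lut[utf8ToInt(b) + 1L] <- vocab$base_tokens[[b]]
    lut[utf8ToInt(tolower(b)) + 1L] <- vocab$base_tokens[[b]]
  }
  lut
}

#' Tokenize a nucleotide string
#'
#' Length-preserving, position-wise mapping of characters to token ids:
#' A/C/G/T (either case) map to their base ids, every other letter maps to
#' `UNK`. No k-mer merging takes place, so the representation keeps
#' single-nucleotide resolution.
#'
#' @param sequence A character scalar over the DNA alphabet (ambiguity
#'   letters allowed).
#' @param vocab A [token_vocab()].
#' @return Integer vector of token ids, one per input character.
#' @examples
#' tokenize("ACGT")
#' tokenize("ANGT")  # N maps to UNK
#' @export
tokenize <- function(sequence, vocab = token_vocab()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) return(integer(0))
  lut <- vocab_lookup(vocab)
  as.integer(lut[utf8ToInt(sequence) + 1L])
}

#' Render token ids back to a nucleotide string
#'
#' Inverse of [tokenize()] on the base alphabet; `PAD` renders as `-`,
#' `UNK` as `N`, `SEP` as `|`.
#'
#' @param ids Integer vector of token ids.
#' @param vocab A [token_vocab()].
#' @return A character scalar.
#' @examples
#' detokenize(c(0L, 2L, 3L, 1L))
#' @export
detokenize <- function(ids, vocab = token_vocab()) {
  if (length(ids) == 0L) return("")
  ids <- as.integer(ids)
  if (any(is.na(ids)) || any(ids < 0L) || any(ids >= vocab$size)) {
    stop("detokenize(): token id out of range [0, ", vocab$size - 1L, "]")
  }
  chars <- character(vocab$size)
  chars[vocab$base_tokens + 1L] <- names(vocab$base_tokens)
  chars[vocab$special_tokens[["PAD"]] + 1L] <- "-"
  chars[vocab$special_tokens[["SEP"]] + 1L] <- "|"
  chars[vocab$special_tokens[["UNK"]] + 1L] <- "N"
  paste(chars[ids + 1L], collapse = "")
}

# stable short hash of the vocabulary mapping, stored in window containers
# and checkpoints so mismatched artifacts are rejected early
vocab_hash <- function(vocab = token_vocab()) {
  key <- paste(
    paste(names(vocab$base_tokens), vocab$base_tokens, sep = "=", collapse = ","),
    paste(names(vocab$special_tokens), vocab$special_tokens, sep = "=", collapse = ","),
    sep = ";"
  )
  # small deterministic polynomial hash over the key bytes
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
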