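#' @title Model-ready sequence windows
#' @description Construct a tokenized window. Users normally obtain windows
#'   from [segment_all()], [snp_windows()] or [window_stream()] rather than
#'   calling this directly.
#' @param sample_id,chrom_id Identifiers copied from the source sequence.
#' @param start,end 0-based half-open span on the chromosome actually
#'   covered by real bases (`end - start <= L_in`).
#' @param token_ids Integer vector of length `L_in`.
#' @param pad_mask Logical vector of length `L_in`; `TRUE` marks a real base.
#' @param mode `"ALL_SEQUENCE"` or `"SNP_SEQUENCE"`.
#' @param anchor_pos For SNP windows, the 0-based chromosome index of the
#'   variant; `NA` otherwise.
#' @return An object of class `genome_window`.
#' @export
genome_window <- function(sample_id, chrom_id, start, end, token_ids, pad_mask,
                          mode = c("ALL_SEQUENCE", "SNP_SEQUENCE"),
                          anchor_pos = NA_integer_) {
  mode <- match.arg(mode)
  stopifnot(
    length(token_ids) == length(pad_mask),
    end - start <= length(token_ids),
    sum(pad_mask) == end - start
  )
  structure(
    list(
      sample_id = sample_id, chrom_id = chrom_id,
      start = as.integer(start), end = as.integer(end),
      token_ids = as.integer(token_ids), pad_mask = as.logical(pad_mask),
      mode = mode, anchor_pos = as.integer(anchor_pos)
    ),
    class = "genome_window"
  )
}

#' @export
print.genome_window <- function(x, ...) {
  cat(sprintf(
    "<genome_window> %s:%s [%d,%d) L=%d real=%d mode=%s\n",
    x$sample_id, x$chrom_id, x$start, x$end,
    length(x$token_ids), sum(x$pad_mask), x$mode
  ))
  invisible(x)
}

#' Tile a chromosome into consecutive fixed-length windows
#'
#' All-sequence input mode: the chromosome is segmented into non-overlapping
#' fragments `[0, L_in)`, `[L_in, 2 L_in)`, ... so that every nucleotide is
#' covered exactly once. The final short fragment is right-padded with `PAD`
#' tokens; the window count is `ceiling(length / L_in)`.
#'
#' @param genome A [genome_sequence()].
#' @param L_in Window length in nucleotides (>= 2).
#' @param vocab A [token_vocab()].
#' @return List of [genome_window()]; empty for an empty sequence.
#' @examples
#' g <- genome_sequence("s1", "chr1", strrep("ACGT", 3))
#' length(segment_all(g, 8L))  # ceiling(12 / 8) = 2
#' @export
segment_all <- function(genome, L_in, vocab = token_vocab()) {
  stopifnot(inherits(genome, "genome_sequence"), L_in >= 2)
  L_in <- as.integer(L_in)
  n <- genome$length
  if (n == 0L) return(list())
  ids_full <- tokenize(genome$sequence, vocab)
  pad_id <- vocab$special_tokens[["PAD"]]
  n_win <- ceiling(n / L_in)
  lapply(seq_len(n_win), function(k) {
    start <- (k - 1L) * L_in
    end <- min(k * L_in, n)
    ids <- ids_full[(start + 1L):end]
    n_real <- end - start
    if (n_real < L_in) ids <- c(ids, rep(pad_id, L_in - n_real))
    genome_window(
      genome$sample_id, genome$chrom_id, start, end,
      ids, c(rep(TRUE, n_real), rep(FALSE, L_in - n_real)),
      mode = "ALL_SEQUENCE"
    )
  })
}

#' Extract one window centred on each variant site
#'
#' SNP input mode: for a variant at 0-based chromosome index `i` the window
#' spans `[i - L_in/2, i + L_in/2)`, placing the variant base at offset
#' `L_in/2` (with `L_in/2` flanking bases on the left and `L_in/2 - 1` on
#' the right). Spans clipped by a chromosome end are padded on the clipped
#' side so the variant keeps its fixed offset; overlapping windows are kept,
#' one per site.
#'
#' @param genome A [genome_sequence()].
#' @param sites List of [variant_site()] on `genome$chrom_id`.
#' @param L_in Even window length.
#' @param vocab A [token_vocab()].
#' @return List of [genome_window()], one per site, in input order.
#' @export
snp_windows <- function(genome, sites, L_in, vocab = token_vocab()) {
  stopifnot(inherits(genome, "genome_sequence"), L_in >= 2, L_in %% 2 == 0)
  L_in <- as.integer(L_in)
  half <- L_in %/% 2L
  pad_id <- vocab$special_tokens[["PAD"]]
  ids_full <- tokenize(genome$sequence, vocab)
  lapply(sites, function(s) {
    stopifnot(inherits(s, "variant_site"))
    if (s$chrom_id != genome$chrom_id) {
      stop("snp_windows(): site on ", s$chrom_id, " but genome is ", genome$chrom_id)
    }
    i <- s$pos - 1L  # 0-based variant index
    if (i < 0L || i >= genome$length) {
      stop(
        "snp_windows(): site ", s$chrom_id, ":", s$pos,
        " outside chromosome of length ", genome$length
      )
    }
    lo <- i - half
    hi <- i + half  # exclusive
    start <- max(lo, 0L)
    end <- min(hi, genome$length)
    left_pad <- start - lo
    right_pad <- hi - end
    ids <- c(
      rep(pad_id, left_pad),
      ids_full[(start + 1L):end],
      rep(pad_id, right_pad)
    )
    mask <- c(
      rep(FALSE, left_pad),
      rep(TRUE, end - start),
      rep(FALSE, right_pad)
    )
    genome_window(
      genome$sample_id, genome$chrom_id, start, end, ids, mask,
      mode = "SNP_SEQUENCE", anchor_pos = i
    )
  })
}

#' Stream windows for a set of chromosomes
#'
#' Deterministic window generation across chromosomes: windows are grouped
#' by (sample, chromosome) in the order the chromosomes are supplied, then
#' ordered by ascending start. Repeated invocation yields identical output.
#'
#' @param genomes List of [genome_sequence()].
#' @param mode `"ALL_SEQUENCE"` or `"SNP_SEQUENCE"`.
#' @param L_in Window length.
#' @param sites List of [variant_site()], required in SNP mode.
#' @param vocab A [token_vocab()].
#' @return Flat list of [genome_window()].
#' @export
window_stream <- function(genomes, mode = c("ALL_SEQUENCE", "SNP_SEQUENCE"),
                          L_in, sites = NULL, vocab = token_vocab()) {
  mode <- match.arg(mode)
  if (mode == "SNP_SEQUENCE" && (is.null(sites) || length(sites) == 0L)) {
    stop("window_stream(): SNP_SEQUENCE mode requires variant sites")
  }
  out <- lapply(genomes, function(g) {
    if (mode == "ALL_SEQUENCE") {
      segment_all(g, L_in, vocab)
    } else {
      on_chrom <- Filter(function(s) s$chrom_id == g$chrom_id, sites)
      snp_windows(g, on_chrom, L_in, vocab)
    }
  })
  unlist(out, recursive = FALSE)
}

#' Write windows to the package's binary container
#'
#' Header records the window length and a vocabulary hash so stale
#' artifacts are rejected on read; each record stores ids (unsigned bytes),
#' the pad mask, coordinates and mode.
#'
#' @param windows List of [genome_window()].
#' @param path Output file.
#' @param vocab A [token_vocab()].
#' @return `path`, invisibly.
#' @export
write_windows <- function(windows, path, vocab = token_vocab()) {
  stopifnot(length(windows) > 0L)
  L_in <- length(windows[[1]]$token_ids)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("GLMW"), con)
  writeBin(1L, con, size = 4, endian = "little")
  writeBin(as.integer(L_in), con, size = 4, endian = "little")
  hash <- vocab_hash(vocab)
  writeBin(charToRaw(hash), con)
  writeBin(length(windows), con, size = 4, endian = "little")
  put_str <- function(s) {
    r <- charToRaw(s)
    writeBin(length(r), con, size = 4, endian = "little")
    writeBin(r, con)
  }
  for (w in windows) {
    put_str(w$sample_id)
    put_str(w$chrom_id)
    writeBin(c(w$start, w$end, as.integer(w$anchor_pos)), con,
             size = 4, endian = "little")
    writeBin(as.integer(w$mode == "SNP_SEQUENCE"), con, size = 1)
    writeBin(as.raw(w$token_ids), con)
    writeBin(as.raw(as.integer(w$pad_mask)), con)
  }
  invisible(path)
}

#' Read windows from the binary container
#'
#' @param path File written by [write_windows()].
#' @param vocab Vocabulary expected by the reader; a hash mismatch errors.
#' @return List of [genome_window()].
#' @export
read_windows <- function(path, vocab = token_vocab()) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4))
  if (magic != "GLMW") stop("read_windows(): not a window container: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")  # version
  L_in <- readBin(con, "integer", 1, size = 4, endian = "little")
  hash <- rawToChar(readBin(con, "raw", 8))
  if (hash != vocab_hash(vocab)) {
    stop("read_windows(): vocabulary hash mismatch (file ", hash, ")")
  }
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  get_str <- function() {
    k <- readBin(con, "integer", 1, size = 4, endian = "little")
    rawToChar(readBin(con, "raw", k))
  }
  lapply(seq_len(n), function(i) {
    sample_id <- get_str()
    chrom_id <- get_str()
    coords <- readBin(con, "integer", 3, size = 4, endian = "little")
    is_snp <- readBin(con, "integer", 1, size = 1)
    ids <- as.integer(readBin(con, "raw", L_in))
    mask <- as.logical(as.integer(readBin(con, "raw", L_in)))
    genome_window(
      sample_id, chrom_id, coords[1], coords[2], ids, mask,
      mode = if (is_snp == 1L) "SNP_SEQUENCE" else "ALL_SEQUENCE",
      anchor_pos = coords[3]
    )
  })
}

#' Export window coordinates as BED for inspection
#'
#' @param windows List of [genome_window()].
#' @param path Output BED file (chrom, start, end, name = sample/mode).
#' @return `path`, invisibly.
#' @export
windows_to_bed <- function(windows, path) {
  lines <- vapply(windows, function(w) {
    paste(w$chrom_id, w$start, w$end, paste0(w$sample_id, "/", w$mode), sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
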