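# Plain-text persistence of per-(sample, chromosome) embedding tables, so
# chromosome vectors can be refused (average vs concatenation) without
# re-running the model.

#' Write a per-chromosome embedding table
#'
#' Tab-separated text: `sample_id`, `chrom_id`, then one column per
#' embedding dimension at full precision (bit-identical round trip).
#'
#' @param cvs A [chrom_vectors_from_windows()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_chrom_vectors <- function(cvs, path) {
  stopifnot(inherits(cvs, "chrom_vector_set"))
  d <- ncol(cvs$values)
  num <- vapply(seq_len(d), function(j) sprintf("%.17g", cvs$values[, j]),
                character(nrow(cvs$values)))
  if (nrow(cvs$values) == 1L) num <- matrix(num, nrow = 1)
  lines <- c(
    paste(c("sample_id", "chrom_id", paste0("e", seq_len(d))), collapse = "\t"),
    apply(cbind(cvs$sample_id, cvs$chrom_id, num), 1, paste, collapse = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-chromosome embedding table
#'
#' @param path File written by [write_chrom_vectors()].
#' @return A `chrom_vector_set`.
#' @export
read_chrom_vectors <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  structure(
    list(
      sample_id = as.character(df$sample_id),
      chrom_id = as.character(df$chrom_id),
      values = as.matrix(df[, -(1:2), drop = FALSE])
    ),
    class = "chrom_vector_set"
  )
}
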