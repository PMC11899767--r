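# Aggregation of window embeddings into per-chromosome vectors, optional
# dimension reduction to D_vec, and fusion of chromosomes into one
# per-sample feature vector by averaging or concatenation.

#' Aggregate window embeddings into one chromosome vector
#'
#' Arithmetic mean of the window vectors, so the result does not scale
#' with chromosome length (window count).
#'
#' @param window_vectors A numeric matrix `[n_windows x d]` or a non-empty
#'   list of equal-length numeric vectors.
#' @return Numeric vector of length `d`.
#' @export
chromosome_vector <- function(window_vectors) {
  if (is.list(window_vectors)) {
    if (length(window_vectors) == 0L) stop("chromosome_vector(): empty input")
    window_vectors <- do.call(rbind, window_vectors)
  }
  if (nrow(window_vectors) == 0L) stop("chromosome_vector(): empty input")
  colMeans(window_vectors)
}

#' Per-(sample, chromosome) embedding table
#'
#' Embeds every window with the model, then averages windows within each
#' (sample, chromosome) group.
#'
#' @param model A trained [hyena_model()][init_hyena].
#' @param windows List of [genome_window()].
#' @param batch_size Windows per forward pass.
#' @return An object of class `chrom_vector_set`: list with character
#'   vectors `sample_id`, `chrom_id` and a numeric matrix `values`
#'   `[n_groups x d_model]`, ordered as first encountered.
#' @export
chrom_vectors_from_windows <- function(model, windows, batch_size = 32L) {
  stopifnot(length(windows) > 0L)
  emb <- embed_windows(model, windows, batch_size = batch_size)
  key <- paste(
    vapply(windows, `[[`, "", "sample_id"),
    vapply(windows, `[[`, "", "chrom_id"),
    sep = "\r"
  )
  keys <- unique(key)
  values <- do.call(rbind, lapply(keys, function(k) {
    chromosome_vector(emb[key == k, , drop = FALSE])
  }))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  structure(
    list(
      sample_id = vapply(parts, `[[`, "", 1L),
      chrom_id = vapply(parts, `[[`, "", 2L),
      values = values
    ),
    class = "chrom_vector_set"
  )
}

#' @export
print.chrom_vector_set <- function(x, ...) {
  cat(sprintf(
    "<chrom_vector_set> %d (sample, chromosome) vectors of width %d\n",
    nrow(x$values), ncol(x$values)
  ))
  invisible(x)
}

#' Fit a dimension reducer to D_vec
#'
#' Identity when `D_vec` equals the input width; otherwise a principal
#' component projection (centred, unscaled) fitted on the supplied rows —
#' inside cross-validation these must be training-fold rows only, so the
#' reduction never sees test samples.
#'
#' @param M Numeric matrix `[n x d]` of chromosome vectors to fit on.
#' @param D_vec Target width (`<= d`; for a PCA fit also `<= n`).
#' @return An object of class `dim_reducer` with elements `kind`, `D_vec`
#'   and, for PCA, `center` and `rotation`.
#' @seealso [apply_reducer()]
#' @export
fit_reducer <- function(M, D_vec) {
  d <- ncol(M)
  if (D_vec > d) stop("fit_reducer(): D_vec (", D_vec, ") exceeds input width (", d, ")")
  if (D_vec == d) {
    return(structure(list(kind = "identity", D_vec = D_vec), class = "dim_reducer"))
  }
  if (nrow(M) < D_vec) {
    stop("fit_reducer(): need at least D_vec = ", D_vec, " rows to fit, got ", nrow(M))
  }
  pc <- stats::prcomp(M, center = TRUE, scale. = FALSE, rank. = D_vec)
  structure(
    list(kind = "pca", D_vec = D_vec, center = pc$center,
         rotation = pc$rotation[, seq_len(D_vec), drop = FALSE]),
    class = "dim_reducer"
  )
}

#' Apply a fitted dimension reducer
#'
#' @param reducer A [fit_reducer()] object.
#' @param M Numeric matrix `[n x d]`.
#' @return Numeric matrix `[n x D_vec]`.
#' @export
apply_reducer <- function(reducer, M) {
  stopifnot(inherits(reducer, "dim_reducer"))
  if (reducer$kind == "identity") return(M)
  sweep(M, 2, reducer$center) %*% reducer$rotation
}

#' Reduce chromosome vectors to D_vec
#'
#' Convenience wrapper: fits the reducer on `M` (or `fit_on` when given)
#' and applies it to `M`.
#'
#' @param M Numeric matrix `[n x d]`.
#' @param D_vec Target width.
#' @param fit_on Optional matrix to fit the reducer on (training rows).
#' @return List with `values` (`[n x D_vec]`) and `reducer`.
#' @export
reduce_dim <- function(M, D_vec, fit_on = NULL) {
  reducer <- fit_reducer(if (is.null(fit_on)) M else fit_on, D_vec)
  list(values = apply_reducer(reducer, M), reducer = reducer)
}

#' Fuse one sample's chromosome vectors by averaging
#'
#' Element-wise mean across chromosomes; the result has width `D_vec` and
#' is invariant under chromosome permutation.
#'
#' @param values Numeric matrix `[n_chrom x D_vec]`, one row per chromosome.
#' @param sample_id Sample identifier.
#' @return An object of class `sample_feature_vector` (fields `sample_id`,
#'   `mode = "AVERAGE"`, `values`).
#' @export
fuse_average <- function(values, sample_id = "sample") {
  values <- as.matrix(values)
  if (nrow(values) == 0L) stop("fuse_average(): no chromosome vectors")
  structure(
    list(sample_id = sample_id, mode = "AVERAGE",
         values = colMeans(values), chrom_order = NULL),
    class = "sample_feature_vector"
  )
}

#' Fuse one sample's chromosome vectors by concatenation
#'
#' Rows are concatenated in the order given by `chrom_order`, yielding a
#' vector of width `n_chrom * D_vec` whose block `k` is exactly chromosome
#' `chrom_order[k]`'s vector.
#'
#' @param values Numeric matrix `[n_chrom x D_vec]` with rownames set to
#'   chromosome ids.
#' @param chrom_order Character vector: every chromosome exactly once.
#' @param sample_id Sample identifier.
#' @return An object of class `sample_feature_vector` with
#'   `mode = "CONCAT"` and the recorded `chrom_order`.
#' @export
fuse_concat <- function(values, chrom_order, sample_id = "sample") {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("fuse_concat(): values needs chromosome rownames")
  if (anyDuplicated(chrom_order) || !setequal(chrom_order, rownames(values)) ||
      length(chrom_order) != nrow(values)) {
    stop("fuse_concat(): chrom_order must list each chromosome exactly once")
  }
  structure(
    list(sample_id = sample_id, mode = "CONCAT",
         values = as.vector(t(values[chrom_order, , drop = FALSE])),
         chrom_order = chrom_order),
    class = "sample_feature_vector"
  )
}

#' @export
print.sample_feature_vector <- function(x, ...) {
  cat(sprintf(
    "<sample_feature_vector> sample=%s mode=%s width=%d\n",
    x$sample_id, x$mode, length(x$values)
  ))
  invisible(x)
}

#' Build the per-sample feature table
#'
#' Applies an optional dimension reduction to all chromosome vectors and
#' fuses each sample's rows by the requested mode. Chromosome order for
#' concatenation defaults to lexicographic, so repeated runs agree.
#'
#' @param cvs A [chrom_vectors_from_windows()] result.
#' @param fusion `"AVERAGE"` or `"CONCAT"`.
#' @param D_vec Target per-chromosome width; `NULL` keeps `d_model`.
#' @param reducer Optional pre-fitted [fit_reducer()] (e.g. fitted on
#'   training folds); by default one is fitted on all rows of `cvs`.
#' @param chrom_order Chromosome order for `"CONCAT"`.
#' @return A [tibble::tibble] with `sample_id` and numeric feature columns
#'   `f1 ... fK`; the reducer is attached as attribute `"reducer"`, the
#'   fusion mode as `"fusion"` and the chromosome order as `"chrom_order"`.
#' @export
fuse_samples <- function(cvs, fusion = c("AVERAGE", "CONCAT"), D_vec = NULL,
                         reducer = NULL, chrom_order = NULL) {
  fusion <- match.arg(fusion)
  stopifnot(inherits(cvs, "chrom_vector_set"))
  M <- cvs$values
  if (!is.null(D_vec) && is.null(reducer)) reducer <- fit_reducer(M, D_vec)
  if (!is.null(reducer)) M <- apply_reducer(reducer, M)
  if (is.null(chrom_order)) chrom_order <- sort(unique(cvs$chrom_id))
  samples <- unique(cvs$sample_id)
  rows <- lapply(samples, function(s) {
    sel <- cvs$sample_id == s
    vals <- M[sel, , drop = FALSE]
    rownames(vals) <- cvs$chrom_id[sel]
    if (fusion == "AVERAGE") {
      fuse_average(vals, sample_id = s)$values
    } else {
      fuse_concat(vals, chrom_order, sample_id = s)$values
    }
  })
  feat <- do.call(rbind, rows)
  colnames(feat) <- paste0("f", seq_len(ncol(feat)))
  out <- tibble::as_tibble(as.data.frame(feat))
  out <- tibble::add_column(out, sample_id = samples, .before = 1)
  attr(out, "reducer") <- reducer
  attr(out, "fusion") <- fusion
  attr(out, "chrom_order") <- chrom_order
  out
}

#' Write a feature table at full precision
#'
#' Tab-separated text with 17 significant digits, so write/read round
#' trips are bit-identical.
#'
#' @param features Tibble from [fuse_samples()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  num <- vapply(
    features[-1],
    function(col) sprintf("%.17g", col),
    character(nrow(features))
  )
  if (nrow(features) == 1L) num <- matrix(num, nrow = 1)
  lines <- c(
    paste(colnames(features), collapse = "\t"),
    apply(cbind(features$sample_id, num), 1, paste, collapse = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a feature table written by [write_features()]
#'
#' @param path Input file.
#' @return A [tibble::tibble] with `sample_id` and numeric feature columns.
#' @export
read_features <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = NA)
  df$sample_id <- as.character(df$sample_id)
  tibble::as_tibble(df)
}
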