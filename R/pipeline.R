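# High-level pipeline: train the language model on genome windows (stage
# A), embed whole genomes into per-sample feature vectors (stage B), and
# evaluate the vectors in cross-validated trait prediction (stage C).

#' Read genomes from a FASTA file or a directory of per-sample FASTA files
#'
#' A directory is read as one sample per file (sample id = file name
#' without extension, files in sorted order); a single file as one sample.
#'
#' @param path FASTA file or directory containing `.fa`/`.fasta` files.
#' @return Flat list of [genome_sequence()].
#' @export
read_genomes <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(fa|fasta)$", full.names = TRUE))
    if (length(files) == 0L) stop("read_genomes(): no FASTA files in ", path)
    unlist(lapply(files, read_fasta), recursive = FALSE)
  } else {
    read_fasta(path)
  }
}

#' Train the language model on a set of genomes (stage A)
#'
#' Windows every chromosome under the requested input mode and trains a
#' fresh model with the next-nucleotide objective.
#'
#' @param genomes List of [genome_sequence()].
#' @param config A [hyena_config()].
#' @param mode `"ALL_SEQUENCE"` or `"SNP_SEQUENCE"`.
#' @param sites Variant sites (SNP mode).
#' @param eval_corpus Optional held-out windows logged each epoch.
#' @param verbose Print per-epoch losses.
#' @return A trained [hyena_model()][init_hyena].
#' @export
pipeline_train <- function(genomes, config, mode = "ALL_SEQUENCE",
                           sites = NULL, eval_corpus = NULL, verbose = FALSE) {
  if (length(genomes) == 0L) stop("pipeline_train(): no input genomes")
  windows <- window_stream(genomes, mode = mode, L_in = config$L_in, sites = sites)
  train_lm(windows, config, eval_corpus = eval_corpus, verbose = verbose)
}

#' Embed genomes into per-sample feature vectors (stage B)
#'
#' Windows each sample's chromosomes, embeds every window, averages
#' windows into chromosome vectors, optionally reduces them to `D_vec`
#' principal components, and fuses chromosomes per sample.
#'
#' @param model A trained [hyena_model()][init_hyena].
#' @param genomes List of [genome_sequence()] (all samples).
#' @param mode `"ALL_SEQUENCE"` or `"SNP_SEQUENCE"`.
#' @param fusion `"AVERAGE"` or `"CONCAT"`.
#' @param D_vec Optional per-chromosome width (defaults to `d_model`).
#' @param sites Variant sites (SNP mode).
#' @param batch_size Windows per forward pass.
#' @return Feature tibble from [fuse_samples()].
#' @export
pipeline_embed <- function(model, genomes, mode = "ALL_SEQUENCE",
                           fusion = "AVERAGE", D_vec = NULL, sites = NULL,
                           batch_size = 32L) {
  if (mode == "SNP_SEQUENCE" && (is.null(sites) || length(sites) == 0L)) {
    stop("pipeline_embed(): SNP_SEQUENCE mode requires variant sites")
  }
  windows <- window_stream(genomes, mode = mode, L_in = model$config$L_in,
                           sites = sites)
  cvs <- chrom_vectors_from_windows(model, windows, batch_size = batch_size)
  fuse_samples(cvs, fusion = fusion, D_vec = D_vec)
}

#' Cross-validated trait prediction from a feature table (stage C)
#'
#' Runs [tenfold_cv()] once per trait in the trait table. Qualitative
#' traits are first cleaned with [filter_categories()].
#'
#' @param features Feature tibble ([pipeline_embed()] / [read_features()]).
#' @param traits Trait table ([trait_records()] / [read_traits()]).
#' @param spec A [predictor_spec()].
#' @param min_count Minimum category size kept for qualitative traits.
#' @param k Folds.
#' @param seed Seed for partitions and stochastic predictors.
#' @return Named list of `cv_report`, one per trait.
#' @export
pipeline_predict <- function(features, traits, spec = predictor_spec("gbt"),
                             min_count = 50L, k = 10L, seed = 1000L) {
  common <- intersect(features$sample_id, traits$sample_id)
  if (length(common) == 0L) stop("pipeline_predict(): no overlapping samples")
  out <- list()
  for (tn in unique(traits$trait_name)) {
    rec <- traits[traits$trait_name == tn, , drop = FALSE]
    if (unique(rec$trait_type) == "QUALITATIVE") {
      rec <- filter_categories(rec, min_count = min_count)$records
    } else {
      rec <- rec[!is.na(suppressWarnings(as.numeric(rec$value))), , drop = FALSE]
      rec$value <- as.numeric(rec$value)
    }
    out[[tn]] <- tenfold_cv(features, rec, spec, k = k, seed = seed)
  }
  out
}

#' Sweep context window and feature dimension (experiment driver)
#'
#' Trains one model per `L_in`, embeds at every feasible `D_vec`
#' (`D_vec <= d_model`; infeasible cells are recorded as skipped, not
#' dropped silently), and cross-validates each cell's features.
#'
#' @param genomes Training + embedding genomes (list of
#'   [genome_sequence()]).
#' @param traits Trait table.
#' @param L_in_grid,D_vec_grid Grids to sweep.
#' @param base_config A [hyena_config()] supplying all other
#'   hyperparameters.
#' @param spec Predictor to evaluate with.
#' @param mode,fusion Input and fusion modes.
#' @param sites Variant sites (SNP mode).
#' @param k,seed Cross-validation settings.
#' @return List with `summary` (tibble: `L_in`, `D_vec`, `status`, mean
#'   metrics per cell) and `reports` (named list of per-trait report
#'   lists, keys `"L<L_in>_D<D_vec>"`).
#' @export
pipeline_sweep <- function(genomes, traits, L_in_grid, D_vec_grid,
                           base_config, spec = predictor_spec("gbt"),
                           mode = "ALL_SEQUENCE", fusion = "AVERAGE",
                           sites = NULL, k = 10L, seed = 1000L) {
  rows <- list()
  reports <- list()
  for (L in L_in_grid) {
    cfg <- do.call(hyena_config, utils::modifyList(unclass(base_config), list(L_in = L)))
    model <- pipeline_train(genomes, cfg, mode = mode, sites = sites)
    for (D in D_vec_grid) {
      key <- sprintf("L%d_D%d", L, D)
      if (D > cfg$d_model) {
        rows[[key]] <- tibble::tibble(
          L_in = L, D_vec = D, status = "skipped (D_vec > d_model)",
          mean_mse = NA_real_, mean_mae = NA_real_, mean_pcc = NA_real_
        )
        next
      }
      feats <- pipeline_embed(model, genomes, mode = mode, fusion = fusion,
                              D_vec = if (D == cfg$d_model) NULL else D,
                              sites = sites)
      reps <- pipeline_predict(feats, traits, spec, k = k, seed = seed)
      quant <- Filter(function(r) r$trait_type == "QUANTITATIVE", reps)
      rows[[key]] <- tibble::tibble(
        L_in = L, D_vec = D, status = "ok",
        mean_mse = mean(vapply(quant, function(r) r$mean_metrics[["mse"]], 0)),
        mean_mae = mean(vapply(quant, function(r) r$mean_metrics[["mae"]], 0)),
        mean_pcc = mean(vapply(quant, function(r) r$mean_metrics[["pcc"]], 0))
      )
      reports[[key]] <- reps
    }
  }
  list(summary = do.call(rbind, rows), reports = reports)
}

#' Permutation null for cross-validated correlation
#'
#' Re-runs the cross-validation with labels randomly permuted
#' `n_perm` times and returns the mean held-out metric of each permuted
#' run — the reference distribution a real signal must beat.
#'
#' @param features Feature tibble.
#' @param targets Trait rows for a single quantitative trait.
#' @param spec A [predictor_spec()].
#' @param n_perm Number of permutations.
#' @param metric Metric name to extract (default `"pcc"`).
#' @param k,seed Cross-validation settings; permutation `i` uses
#'   `seed + i` for the shuffle.
#' @return Numeric vector of length `n_perm`.
#' @export
permutation_null <- function(features, targets, spec, n_perm = 20L,
                             metric = "pcc", k = 10L, seed = 1000L) {
  vapply(seq_len(n_perm), function(i) {
    shuffled <- targets
    with_seed(seed + i, {
      shuffled$value <- sample(shuffled$value)
    })
    rep_i <- tenfold_cv(features, shuffled, spec, k = k, seed = seed)
    rep_i$mean_metrics[[metric]]
  }, 0)
}
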