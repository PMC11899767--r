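# Supervised evaluation harness: trait tables, min-max normalization,
# small-category filtering, stratified ten-fold cross-validation and a
# registry of predictors.

#' Build a trait record table
#'
#' @param sample_id,trait_name Character vectors.
#' @param value Trait values: numeric for quantitative traits, labels for
#'   qualitative ones (stored as character).
#' @param trait_type `"QUANTITATIVE"` or `"QUALITATIVE"`, recycled.
#' @return A [tibble::tibble] with columns `sample_id`, `trait_name`,
#'   `value`, `trait_type`.
#' @export
trait_records <- function(sample_id, trait_name, value, trait_type) {
  trait_type <- match.arg(trait_type, c("QUANTITATIVE", "QUALITATIVE"))
  tibble::tibble(
    sample_id = as.character(sample_id),
    trait_name = as.character(trait_name),
    value = if (trait_type == "QUANTITATIVE") as.numeric(value) else as.character(value),
    trait_type = trait_type
  )
}

#' Read a trait table
#'
#' Expects tab-separated columns `sample_id`, `trait_name`, `value`,
#' `trait_type`; quantitative values are parsed as numbers (empty or NA
#' entries stay missing).
#'
#' @param path Input file.
#' @return A [tibble::tibble].
#' @export
read_traits <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  stopifnot(all(c("sample_id", "trait_name", "value", "trait_type") %in% names(df)))
  tibble::as_tibble(df)
}

#' Write a trait table
#'
#' @param records Tibble from [trait_records()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_traits <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Min-max normalization of trait values
#'
#' Affine map of the fitted range onto `[0, 1]`. The transform is
#' invertible and, applied to out-of-range values (e.g. a test fold
#' exceeding the training maximum), extends linearly without clipping.
#'
#' @param values Numeric vector with at least two distinct values.
#' @return List with `values` (normalized), and `transform` (`min`,
#'   `range`) for [apply_norm()] / [invert_norm()].
#' @export
normalize_traits <- function(values) {
  values <- as.numeric(values)
  lo <- min(values); hi <- max(values)
  if (!is.finite(lo) || !is.finite(hi) || hi == lo) {
    stop("normalize_traits(): need >= 2 distinct finite values")
  }
  tr <- list(min = lo, range = hi - lo)
  list(values = apply_norm(tr, values), transform = tr)
}

#' @rdname normalize_traits
#' @param transform A transform from [normalize_traits()].
#' @export
apply_norm <- function(transform, values) (values - transform$min) / transform$range

#' @rdname normalize_traits
#' @export
invert_norm <- function(transform, values) values * transform$range + transform$min

#' Drop missing values and under-represented categories
#'
#' For a qualitative trait: removes records with missing labels, then
#' every category whose count is below `min_count`. The removal log lists
#' each dropped category with its count.
#'
#' @param records Trait table rows for one qualitative trait.
#' @param min_count Minimum samples a category needs to be kept.
#' @return List with `records` (kept rows) and `removed` (tibble of
#'   `category`, `count`, `reason`).
#' @export
filter_categories <- function(records, min_count = 50L) {
  if (nrow(records) == 0L) stop("filter_categories(): empty input")
  missing <- is.na(records$value) | records$value == ""
  n_missing <- sum(missing)
  records <- records[!missing, , drop = FALSE]
  counts <- table(records$value)
  small <- names(counts)[counts < min_count]
  removed <- tibble::tibble(
    category = small,
    count = as.integer(counts[small]),
    reason = sprintf("count < %d", min_count)
  )
  kept <- records[!(records$value %in% small), , drop = FALSE]
  if (nrow(kept) == 0L) {
    stop("filter_categories(): every category fell below min_count = ", min_count)
  }
  if (n_missing > 0L || nrow(removed) > 0L) {
    message(sprintf(
      "filter_categories(): dropped %d missing record(s); removed categories: %s",
      n_missing,
      if (nrow(removed)) paste0(removed$category, " (n=", removed$count, ")", collapse = ", ")
      else "none"
    ))
  }
  list(records = kept, removed = removed)
}

#' Assign samples to cross-validation folds
#'
#' Random partition into `k` folds with sizes differing by at most one;
#' when `labels` are given the assignment is stratified so each category
#' is spread as evenly as possible across folds.
#'
#' @param n Number of samples.
#' @param k Number of folds.
#' @param labels Optional class labels for stratification.
#' @param seed Seed; the same seed reproduces the same partition.
#' @return Integer vector of fold ids in `1..k`.
#' @export
make_folds <- function(n, k = 10L, labels = NULL, seed = 1000L) {
  stopifnot(n >= k)
  with_seed(seed, {
    fold <- integer(n)
    if (is.null(labels)) {
      fold <- rep_len(seq_len(k), n)[sample.int(n)]
    } else {
      labels <- as.character(labels)
      counter <- 0L
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        idx <- idx[sample.int(length(idx))]
        fold[idx] <- ((counter + seq_along(idx) - 1L) %% k) + 1L
        counter <- counter + length(idx)
      }
    }
    fold
  })
}

# ---- predictor registry ----------------------------------------------------

predictor_registry <- function() {
  c("gbt", "random_forest", "extra_trees", "knn", "ridge", "mlp", "cnn")
}

#' Specify a predictor
#'
#' @param name One of `"gbt"` (gradient-boosted trees), `"random_forest"`,
#'   `"extra_trees"`, `"knn"`, `"ridge"` (penalized linear model),
#'   `"mlp"` (single-hidden-layer feedforward network) or `"cnn"`
#'   (small 1-D convolutional network over the feature vector).
#' @param ... Hyperparameter overrides for the chosen predictor.
#' @return An object of class `predictor_spec`.
#' @export
predictor_spec <- function(name, ...) {
  if (!name %in% predictor_registry()) {
    stop("predictor_spec(): unknown predictor '", name, "'; registered: ",
         paste(predictor_registry(), collapse = ", "))
  }
  structure(list(name = name, params = list(...)), class = "predictor_spec")
}

pget <- function(spec, key, default) {
  if (!is.null(spec$params[[key]])) spec$params[[key]] else default
}

#' Fit a predictor on training data and predict the test set
#'
#' All predictors are run with fixed seeds so repeated calls give
#' identical predictions where the underlying method permits.
#'
#' @param spec A [predictor_spec()].
#' @param X_train,X_test Numeric feature matrices.
#' @param y_train Numeric vector (quantitative) or labels (qualitative).
#' @param trait_type `"QUANTITATIVE"` or `"QUALITATIVE"`.
#' @param seed Seed for stochastic predictors.
#' @return Predictions for every test row.
#' @export
run_predictor <- function(spec, X_train, y_train, X_test,
                          trait_type = "QUANTITATIVE", seed = 1000L) {
  stopifnot(inherits(spec, "predictor_spec"))
  classify <- trait_type == "QUALITATIVE"
  X_train <- as.matrix(X_train); X_test <- as.matrix(X_test)
  switch(
    spec$name,
    gbt = with_seed(seed, {
      pars <- list(
        max_depth = pget(spec, "max_depth", 4L),
        eta = pget(spec, "eta", 0.1),
        nthread = 1
      )
      if (classify) {
        labs <- sort(unique(as.character(y_train)))
        y <- match(as.character(y_train), labs) - 1L
        pars$objective <- "multi:softmax"
        pars$num_class <- length(labs)
        dtr <- xgboost::xgb.DMatrix(X_train, label = y)
        bst <- xgboost::xgb.train(pars, dtr, nrounds = pget(spec, "nrounds", 100L),
                                  verbose = 0)
        labs[stats::predict(bst, xgboost::xgb.DMatrix(X_test)) + 1L]
      } else {
        pars$objective <- "reg:squarederror"
        dtr <- xgboost::xgb.DMatrix(X_train, label = y_train)
        bst <- xgboost::xgb.train(pars, dtr, nrounds = pget(spec, "nrounds", 100L),
                                  verbose = 0)
        stats::predict(bst, xgboost::xgb.DMatrix(X_test))
      }
    }),
    random_forest = ,
    extra_trees = {
      df_tr <- data.frame(X_train)
      df_te <- data.frame(X_test)
      colnames(df_te) <- colnames(df_tr)
      y <- if (classify) factor(y_train) else y_train
      fit <- ranger::ranger(
        x = df_tr, y = y,
        num.trees = pget(spec, "num_trees", 300L),
        mtry = pget(spec, "mtry", max(1L, floor(sqrt(ncol(X_train))))),
        splitrule = if (spec$name == "extra_trees") "extratrees"
                    else if (classify) "gini" else "variance",
        num.random.splits = if (spec$name == "extra_trees") 1L else 1L,
        seed = seed, num.threads = 1
      )
      pr <- stats::predict(fit, df_te, num.threads = 1)$predictions
      if (classify) as.character(pr) else pr
    },
    knn = {
      k <- pget(spec, "k", 5L)
      if (classify) {
        as.character(class::knn(X_train, X_test, cl = factor(y_train), k = k))
      } else {
        # distance-based k-nearest-neighbour regression
        d2 <- outer(rowSums(X_test^2), rowSums(X_train^2), "+") -
          2 * X_test %*% t(X_train)
        apply(d2, 1, function(r) mean(y_train[order(r)[seq_len(k)]]))
      }
    },
    ridge = {
      lambda <- pget(spec, "lambda", 0.01)
      if (classify) {
        fam <- if (length(unique(y_train)) > 2) "multinomial" else "binomial"
        fit <- glmnet::glmnet(X_train, factor(y_train), alpha = 0,
                              lambda = lambda, family = fam)
        as.character(stats::predict(fit, X_test, type = "class")[, 1])
      } else {
        fit <- glmnet::glmnet(X_train, y_train, alpha = 0, lambda = lambda)
        as.numeric(stats::predict(fit, X_test))
      }
    },
    mlp = {
      with_seed(seed, {
        if (classify) {
          fit <- nnet::nnet(
            X_train, nnet::class.ind(factor(y_train)),
            size = pget(spec, "size", 16L), decay = pget(spec, "decay", 1e-3),
            maxit = pget(spec, "maxit", 200L), softmax = TRUE, trace = FALSE,
            MaxNWts = 1e5
          )
          levels(factor(y_train))[max.col(stats::predict(fit, X_test))]
        } else {
          fit <- nnet::nnet(
            X_train, y_train, size = pget(spec, "size", 16L),
            decay = pget(spec, "decay", 1e-3), maxit = pget(spec, "maxit", 200L),
            linout = TRUE, trace = FALSE, MaxNWts = 1e5
          )
          as.numeric(stats::predict(fit, X_test))
        }
      })
    },
    cnn = {
      fit_cnn(X_train, y_train, X_test, classify = classify, seed = seed,
              n_filter = pget(spec, "n_filter", 8L),
              kernel = pget(spec, "kernel", 5L),
              epochs = pget(spec, "epochs", 120L),
              lr = pget(spec, "lr", 1e-2))
    },
    stop("run_predictor(): unknown predictor '", spec$name, "'; registered: ",
         paste(predictor_registry(), collapse = ", "))
  )
}

# minimal seeded 1-D convolutional network over the feature axis:
# conv(kernel) -> ReLU -> mean pool -> linear head, trained with Adam.
fit_cnn <- function(X_train, y_train, X_test, classify, seed,
                    n_filter = 8L, kernel = 5L, epochs = 120L, lr = 1e-2) {
  p <- ncol(X_train)
  kernel <- min(kernel, p)
  labs <- NULL
  if (classify) {
    labs <- sort(unique(as.character(y_train)))
    Y <- diag(length(labs))[match(as.character(y_train), labs), , drop = FALSE]
  } else {
    Y <- matrix(y_train, ncol = 1)
  }
  n_out <- ncol(Y)
  # im2col view of each sample's feature vector
  n_pos <- p - kernel + 1L
  im2col <- function(X) {
    idx <- outer(seq_len(kernel), seq_len(n_pos) - 1L, "+")
    array(X[, as.vector(idx), drop = FALSE], c(nrow(X), kernel, n_pos))
  }
  A_tr <- im2col(X_train); A_te <- im2col(X_test)
  with_seed(seed, {
    W <- matrix(stats::rnorm(kernel * n_filter, sd = 0.3), kernel, n_filter)
    bW <- rep(0, n_filter)
    V <- matrix(stats::rnorm(n_filter * n_out, sd = 0.3), n_filter, n_out)
    bV <- rep(0, n_out)
    theta <- c(W, bW, V, bV)
    st <- adam_init(theta)
    unpack <- function(th) {
      i <- 0
      W <<- matrix(th[i + seq_len(kernel * n_filter)], kernel, n_filter); i <- i + kernel * n_filter
      bW <<- th[i + seq_len(n_filter)]; i <- i + n_filter
      V <<- matrix(th[i + seq_len(n_filter * n_out)], n_filter, n_out); i <- i + n_filter * n_out
      bV <<- th[i + seq_len(n_out)]
    }
    # flatten conv as matrix product: for each position, columns are the
    # kernel window; stack positions along rows
    conv_fwd <- function(A) {
      n <- dim(A)[1]
      M <- matrix(aperm(A, c(1, 3, 2)), n * n_pos, kernel)
      Z <- addb(M %*% W, bW)            # [n*n_pos x n_filter]
      R <- pmax(Z, 0)
      Pl <- rowsum(R, group = rep(seq_len(n), times = n_pos)) / n_pos
      list(M = M, Z = Z, R = R, P = Pl, out = addb(Pl %*% V, bV))
    }
    n_tr <- nrow(X_train)
    for (ep in seq_len(epochs)) {
      f <- conv_fwd(A_tr)
      if (classify) {
        mx <- f$out[cbind(seq_len(n_tr), max.col(f$out, ties.method = "first"))]
        P <- exp(f$out - mx)
        P <- P / rowSums(P)
        dout <- (P - Y) / n_tr
      } else {
        dout <- 2 * (f$out - Y) / n_tr
      }
      dV <- crossprod(f$P, dout); dbV <- colSums(dout)
      dP <- dout %*% t(V)
      dR <- dP[rep(seq_len(n_tr), times = n_pos), , drop = FALSE] / n_pos
      dZ <- dR * (f$Z > 0)
      dW <- crossprod(f$M, dZ); dbW <- colSums(dZ)
      g <- c(dW, dbW, dV, dbV)
      up <- adam_step(theta, g, st, lr = lr, clip = 10)
      theta <- up$theta; st <- up$state
      unpack(theta)
    }
    pred <- conv_fwd(A_te)$out
    if (classify) labs[max.col(pred, ties.method = "first")] else as.numeric(pred)
  })
}

# ---- cross-validation ------------------------------------------------------

#' Ten-fold cross-validated trait prediction
#'
#' Randomly partitions the samples into `k` folds of near-equal size
#' (stratified by label for qualitative traits), then trains the predictor
#' on nine folds and tests on the held-out fold, rotating through all
#' folds. Target normalization (min-max, quantitative traits) and any
#' feature-space dimension reduction are fitted on the training fold only,
#' so no information leaks from test samples. MSE and MAE are reported on
#' the normalized scale; the Pearson correlation is computed after mapping
#' predictions back to the original trait scale.
#'
#' @param features Feature tibble ([fuse_samples()] / [read_features()]):
#'   `sample_id` plus numeric columns.
#' @param targets Trait table rows for a single trait ([trait_records()]).
#' @param spec A [predictor_spec()].
#' @param k Number of folds.
#' @param seed Seed for the partition and stochastic predictors.
#' @param reduce_to Optional width for per-fold principal-component
#'   reduction of the features.
#' @return An object of class `cv_report`; see [tidy.cv_report()] and
#'   [glance.cv_report()].
#' @export
tenfold_cv <- function(features, targets, spec, k = 10L, seed = 1000L,
                       reduce_to = NULL) {
  stopifnot(inherits(spec, "predictor_spec"))
  trait_type <- unique(targets$trait_type)
  stopifnot(length(trait_type) == 1L)
  trait_name <- unique(targets$trait_name)
  stopifnot(length(trait_name) == 1L)
  classify <- trait_type == "QUALITATIVE"
  ids <- intersect(features$sample_id, targets$sample_id)
  if (length(ids) == 0L) stop("tenfold_cv(): no overlapping sample ids")
  if (anyDuplicated(targets$sample_id[targets$sample_id %in% ids])) {
    stop("tenfold_cv(): duplicated sample ids in targets")
  }
  if (length(ids) < 2L * k) {
    stop("tenfold_cv(): need at least ", 2L * k, " matched samples, got ", length(ids))
  }
  X <- as.matrix(features[match(ids, features$sample_id), -1, drop = FALSE])
  yv <- targets$value[match(ids, targets$sample_id)]
  y <- if (classify) as.character(yv) else as.numeric(yv)
  fold <- make_folds(length(ids), k = k,
                     labels = if (classify) y else NULL, seed = seed)
  per_fold <- lapply(seq_len(k), function(f) {
    tr <- fold != f; te <- !tr
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    if (!is.null(reduce_to)) {
      red <- fit_reducer(Xtr, reduce_to)
      Xtr <- apply_reducer(red, Xtr)
      Xte <- apply_reducer(red, Xte)
    }
    if (classify) {
      pred <- run_predictor(spec, Xtr, y[tr], Xte, trait_type, seed = seed + f)
      tibble::tibble(fold = f, accuracy = classification_accuracy(y[te], pred))
    } else {
      # a constant training target cannot be min-max scaled; pass it through
      nm <- if (stats::sd(y[tr]) == 0) {
        list(values = y[tr], transform = list(min = 0, range = 1))
      } else {
        normalize_traits(y[tr])
      }
      pred_n <- run_predictor(spec, Xtr, nm$values, Xte, trait_type, seed = seed + f)
      obs_n <- apply_norm(nm$transform, y[te])
      pred_o <- invert_norm(nm$transform, pred_n)
      # correlation is undefined on a constant fold; record NA, not an error
      pcc_f <- tryCatch(pcc(y[te], pred_o), error = function(e) NA_real_)
      tibble::tibble(
        fold = f,
        mse = mse(obs_n, pred_n),
        mae = mae(obs_n, pred_n),
        pcc = pcc_f
      )
    }
  })
  fold_metrics <- do.call(rbind, per_fold)
  mean_metrics <- colMeans(fold_metrics[-1], na.rm = TRUE)
  structure(
    list(
      trait_name = trait_name, predictor_name = spec$name,
      trait_type = trait_type, fold_metrics = fold_metrics,
      mean_metrics = mean_metrics, n_samples = length(ids),
      k = k, seed = seed
    ),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "<cv_report> trait=%s predictor=%s n=%d folds=%d\n  mean: %s\n",
    x$trait_name, x$predictor_name, x$n_samples, x$k,
    paste(names(x$mean_metrics), sprintf("%.4f", x$mean_metrics),
          sep = "=", collapse = " ")
  ))
  invisible(x)
}

#' Per-fold metrics of a cross-validation report
#'
#' @param x A [tenfold_cv()] report.
#' @param ... Unused.
#' @return Tibble with one row per fold.
#' @export
tidy.cv_report <- function(x, ...) {
  tibble::add_column(
    x$fold_metrics,
    trait_name = x$trait_name, predictor_name = x$predictor_name,
    .before = 1
  )
}

#' One-row summary of a cross-validation report
#'
#' @param x A [tenfold_cv()] report.
#' @param ... Unused.
#' @return One-row tibble with the mean metrics, `n_samples` and `k`.
#' @export
glance.cv_report <- function(x, ...) {
  out <- tibble::as_tibble(as.list(x$mean_metrics))
  tibble::add_column(
    out,
    trait_name = x$trait_name, predictor_name = x$predictor_name,
    n_samples = x$n_samples, k = x$k, .before = 1
  )
}

#' Turn a genolm object into a tidy tibble
#'
#' @param x An object with a `tidy` method (e.g. a [tenfold_cv()] report).
#' @param ... Passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row model summary of a genolm object
#'
#' @param x An object with a `glance` method (e.g. a [tenfold_cv()] report).
#' @param ... Passed to methods.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Save a cross-validation report as JSON and CSV
#'
#' @param report A [tenfold_cv()] report.
#' @param stem Output path stem; writes `<stem>.json` and `<stem>.csv`.
#' @return The JSON path, invisibly.
#' @export
write_cv_report <- function(report, stem) {
  json_path <- paste0(stem, ".json")
  jsonlite::write_json(
    list(
      trait_name = report$trait_name, predictor_name = report$predictor_name,
      trait_type = report$trait_type, n_samples = report$n_samples,
      k = report$k, seed = report$seed,
      fold_metrics = report$fold_metrics,
      mean_metrics = as.list(report$mean_metrics)
    ),
    json_path, auto_unbox = TRUE, digits = NA
  )
  utils::write.csv(tidy.cv_report(report), paste0(stem, ".csv"), row.names = FALSE)
  invisible(json_path)
}

#' Plot per-fold metrics of a cross-validation report
#'
#' @param object A [tenfold_cv()] report.
#' @param ... Unused.
#' @return A ggplot object (requires the ggplot2 package).
#' @exportS3Method ggplot2::autoplot
autoplot.cv_report <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("autoplot.cv_report() needs ggplot2")
  }
  fm <- object$fold_metrics
  long <- do.call(rbind, lapply(setdiff(names(fm), "fold"), function(m) {
    data.frame(fold = fm$fold, metric = m, value = fm[[m]])
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = factor(fold), y = value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(
      x = "fold", y = NULL,
      title = sprintf("%s / %s (10-fold CV)", object$trait_name, object$predictor_name)
    )
}
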