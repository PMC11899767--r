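test_that("min-max normalization is exact, invertible and unclipped", {
  nm <- normalize_traits(c(0, 5, 10))
  expect_identical(nm$values, c(0, 0.5, 1))
  x <- c(2.5, 7.1, 9.9)
  expect_lt(max(abs(invert_norm(nm$transform, apply_norm(nm$transform, x)) - x)), 1e-12)
  expect_identical(apply_norm(nm$transform, 15), 1.5)  # beyond training max
  expect_error(normalize_traits(c(3, 3, 3)), "distinct")
})

test_that("category filtering reproduces the flower-colour fixture", {
  counts <- c(P = 3227L, W = 1631L, Dp = 30L, B = 5L, Lp = 5L, Pth = 4L)
  records <- trait_records(
    sample_id = paste0("s", seq_len(sum(counts))),
    trait_name = "FC",
    value = rep(names(counts), counts),
    trait_type = "QUALITATIVE"
  )
  res <- suppressMessages(filter_categories(records, min_count = 50L))
  expect_setequal(unique(res$records$value), c("P", "W"))
  expect_identical(nrow(res$records), 3227L + 1631L)
  expect_setequal(res$removed$category, c("Dp", "B", "Lp", "Pth"))
  expect_identical(sum(res$removed$count), 30L + 5L + 5L + 4L)
})

test_that("category filtering drops missing values and guards degenerate input", {
  rec <- trait_records(paste0("s", 1:120), "t",
                       c(rep("x", 60), rep("y", 59), NA), "QUALITATIVE")
  res <- suppressMessages(filter_categories(rec, min_count = 50L))
  expect_identical(nrow(res$records), 119L)
  expect_identical(nrow(res$removed), 0L)
  small <- trait_records(paste0("s", 1:10), "t", rep(c("a", "b"), 5), "QUALITATIVE")
  expect_error(suppressMessages(filter_categories(small, min_count = 50L)),
               "below min_count")
  expect_error(filter_categories(small[0, ], 50L), "empty")
})

test_that("fold assignment is a true partition with near-equal sizes", {
  for (n in c(20L, 37L, 95L, 100L, 143L, 200L)) {
    fold <- make_folds(n, k = 10L, seed = n)
    expect_length(fold, n)
    sizes <- tabulate(fold, nbins = 10L)
    expect_lte(diff(range(sizes)), 1L)
    expect_identical(sum(sizes), n)
  }
  expect_identical(make_folds(57L, seed = 9L), make_folds(57L, seed = 9L))
})

test_that("stratified folds spread every class across folds", {
  set.seed(61)
  labels <- rep(c("a", "b", "c"), c(60, 30, 10))
  fold <- make_folds(length(labels), k = 10L, labels = labels, seed = 3L)
  sizes <- tabulate(fold, nbins = 10L)
  expect_lte(diff(range(sizes)), 1L)
  for (cl in c("a", "b", "c")) {
    per_fold <- tabulate(fold[labels == cl], nbins = 10L)
    expect_lte(diff(range(per_fold)), 1L)
  }
})

test_that("unknown predictors are rejected with the registry listed", {
  expect_error(predictor_spec("svm"), "registered: gbt")
})

test_that("simple predictors behave on realizable problems", {
  set.seed(62)
  X <- matrix(rnorm(60 * 5), 60, 5)
  beta <- c(1, -2, 0.5, 0, 3)
  y <- as.vector(X %*% beta)
  # ridge on an exactly linear target: near-perfect in-sample fit
  pr <- run_predictor(predictor_spec("ridge", lambda = 1e-4), X, y, X)
  expect_lt(mse(y, pr), 1e-2 * stats::var(y))
  # 1-NN memorizes the training set
  lab <- ifelse(X[, 1] > 0, "hi", "lo")
  pk <- run_predictor(predictor_spec("knn", k = 1L), X, lab, X, "QUALITATIVE")
  expect_identical(pk, lab)
  pkr <- run_predictor(predictor_spec("knn", k = 1L), X, y, X)
  expect_lt(max(abs(pkr - y)), 1e-10)
})

test_that("stochastic predictors are reproducible under a fixed seed", {
  set.seed(63)
  X <- matrix(rnorm(50 * 4), 50, 4)
  y <- rnorm(50)
  Xte <- matrix(rnorm(10 * 4), 10, 4)
  for (name in c("gbt", "random_forest", "extra_trees", "mlp", "cnn")) {
    spec <- predictor_spec(name)
    p1 <- run_predictor(spec, X, y, Xte, seed = 7L)
    p2 <- run_predictor(spec, X, y, Xte, seed = 7L)
    expect_identical(p1, p2)
  }
})

test_that("ten-fold CV partitions once, averages folds, and passes degenerate data through", {
  set.seed(64)
  feats <- tibble::tibble(sample_id = paste0("s", 1:100))
  feats$f1 <- rnorm(100); feats$f2 <- rnorm(100)
  # constant target with a constant-capable predictor: per-fold MSE 0
  targ <- trait_records(feats$sample_id, "t", rep(0.5, 100), "QUANTITATIVE")
  rep_ <- tenfold_cv(feats, targ, predictor_spec("knn", k = 5L), seed = 8L)
  expect_identical(nrow(rep_$fold_metrics), 10L)
  expect_identical(max(rep_$fold_metrics$mse), 0)
  expect_true(all(is.na(rep_$fold_metrics$pcc)))
  expect_equal(rep_$mean_metrics[["mse"]], mean(rep_$fold_metrics$mse), tolerance = 1e-15)
  expect_error(
    tenfold_cv(feats, trait_records("zz", "t", 1, "QUANTITATIVE"),
               predictor_spec("knn")),
    "no overlapping|at least"
  )
})

test_that("per-fold reduction differs from leaky full-data reduction", {
  # constructed leak: one extreme test-fold outlier dominates the principal
  # axis, so fitting the reducer on all data vs the training fold changes
  # the projected features and hence the metrics
  set.seed(65)
  n <- 60L
  X <- matrix(rnorm(n * 6, sd = 1), n, 6)
  X[1, ] <- 50  # outlier sample
  y <- rnorm(n)
  feats <- tibble::tibble(sample_id = paste0("s", 1:n))
  for (j in 1:6) feats[[paste0("f", j)]] <- X[, j]
  targ <- trait_records(feats$sample_id, "t", y, "QUANTITATIVE")
  honest <- tenfold_cv(feats, targ, predictor_spec("knn", k = 3L),
                       seed = 5L, reduce_to = 2L)
  # leaky variant computed directly: reducer fitted on all rows
  leaky_red <- fit_reducer(X, 2L)
  Xl <- apply_reducer(leaky_red, X)
  featsl <- tibble::tibble(sample_id = feats$sample_id)
  featsl$f1 <- Xl[, 1]; featsl$f2 <- Xl[, 2]
  leaky <- tenfold_cv(featsl, targ, predictor_spec("knn", k = 3L), seed = 5L)
  expect_false(isTRUE(all.equal(honest$mean_metrics[["mse"]],
                                leaky$mean_metrics[["mse"]])))
})

test_that("a perfect feature set yields perfect metrics end to end", {
  set.seed(66)
  n <- 100L
  y <- rnorm(n)
  feats <- tibble::tibble(sample_id = paste0("s", 1:n), f1 = y)
  targ <- trait_records(feats$sample_id, "t", y, "QUANTITATIVE")
  rep_ <- tenfold_cv(feats, targ, predictor_spec("knn", k = 1L), seed = 2L)
  expect_lt(rep_$mean_metrics[["mse"]], 1e-3)
  expect_gt(rep_$mean_metrics[["pcc"]], 0.99)
  lab <- ifelse(y > 0, "hi", "lo")
  featc <- tibble::tibble(sample_id = feats$sample_id, f1 = as.numeric(y > 0))
  targc <- trait_records(feats$sample_id, "t", lab, "QUALITATIVE")
  repc <- tenfold_cv(featc, targc, predictor_spec("knn", k = 1L), seed = 2L)
  expect_identical(repc$mean_metrics[["accuracy"]], 1)
})

test_that("tidy and glance expose fold and summary views", {
  set.seed(67)
  feats <- tibble::tibble(sample_id = paste0("s", 1:40), f1 = rnorm(40))
  targ <- trait_records(feats$sample_id, "t", rnorm(40), "QUANTITATIVE")
  rep_ <- tenfold_cv(feats, targ, predictor_spec("knn", k = 3L), seed = 1L)
  td <- tidy(rep_)
  expect_identical(nrow(td), 10L)
  expect_true(all(c("trait_name", "fold", "mse", "mae", "pcc") %in% names(td)))
  gl <- glance(rep_)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$mse, mean(td$mse), tolerance = 1e-15)
  stem <- withr::local_tempfile()
  write_cv_report(rep_, stem)
  js <- jsonlite::read_json(paste0(stem, ".json"))
  expect_equal(js$mean_metrics$mse, rep_$mean_metrics[["mse"]], tolerance = 1e-9)
})
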