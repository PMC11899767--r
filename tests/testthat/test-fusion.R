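test_that("chromosome vectors are window means", {
  v <- c(1, 2, 3)
  expect_identical(chromosome_vector(list(v)), v)
  expect_identical(chromosome_vector(list(v, -v)), c(0, 0, 0))
  set.seed(41)
  M <- matrix(rnorm(100 * 6), 100, 6)
  naive <- rep(0, 6)
  for (i in 1:100) naive <- naive + M[i, ]
  expect_lt(max(abs(chromosome_vector(M) - naive / 100)), 1e-10)
  expect_error(chromosome_vector(list()), "empty")
})

test_that("dimension reduction is the identity at full width and exact on rank-1 data", {
  set.seed(42)
  M <- matrix(rnorm(30 * 8), 30, 8)
  red <- reduce_dim(M, 8L)
  expect_identical(red$values, M)
  expect_identical(red$reducer$kind, "identity")
  # rank-1 matrix: one component reconstructs exactly
  u <- rnorm(30); w <- rnorm(8)
  R1 <- outer(u, w)
  fit <- fit_reducer(R1, 1L)
  scores <- apply_reducer(fit, R1)
  recon <- scores %*% t(fit$rotation) + rep(fit$center, each = 30)
  expect_lt(max(abs(recon - R1)), 1e-8)
  expect_error(fit_reducer(M, 9L), "exceeds")
})

test_that("principal-component scores are uncorrelated on the fitting split", {
  set.seed(43)
  M <- matrix(rnorm(60 * 10), 60, 10) %*% matrix(rnorm(100), 10, 10)
  red <- reduce_dim(M, 4L)
  cv <- stats::cov(red$values)
  off <- cv - diag(diag(cv))
  expect_lt(max(abs(off)), 1e-10)
})

test_that("average fusion is idempotent and permutation-invariant", {
  v <- rnorm(6)
  M <- matrix(rep(v, each = 20), 20, 6)
  expect_equal(fuse_average(M)$values, v, tolerance = 1e-12)
  E <- diag(20)
  expect_equal(fuse_average(E)$values, rep(1 / 20, 20), tolerance = 1e-15)
  set.seed(44)
  M2 <- matrix(rnorm(20 * 6), 20, 6)
  perm <- sample(20)
  expect_equal(fuse_average(M2)$values, fuse_average(M2[perm, ])$values,
               tolerance = 1e-12)
})

test_that("concatenation fusion is order-sensitive with recoverable blocks", {
  set.seed(45)
  n_chrom <- 20L; D <- 512L
  M <- matrix(rnorm(n_chrom * D), n_chrom, D,
              dimnames = list(paste0("chr", sprintf("%02d", 1:n_chrom)), NULL))
  ord <- rownames(M)
  f <- fuse_concat(M, ord)
  expect_length(f$values, 10240L)
  for (k in c(1L, 7L, 20L)) {
    expect_identical(f$values[((k - 1L) * D + 1L):(k * D)], M[ord[k], ])
  }
  ord2 <- ord; ord2[1:2] <- ord2[2:1]
  f2 <- fuse_concat(M, ord2)
  expect_false(identical(f$values, f2$values))
  expect_error(fuse_concat(M, ord[-1]), "exactly once")
  expect_error(fuse_concat(M, c(ord[-1], ord[2])), "exactly once")
})

test_that("when all chromosome vectors agree, averaging equals any concat block", {
  v <- rnorm(5)
  M <- matrix(rep(v, each = 4), 4, 5, dimnames = list(paste0("c", 1:4), NULL))
  avg <- fuse_average(M)$values
  cat_ <- fuse_concat(M, paste0("c", 1:4))$values
  expect_equal(avg, cat_[1:5], tolerance = 1e-15)
})

test_that("fuse_samples honours widths and fusion modes", {
  set.seed(46)
  cvs <- structure(
    list(
      sample_id = rep(c("s1", "s2"), each = 3),
      chrom_id = rep(c("chr1", "chr2", "chr3"), 2),
      values = matrix(rnorm(6 * 8), 6, 8)
    ),
    class = "chrom_vector_set"
  )
  avg <- fuse_samples(cvs, "AVERAGE")
  expect_identical(dim(avg), c(2L, 9L))
  con <- fuse_samples(cvs, "CONCAT")
  expect_identical(dim(con), c(2L, 25L))
  red <- fuse_samples(cvs, "CONCAT", D_vec = 2L)
  expect_identical(dim(red), c(2L, 7L))
  expect_s3_class(attr(red, "reducer"), "dim_reducer")
})

test_that("feature tables round-trip through disk bit-identically", {
  set.seed(47)
  feats <- tibble::tibble(
    sample_id = c("a", "b", "c"),
    f1 = rnorm(3), f2 = rnorm(3) * 1e-13, f3 = rnorm(3) * 1e7
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_features(feats, path)
  back <- read_features(path)
  expect_identical(back$sample_id, feats$sample_id)
  for (cn in c("f1", "f2", "f3")) expect_identical(back[[cn]], feats[[cn]])
})

test_that("chromosome-vector tables round-trip for standalone refusion", {
  set.seed(48)
  cvs <- structure(
    list(
      sample_id = rep("s1", 2), chrom_id = c("chr1", "chr2"),
      values = matrix(rnorm(8), 2, 4)
    ),
    class = "chrom_vector_set"
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_chrom_vectors(cvs, path)
  back <- read_chrom_vectors(path)
  expect_identical(back$sample_id, cvs$sample_id)
  expect_identical(back$chrom_id, cvs$chrom_id)
  expect_identical(unname(back$values), unname(cvs$values))
})
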