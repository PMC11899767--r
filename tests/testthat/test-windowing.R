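test_that("all-sequence tiling has ceiling(len/L_in) windows and exact padding", {
  g <- genome_sequence("s", "chr1", random_dna(10, seed = 3))
  w <- segment_all(g, 4L)
  expect_length(w, 3L)
  expect_identical(w[[3]]$start, 8L)
  expect_identical(w[[3]]$end, 10L)
  expect_identical(sum(w[[3]]$pad_mask), 2L)
  expect_identical(w[[3]]$token_ids[3:4], c(4L, 4L))  # PAD tail

  w8 <- segment_all(genome_sequence("s", "c", random_dna(8, 4)), 4L)
  expect_length(w8, 2L)
  expect_true(all(vapply(w8, function(x) all(x$pad_mask), TRUE)))

  w3 <- segment_all(genome_sequence("s", "c", "ACG"), 4L)
  expect_length(w3, 1L)
  expect_identical(sum(w3[[1]]$pad_mask), 3L)

  expect_identical(segment_all(genome_sequence("s", "c", ""), 4L), list())
})

test_that("tiling reconstructs the chromosome exactly for every length", {
  L <- 8L
  for (len in 1:(3L * L)) {
    g <- genome_sequence("s", "c", random_dna(len, seed = len))
    wins <- segment_all(g, L)
    expect_length(wins, ceiling(len / L))
    rebuilt <- paste(vapply(wins, function(w) {
      detokenize(w$token_ids[w$pad_mask])
    }, ""), collapse = "")
    expect_identical(rebuilt, g$sequence)
  }
})

test_that("SNP windows centre the variant at offset L_in/2", {
  g <- genome_sequence("s", "chr1", random_dna(200, seed = 5))
  s <- variant_site("chr1", 100L, substr(g$sequence, 100, 100), "A")
  w <- snp_windows(g, list(s), 8L)[[1]]
  expect_identical(w$start, 95L)
  expect_identical(w$end, 103L)
  expect_identical(w$anchor_pos, 99L)
  # anchor sits at offset L_in/2 (1-based index 5)
  expect_identical(detokenize(w$token_ids[5]), s$ref_allele)
})

test_that("SNP windows clipped at chromosome edges pad but keep the offset", {
  g <- genome_sequence("s", "chr1", random_dna(20, seed = 6))
  s <- variant_site("chr1", 2L, substr(g$sequence, 2, 2), "A")  # 0-based index 1
  w <- snp_windows(g, list(s), 8L)[[1]]
  expect_identical(w$token_ids[1:3], rep(4L, 3))  # 3 left PADs
  expect_identical(w$pad_mask[1:3], rep(FALSE, 3))
  expect_identical(detokenize(w$token_ids[5]), s$ref_allele)
  # right-edge clipping pads on the right
  s2 <- variant_site("chr1", 20L, substr(g$sequence, 20, 20), "A")
  w2 <- snp_windows(g, list(s2), 8L)[[1]]
  expect_identical(w2$token_ids[6:8], rep(4L, 3))
  expect_identical(detokenize(w2$token_ids[5]), s2$ref_allele)
})

test_that("one window per site, errors outside the chromosome", {
  g <- genome_sequence("s", "chr1", random_dna(500, seed = 7))
  pos <- seq(10L, 490L, by = 7L)
  sites <- lapply(pos, function(p) {
    variant_site("chr1", p, substr(g$sequence, p, p), "A")
  })
  wins <- snp_windows(g, sites, 16L)
  expect_length(wins, length(sites))
  for (i in seq_along(wins)) {
    expect_identical(detokenize(wins[[i]]$token_ids[9]), sites[[i]]$ref_allele)
  }
  bad <- variant_site("chr1", 501L, "A", "C")
  expect_error(snp_windows(g, list(bad), 16L), "chr1:501")
})

test_that("window_stream is deterministic and mode-checked", {
  gs <- list(
    genome_sequence("s", "chr1", random_dna(10, 8)),
    genome_sequence("s", "chr2", random_dna(4, 9))
  )
  w1 <- window_stream(gs, "ALL_SEQUENCE", L_in = 4L)
  expect_length(w1, 4L)  # ceil(10/4) + ceil(4/4)
  expect_identical(w1, window_stream(gs, "ALL_SEQUENCE", L_in = 4L))
  expect_error(window_stream(gs, "SNP_SEQUENCE", L_in = 4L), "requires variant sites")
  sites <- list(
    variant_site("chr1", 3L, substr(gs[[1]]$sequence, 3, 3), "A"),
    variant_site("chr2", 2L, substr(gs[[2]]$sequence, 2, 2), "A")
  )
  expect_length(window_stream(gs, "SNP_SEQUENCE", L_in = 4L, sites = sites), 2L)
})

test_that("window container round-trips and rejects a stale vocabulary hash", {
  g <- genome_sequence("s1", "chr1", random_dna(30, 10))
  wins <- segment_all(g, 8L)
  path <- withr::local_tempfile(fileext = ".win")
  write_windows(wins, path)
  back <- read_windows(path)
  expect_identical(wins, back)
  # corrupt the stored hash
  raw <- readBin(path, "raw", file.size(path))
  raw[13:20] <- charToRaw("deadbeef")
  writeBin(raw, path)
  expect_error(read_windows(path), "hash mismatch")
})

test_that("BED export lists one row per window", {
  g <- genome_sequence("s1", "chr1", random_dna(30, 11))
  wins <- segment_all(g, 8L)
  bed <- withr::local_tempfile(fileext = ".bed")
  windows_to_bed(wins, bed)
  lines <- readLines(bed)
  expect_length(lines, length(wins))
  expect_match(lines[1], "^chr1\t0\t8\t")
})
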