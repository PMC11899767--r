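test_that("tokenize maps bases position-wise and uppercases nothing away", {
  expect_identical(tokenize("ACGT"), c(0L, 2L, 3L, 1L))
  expect_identical(tokenize("ANGT"), c(0L, 6L, 3L, 1L))
  expect_identical(tokenize(""), integer(0))
  # IUPAC ambiguity letters all map to UNK; length always preserved
  expect_identical(tokenize("RYSWKM"), rep(6L, 6))
  expect_length(tokenize(random_dna(501)), 501L)
})

test_that("detokenize inverts tokenize and renders specials", {
  expect_identical(detokenize(c(0L, 2L, 3L, 1L)), "ACGT")
  expect_identical(detokenize(c(4L, 4L)), "--")
  expect_identical(detokenize(integer(0)), "")
  expect_error(detokenize(c(0L, 7L)), "out of range")
  for (seed in 1:20) {
    s <- random_dna(50, seed = seed)
    expect_identical(detokenize(tokenize(s)), s)
  }
})

test_that("FASTA read normalizes case, keeps order, survives a round trip", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", "acgt"), fa)
  g <- read_fasta(fa)
  expect_length(g, 1L)
  expect_identical(g[[1]]$sequence, "ACGT")
  expect_identical(g[[1]]$length, 4L)

  writeLines(character(0), fa)
  expect_identical(read_fasta(fa), list())

  writeLines(c(">a", "ACGTACGTAC", ">b", "ACGTACG"), fa)
  g2 <- read_fasta(fa)
  expect_identical(vapply(g2, `[[`, 0L, "length"), c(10L, 7L))
  expect_identical(vapply(g2, `[[`, "", "chrom_id"), c("a", "b"))

  fa2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(g2, fa2)
  g3 <- read_fasta(fa2, sample_id = g2[[1]]$sample_id)
  expect_identical(g2, g3)
})

test_that("malformed FASTA errors name the offending line", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c("ACGT", ">chr1"), fa)
  expect_error(read_fasta(fa), "line 1")
  expect_error(read_fasta(file.path(tempdir(), "nope.fa")), "no such file")
})

test_that("VCF reading keeps biallelic SNPs and counts skips", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t100\t.\tA\tG\t.\tPASS\t.",
    "chr1\t200\t.\tAT\tA\t.\tPASS\t.",       # indel -> skipped
    "chr1\t300\t.\tC\tG,T\t.\tPASS\t."       # multi-allelic -> skipped
  ), vcf)
  expect_message(sites <- read_variants(vcf), "skipped 2")
  expect_length(sites, 1L)
  expect_identical(sites[[1]]$chrom_id, "chr1")
  expect_identical(sites[[1]]$pos, 100L)
  expect_identical(sites[[1]]$ref_allele, "A")
  expect_identical(sites[[1]]$alt_allele, "G")
  expect_identical(attr(sites, "n_skipped"), 2L)
})

test_that("VCF with no records gives an empty site list", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  ), vcf)
  sites <- read_variants(vcf)
  expect_length(sites, 0L)
  expect_identical(attr(sites, "n_skipped"), 0L)
})

test_that("write_variants emits VCF that reads back identically", {
  sites <- list(
    variant_site("chr1", 5L, "A", "T"),
    variant_site("chr2", 9L, "G", "C")
  )
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_variants(sites, vcf)
  back <- read_variants(vcf)
  expect_identical(length(back), 2L)
  expect_identical(lapply(back, unclass), lapply(sites, unclass))
})
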