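test_that("reference simulation honours composition, determinism and degeneracy", {
  cfg <- sim_config(n_samples = 2, n_chrom = 1, chrom_len = 500,
                    base_composition = c(A = 1, C = 0, G = 0, T = 0),
                    n_sites = 5, n_qtl = 2, seed = 1)
  ref <- simulate_reference(cfg)
  expect_identical(ref[[1]]$sequence, strrep("A", 500))

  cfg2 <- sim_config(n_samples = 2, n_chrom = 1, chrom_len = 100000,
                     base_composition = c(A = 0.4, C = 0.1, G = 0.1, T = 0.4),
                     n_sites = 5, n_qtl = 2, seed = 2)
  ref2 <- simulate_reference(cfg2)
  freq <- table(strsplit(ref2[[1]]$sequence, "")[[1]]) / 100000
  for (b in c("A", "C", "G", "T")) {
    p <- cfg2$base_composition[[b]]
    se <- sqrt(p * (1 - p) / 100000)
    expect_lt(abs(freq[[b]] - p), 3 * se + 1e-9)
  }
  expect_identical(simulate_reference(cfg2)[[1]]$sequence, ref2[[1]]$sequence)
})

test_that("population genomes carry exactly their drawn alleles", {
  cfg <- sim_config(n_samples = 20, n_chrom = 2, chrom_len = 800,
                    n_sites = 30, n_qtl = 5, seed = 3)
  ref <- simulate_reference(cfg)
  pop <- simulate_population(ref, cfg)
  expect_length(pop$sites, 30L)
  expect_identical(dim(pop$genotypes), c(20L, 30L))
  chrom_of <- vapply(pop$sites, `[[`, "", "chrom_id")
  for (si in c(1L, 7L, 20L)) {
    sid <- rownames(pop$genotypes)[si]
    own <- Filter(function(g) g$sample_id == sid, pop$genomes)
    names(own) <- vapply(own, `[[`, "", "chrom_id")
    for (j in seq_along(pop$sites)) {
      s <- pop$sites[[j]]
      base <- substr(own[[s$chrom_id]]$sequence, s$pos, s$pos)
      expected <- if (pop$genotypes[si, j] == 1L) s$alt_allele else s$ref_allele
      expect_identical(base, expected)
    }
  }
  # reference base at each site matches the site record
  for (j in seq_along(pop$sites)) {
    s <- pop$sites[[j]]
    ref_chrom <- Filter(function(g) g$chrom_id == s$chrom_id, ref)[[1]]
    expect_identical(substr(ref_chrom$sequence, s$pos, s$pos), s$ref_allele)
  }
})

test_that("emitted FASTA and VCF reproduce the in-memory objects", {
  cfg <- sim_config(n_samples = 4, n_chrom = 2, chrom_len = 300,
                    n_sites = 10, n_qtl = 2, seed = 4)
  dir <- withr::local_tempdir()
  suppressMessages(write_sim(cfg, dir))
  ref <- simulate_reference(cfg)
  back <- read_fasta(file.path(dir, "reference.fa"), sample_id = "reference")
  expect_identical(ref[[1]]$sequence, back[[1]]$sequence)
  expect_identical(vapply(ref, `[[`, "", "chrom_id"),
                   vapply(back, `[[`, "", "chrom_id"))
  pop <- simulate_population(ref, cfg)
  sites <- read_variants(file.path(dir, "variants.vcf"))
  expect_identical(length(sites), length(pop$sites))
  expect_identical(lapply(sites, unclass), lapply(pop$sites, unclass))
  traits <- read_traits(file.path(dir, "traits.tsv"))
  expect_setequal(unique(traits$trait_name), c("trait_q", "trait_c"))
  # per-sample FASTA matches in-memory genomes
  s1 <- read_fasta(file.path(dir, "samples", "s0001.fa"), sample_id = "s0001")
  own <- Filter(function(g) g$sample_id == "s0001", pop$genomes)
  expect_identical(s1[[1]]$sequence, own[[1]]$sequence)
})

test_that("trait simulation realizes the requested heritability", {
  cfg <- sim_config(n_samples = 2000, n_chrom = 1, chrom_len = 1000,
                    n_sites = 50, n_qtl = 10, h2 = 0.5, seed = 5)
  ref <- simulate_reference(cfg)
  pop <- simulate_population(ref, cfg)
  tr <- simulate_traits(pop$genotypes, cfg)
  q <- tr$records[tr$records$trait_name == "trait_q", ]
  g <- tr$truth$genetic_values
  ratio <- stats::var(g) / stats::var(as.numeric(q$value))
  expect_lt(abs(ratio - 0.5), 0.05)
  # two-class split at the median is balanced
  cl <- tr$records[tr$records$trait_name == "trait_c", ]
  expect_lte(abs(diff(table(cl$value))), 1L)
})

test_that("h2 = 1 gives a noise-free additive trait", {
  cfg <- sim_config(n_samples = 50, n_chrom = 1, chrom_len = 500,
                    n_sites = 20, n_qtl = 5, h2 = 1, seed = 6)
  ref <- simulate_reference(cfg)
  pop <- simulate_population(ref, cfg)
  tr <- simulate_traits(pop$genotypes, cfg)
  q <- as.numeric(tr$records$value[tr$records$trait_name == "trait_q"])
  expect_identical(q, tr$truth$genetic_values)
  Z <- pop$genotypes[, tr$truth$qtl_sites, drop = FALSE]
  resid <- q - as.vector(Z %*% tr$truth$qtl_effects)
  expect_lt(max(abs(resid)), 1e-12)
})

test_that("the generator is deterministic end to end and validates inputs", {
  cfg <- sim_config(n_samples = 5, n_chrom = 1, chrom_len = 200,
                    n_sites = 8, n_qtl = 3, seed = 7)
  r1 <- simulate_reference(cfg); r2 <- simulate_reference(cfg)
  p1 <- simulate_population(r1, cfg); p2 <- simulate_population(r2, cfg)
  t1 <- simulate_traits(p1$genotypes, cfg); t2 <- simulate_traits(p2$genotypes, cfg)
  expect_identical(p1$genotypes, p2$genotypes)
  expect_identical(t1$records$value, t2$records$value)
  expect_error(sim_config(n_qtl = 10, n_sites = 5), "n_qtl")
  expect_error(sim_config(base_composition = c(0.5, 0.5, 0.5, 0.5)), "sum to 1")
})

test_that("a planted motif is inserted and logged", {
  cfg <- sim_config(n_samples = 1, n_chrom = 1, chrom_len = 5000,
                    n_sites = 2, n_qtl = 1,
                    motif = list(oligomer = "TATAAA", rate = 0.002), seed = 8)
  ref <- simulate_reference(cfg)
  pos <- attr(ref, "motif_positions")$chr1
  expect_gt(length(pos), 0L)
  for (p in pos) {
    expect_identical(substr(ref[[1]]$sequence, p, p + 5L), "TATAAA")
  }
})
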