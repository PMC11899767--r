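# Seeded synthetic data: reference genomes, a biallelic variant panel with
# per-sample haploid alleles, and additive QTL traits with a stated
# heritability. Emulates the statistical structure the pipeline assumes
# (one genome sequence per accession, point variants, additive genetics)
# at desk scale, so every stage is testable without external data.

#' Configuration for the synthetic-data generator
#'
#' @param n_samples Population size.
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Chromosome length in bases (recycled to `n_chrom`).
#' @param n_sites Total polymorphic (SNP) sites across the genome.
#' @param n_qtl Number of causal sites (`<= n_sites`).
#' @param base_composition Probabilities for A/C/G/T (sum to 1).
#' @param markov_order 0 (i.i.d. bases) or 1 (first-order Markov chain).
#' @param transition_matrix Row-stochastic 4x4 matrix (A/C/G/T order),
#'   required when `markov_order = 1`.
#' @param allele_freq_range Range the per-site alternate-allele frequency
#'   is drawn from.
#' @param effect_size_sd Standard deviation of the additive QTL effects.
#' @param h2 Narrow-sense heritability of the quantitative trait, in
#'   `[0, 1]`.
#' @param qual_classes Number of classes for the thresholded qualitative
#'   trait (quantile cuts of the genetic value).
#' @param motif Optional list `(oligomer =, rate =)`: a planted oligomer
#'   inserted into the reference at the given per-base rate.
#' @param seed Master seed; all three generator stages derive from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 300L, n_chrom = 2L, chrom_len = 10000L,
                       n_sites = 100L, n_qtl = 20L,
                       base_composition = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       markov_order = 0L, transition_matrix = NULL,
                       allele_freq_range = c(0.1, 0.5),
                       effect_size_sd = 1, h2 = 0.8, qual_classes = 2L,
                       motif = NULL, seed = 1000L) {
  stopifnot(
    n_samples >= 1, n_chrom >= 1, all(chrom_len >= 1),
    n_sites >= 1, n_qtl >= 1, n_qtl <= n_sites,
    length(base_composition) == 4, all(base_composition >= 0),
    markov_order %in% c(0L, 1L),
    h2 >= 0, h2 <= 1, qual_classes >= 2,
    length(allele_freq_range) == 2, allele_freq_range[1] <= allele_freq_range[2],
    allele_freq_range[1] > 0, allele_freq_range[2] < 1
  )
  if (abs(sum(base_composition) - 1) > 1e-8) {
    stop("sim_config(): base_composition must sum to 1")
  }
  if (markov_order == 1L) {
    stopifnot(is.matrix(transition_matrix), all(dim(transition_matrix) == c(4, 4)))
    if (any(abs(rowSums(transition_matrix) - 1) > 1e-8)) {
      stop("sim_config(): transition_matrix rows must sum to 1")
    }
  }
  structure(
    list(
      n_samples = as.integer(n_samples), n_chrom = as.integer(n_chrom),
      chrom_len = as.integer(rep_len(chrom_len, n_chrom)),
      n_sites = as.integer(n_sites), n_qtl = as.integer(n_qtl),
      base_composition = stats::setNames(base_composition, c("A", "C", "G", "T")),
      markov_order = as.integer(markov_order),
      transition_matrix = transition_matrix,
      allele_freq_range = allele_freq_range,
      effect_size_sd = effect_size_sd, h2 = h2,
      qual_classes = as.integer(qual_classes),
      motif = motif, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate reference chromosomes
#'
#' Bases are drawn i.i.d. from the configured composition, or from a
#' first-order Markov chain started at the composition. An optional motif
#' is overwritten into the sequence at seeded positions (logged in the
#' `motif_positions` attribute).
#'
#' @param config A [sim_config()].
#' @return List of [genome_sequence()] (sample id `"reference"`), one per
#'   chromosome, with attribute `motif_positions`.
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  bases <- c("A", "C", "G", "T")
  with_seed(config$seed, {
    motif_log <- list()
    genomes <- lapply(seq_len(config$n_chrom), function(ci) {
      len <- config$chrom_len[ci]
      p <- config$base_composition[bases]
      if (config$markov_order == 0L) {
        seq_i <- sample.int(4, len, replace = TRUE, prob = p)
      } else {
        Tm <- config$transition_matrix
        seq_i <- integer(len)
        seq_i[1] <- sample.int(4, 1, prob = p)
        for (t in 2:len) seq_i[t] <- sample.int(4, 1, prob = Tm[seq_i[t - 1], ])
      }
      s <- paste(bases[seq_i], collapse = "")
      if (!is.null(config$motif)) {
        m <- toupper(config$motif$oligomer)
        k <- nchar(m)
        n_ins <- stats::rbinom(1, max(len - k, 0), config$motif$rate)
        if (n_ins > 0) {
          at <- sort(sample.int(len - k + 1L, n_ins))
          for (a in at) substr(s, a, a + k - 1L) <- m
          motif_log[[paste0("chr", ci)]] <<- at
        }
      }
      genome_sequence("reference", paste0("chr", ci), s)
    })
    attr(genomes, "motif_positions") <- motif_log
    genomes
  })
}

#' Simulate a population of per-sample genomes over a variant panel
#'
#' Polymorphic sites are placed uniformly (without replacement) across the
#' reference chromosomes in proportion to their lengths; each site gets an
#' alternate allele different from the reference base and an alternate
#' allele frequency drawn from the configured range. Each sample carries
#' the alternate allele at a site with that frequency (haploid 0/1
#' dosage), and its chromosome sequences equal the reference with its
#' alternate alleles substituted.
#'
#' @param reference Output of [simulate_reference()].
#' @param config A [sim_config()].
#' @return List with `genomes` (flat list of [genome_sequence()], samples
#'   x chromosomes), `sites` (list of [variant_site()] in genome order),
#'   `genotypes` (0/1 integer matrix `[n_samples x n_sites]` with sample
#'   ids as rownames) and `allele_freq`.
#' @export
simulate_population <- function(reference, config) {
  stopifnot(inherits(config, "sim_config"))
  bases <- c("A", "C", "G", "T")
  lens <- vapply(reference, `[[`, 0L, "length")
  with_seed(config$seed + 1L, {
    # spread sites over chromosomes proportional to length
    alloc <- floor(config$n_sites * lens / sum(lens))
    rem <- config$n_sites - sum(alloc)
    if (rem > 0) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1L
    sites <- list()
    for (ci in seq_along(reference)) {
      if (alloc[ci] == 0L) next
      pos <- sort(sample.int(lens[ci], alloc[ci]))
      refb <- strsplit(reference[[ci]]$sequence, "")[[1]][pos]
      altb <- vapply(refb, function(b) sample(setdiff(bases, b), 1), "",
                     USE.NAMES = FALSE)
      sites <- c(sites, lapply(seq_along(pos), function(j) {
        variant_site(reference[[ci]]$chrom_id, pos[j], refb[j], altb[j])
      }))
    }
    n_sites <- length(sites)
    freq <- stats::runif(n_sites, config$allele_freq_range[1], config$allele_freq_range[2])
    ids <- sprintf("s%04d", seq_len(config$n_samples))
    G <- matrix(0L, config$n_samples, n_sites, dimnames = list(ids, NULL))
    for (j in seq_len(n_sites)) {
      G[, j] <- stats::rbinom(config$n_samples, 1L, freq[j])
    }
    chrom_ids <- vapply(reference, `[[`, "", "chrom_id")
    genomes <- list()
    for (si in seq_along(ids)) {
      for (ci in seq_along(reference)) {
        s <- reference[[ci]]$sequence
        on_chrom <- which(vapply(sites, `[[`, "", "chrom_id") == chrom_ids[ci])
        carried <- on_chrom[G[si, on_chrom] == 1L]
        for (j in carried) {
          p <- sites[[j]]$pos
          substr(s, p, p) <- sites[[j]]$alt_allele
        }
        genomes[[length(genomes) + 1L]] <- genome_sequence(ids[si], chrom_ids[ci], s)
      }
    }
    list(genomes = genomes, sites = sites, genotypes = G, allele_freq = freq)
  })
}

#' Simulate additive traits from a genotype matrix
#'
#' Draws `n_qtl` causal sites and effects, forms the genetic value
#' `g = Z_qtl %*% effects`, and adds Gaussian noise scaled so the realized
#' heritability `Var(g) / Var(g + e)` matches `h2` (no noise at
#' `h2 = 1`). A qualitative trait is derived by cutting `g` at quantiles
#' into `qual_classes` labelled classes.
#'
#' @param genotypes 0/1 dosage matrix from [simulate_population()].
#' @param config A [sim_config()].
#' @return List with `records` (trait table: one quantitative trait
#'   `"trait_q"`, one qualitative trait `"trait_c"`) and `truth`
#'   (`qtl_sites`, `qtl_effects`, `genetic_values`, `noise_var`, `h2`).
#' @export
simulate_traits <- function(genotypes, config) {
  stopifnot(inherits(config, "sim_config"), config$n_qtl <= ncol(genotypes))
  with_seed(config$seed + 2L, {
    qtl <- sort(sample.int(ncol(genotypes), config$n_qtl))
    eff <- stats::rnorm(config$n_qtl, sd = config$effect_size_sd)
    g <- as.vector(genotypes[, qtl, drop = FALSE] %*% eff)
    var_g <- stats::var(g)
    if (config$h2 == 1 && var_g == 0) {
      stop("simulate_traits(): h2 = 1 with zero genetic variance")
    }
    if (config$h2 == 0) {
      noise_var <- 1
      y <- stats::rnorm(length(g), sd = 1)
    } else if (config$h2 == 1) {
      noise_var <- 0
      y <- g
    } else {
      noise_var <- var_g * (1 - config$h2) / config$h2
      y <- g + stats::rnorm(length(g), sd = sqrt(noise_var))
    }
    # quantile split via ranks so tied genetic values still give balanced classes
    r <- rank(g, ties.method = "first")
    cls <- paste0("C", ceiling(r * config$qual_classes / length(g)))
    ids <- rownames(genotypes)
    rq <- trait_records(ids, "trait_q", y, "QUANTITATIVE")
    # the combined table mixes trait types, so values are kept as text at
    # full precision (17 significant digits round-trip doubles exactly)
    rq$value <- sprintf("%.17g", y)
    records <- rbind(rq, trait_records(ids, "trait_c", cls, "QUALITATIVE"))
    list(
      records = records,
      truth = list(
        qtl_sites = qtl, qtl_effects = eff, genetic_values = g,
        noise_var = noise_var, h2 = config$h2
      )
    )
  })
}

#' Write a full synthetic dataset to disk
#'
#' Emits the reference FASTA, one FASTA per sample, a VCF with the variant
#' panel and per-sample haploid genotypes, the trait table and a truth
#' JSON (QTL positions, effects, heritability) for downstream assertions.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a manifest list of the written paths and counts.
#' @export
write_sim <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- simulate_reference(config)
  pop <- simulate_population(ref, config)
  tr <- simulate_traits(pop$genotypes, config)
  write_fasta(ref, file.path(dir, "reference.fa"))
  ids <- rownames(pop$genotypes)
  sample_dir <- file.path(dir, "samples")
  dir.create(sample_dir, showWarnings = FALSE)
  for (s in ids) {
    own <- Filter(function(g) g$sample_id == s, pop$genomes)
    write_fasta(own, file.path(sample_dir, paste0(s, ".fa")))
  }
  write_variants(pop$sites, file.path(dir, "variants.vcf"), genotypes = pop$genotypes)
  write_traits(tr$records, file.path(dir, "traits.tsv"))
  jsonlite::write_json(
    list(
      qtl_sites = tr$truth$qtl_sites, qtl_effects = tr$truth$qtl_effects,
      genetic_values = tr$truth$genetic_values, noise_var = tr$truth$noise_var,
      h2 = tr$truth$h2, seed = config$seed
    ),
    file.path(dir, "truth.json"), digits = NA
  )
  manifest <- list(
    reference = file.path(dir, "reference.fa"),
    samples = length(ids), chromosomes = config$n_chrom,
    sites = length(pop$sites), qtl = config$n_qtl,
    variants = file.path(dir, "variants.vcf"),
    traits = file.path(dir, "traits.tsv"),
    truth = file.path(dir, "truth.json")
  )
  invisible(manifest)
}
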