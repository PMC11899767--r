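#' A single chromosome sequence for one sample
#'
#' @param sample_id Sample identifier.
#' @param chrom_id Chromosome identifier (non-empty).
#' @param sequence Nucleotide string; uppercased on construction.
#' @return An object of class `genome_sequence` with fields `sample_id`,
#'   `chrom_id`, `sequence` and `length`.
#' @export
genome_sequence <- function(sample_id, chrom_id, sequence) {
  stopifnot(is.character(chrom_id), nzchar(chrom_id), is.character(sequence))
  sequence <- toupper(sequence)
  structure(
    list(
      sample_id = as.character(sample_id),
      chrom_id = as.character(chrom_id),
      sequence = sequence,
      length = nchar(sequence)
    ),
    class = "genome_sequence"
  )
}

#' @export
print.genome_sequence <- function(x, ...) {
  head <- substr(x$sequence, 1L, 40L)
  if (x$length > 40L) head <- paste0(head, "...")
  cat(sprintf(
    "<genome_sequence> sample=%s chrom=%s length=%d\n  %s\n",
    x$sample_id, x$chrom_id, x$length, head
  ))
  invisible(x)
}

#' A biallelic variant site
#'
#' Positions are 1-based on the chromosome, as in VCF; internal window
#' arithmetic converts to 0-based half-open coordinates on ingest.
#'
#' @param chrom_id Chromosome identifier.
#' @param pos 1-based position.
#' @param ref_allele,alt_allele Single bases in `A`, `C`, `G`, `T`.
#' @return An object of class `variant_site`.
#' @export
variant_site <- function(chrom_id, pos, ref_allele, alt_allele) {
  stopifnot(
    is.character(chrom_id), nzchar(chrom_id),
    pos >= 1, pos == as.integer(pos),
    ref_allele %in% c("A", "C", "G", "T"),
    alt_allele %in% c("A", "C", "G", "T")
  )
  structure(
    list(
      chrom_id = as.character(chrom_id),
      pos = as.integer(pos),
      ref_allele = ref_allele,
      alt_allele = alt_allele
    ),
    class = "variant_site"
  )
}

#' Read genome sequences from a FASTA file
#'
#' One `genome_sequence` per record, in file order, with sequences
#' uppercased (soft-masked lowercase runs are kept as ordinary bases, not
#' mapped to UNK). Record names are taken as chromosome ids.
#'
#' @param path FASTA file (wrapped or unwrapped lines).
#' @param sample_id Sample identifier attached to every record; defaults to
#'   the file name without extension.
#' @return List of [genome_sequence()] objects.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgt"), fa)
#' read_fasta(fa)[[1]]$sequence  # "ACGT"
#' @export
read_fasta <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("read_fasta(): no such file: ", path)
  if (is.null(sample_id)) {
    sample_id <- tools::file_path_sans_ext(basename(path))
  }
  # light structural check so malformed input names the offending line
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) return(list())
  if (!startsWith(lines[nonempty[1]], ">")) {
    stop(
      "read_fasta(): malformed FASTA at line ", nonempty[1],
      ": expected '>' header, got: ", substr(lines[nonempty[1]], 1, 30)
    )
  }
  set <- Biostrings::readBStringSet(path)
  lapply(seq_along(set), function(i) {
    genome_sequence(
      sample_id = sample_id,
      # keep only the first word of the header, as aligners do
      chrom_id = strsplit(names(set)[i], "\\s+")[[1]][1],
      sequence = as.character(set[[i]])
    )
  })
}

#' Write genome sequences to a FASTA file
#'
#' @param genomes List of [genome_sequence()] objects.
#' @param path Output file.
#' @param width Line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genomes, path, width = 70L) {
  set <- Biostrings::BStringSet(vapply(genomes, `[[`, "", "sequence"))
  names(set) <- vapply(genomes, `[[`, "", "chrom_id")
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read biallelic SNP sites from a VCF file
#'
#' Keeps one [variant_site()] per biallelic SNP record; multi-allelic
#' records and indels are skipped and the skip count reported via
#' `message()` and the `n_skipped` attribute.
#'
#' @param path A VCF (v4.x) file, plain text or bgzipped.
#' @return List of [variant_site()] with attribute `n_skipped`.
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) stop("read_variants(): no such file: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) {
    out <- list()
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  ref <- toupper(fix[, "REF"])
  alt <- toupper(fix[, "ALT"])
  snp <- ref %in% c("A", "C", "G", "T") &
    alt %in% c("A", "C", "G", "T") &
    !grepl(",", alt, fixed = TRUE)
  n_skipped <- sum(!snp)
  if (n_skipped > 0L) {
    message("read_variants(): skipped ", n_skipped, " non-biallelic-SNP record(s)")
  }
  keep <- which(snp)
  out <- lapply(keep, function(i) {
    variant_site(fix[i, "CHROM"], as.integer(fix[i, "POS"]), ref[i], alt[i])
  })
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write variant sites (and optional genotypes) as VCF
#'
#' Emits a minimal VCF v4.2 with GT columns when a genotype matrix is
#' supplied (haploid calls: 0 = reference allele, 1 = alternate allele).
#'
#' @param sites List of [variant_site()].
#' @param path Output file.
#' @param genotypes Optional integer matrix `[n_samples x n_sites]` of 0/1
#'   dosages; row names are sample ids.
#' @return `path`, invisibly.
#' @export
write_variants <- function(sites, path, genotypes = NULL) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=genolm",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  )
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (!is.null(genotypes)) {
    stopifnot(ncol(genotypes) == length(sites), !is.null(rownames(genotypes)))
    cols <- c(cols, "FORMAT", rownames(genotypes))
  }
  rows <- vapply(seq_along(sites), function(i) {
    s <- sites[[i]]
    base <- paste(
      s$chrom_id, s$pos, paste0("site", i), s$ref_allele, s$alt_allele,
      ".", "PASS", ".",
      sep = "\t"
    )
    if (is.null(genotypes)) return(base)
    paste(base, "GT", paste(genotypes[, i], collapse = "\t"), sep = "\t")
  }, "")
  writeLines(c(header, paste(cols, collapse = "\t"), rows), path)
  invisible(path)
}
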