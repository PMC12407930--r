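## Synthetic-data generators: coding sequences and reference-contig + VCF
## pairs that make every simulation mode testable without downloads. All
## generators are deterministic given their seed (Mersenne-Twister through
## R's RNG, state restored on exit).

.sample_sense_codon <- function(base_freqs) {
  repeat {
    codon <- paste(sample(DNA_BASES4, 3L, replace = TRUE, prob = base_freqs),
                   collapse = "")
    if (translate_codon(codon) != "*") return(codon)
  }
}

#' Generate a synthetic coding sequence
#'
#' Emits ATG, then `n_codons` sense codons drawn base-wise from `base_freqs`
#' (stop codons rejected and resampled), then one uniformly chosen stop
#' codon. The result always has a clean reading frame starting at offset 0
#' with no internal stop.
#'
#' @param n_codons Number of sense codons between start and stop (>= 1).
#' @param base_freqs Frequencies over (T, C, A, G), non-negative, summing
#'   to 1. Default uniform.
#' @param seed Integer seed; identical specs yield identical sequences.
#' @return A single DNA string of length `3 * (n_codons + 2)`.
#' @examples
#' generate_cds(n_codons = 5, seed = 7)
#' @export
generate_cds <- function(n_codons, base_freqs = rep(0.25, 4), seed = 1L) {
  if (!is.numeric(n_codons) || length(n_codons) != 1L || n_codons < 1)
    dnds_parameter_error("'n_codons' must be a positive integer")
  base_freqs <- .check_pi(base_freqs)
  withr::with_seed(as.integer(seed), {
    body <- vapply(seq_len(as.integer(n_codons)),
                   function(i) .sample_sense_codon(base_freqs), "")
    stop_codon <- sample(c("TAA", "TAG", "TGA"), 1L)
    paste0("ATG", paste(body, collapse = ""), stop_codon)
  })
}

#' Generate a synthetic reference contig and matching VCF
#'
#' Builds one contig of i.i.d. uniform bases and `n_variants` SNV records at
#' distinct 1-based positions at least three bases from both contig ends
#' (so every frame index has complete flanks). Each record's REF matches the
#' contig base and ALT is drawn uniformly from the other three bases. The
#' VCF carries a minimal 4.2 header and 8 columns with INFO ".".
#'
#' @param n_variants Number of variant records (>= 1).
#' @param contig_length Contig length in bases; must allow `n_variants`
#'   distinct interior positions.
#' @param seed Integer seed.
#' @param contig Contig name.
#' @return A list: `reference` (named character vector, one contig), `fasta`
#'   (FASTA text, one string), `vcf` (VCF text, one string), `variants`
#'   (data.frame with `chrom`, `pos`, `ref`, `alt`).
#' @examples
#' fx <- generate_reference_and_vcf(n_variants = 5, contig_length = 100, seed = 3)
#' @export
generate_reference_and_vcf <- function(n_variants, contig_length, seed = 1L,
                                       contig = "chr1") {
  if (!is.numeric(n_variants) || length(n_variants) != 1L || n_variants < 1)
    dnds_parameter_error("'n_variants' must be a positive integer")
  n_variants <- as.integer(n_variants)
  contig_length <- as.integer(contig_length)
  lo <- 4L; hi <- contig_length - 3L
  if (hi - lo + 1L < n_variants)
    dnds_parameter_error("'contig_length' too short for 'n_variants' interior positions")
  withr::with_seed(as.integer(seed), {
    seq_chars <- sample(DNA_BASES4, contig_length, replace = TRUE)
    contig_seq <- paste(seq_chars, collapse = "")
    pos <- sort(sample(lo:hi, n_variants, replace = FALSE))
    ref <- seq_chars[pos]
    alt <- unname(vapply(ref, function(r) sample(setdiff(DNA_BASES4, r), 1L), ""))
  })
  reference <- stats::setNames(contig_seq, contig)
  fasta <- paste(c(paste0(">", contig),
                   substring(contig_seq, seq(1L, contig_length, 60L),
                             pmin(seq(1L, contig_length, 60L) + 59L, contig_length))),
                 collapse = "\n")
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s,length=%d>", contig, contig_length),
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.", contig, pos, ref, alt)
  list(reference = reference,
       fasta = paste0(fasta, "\n"),
       vcf = paste0(paste(c(header, rows), collapse = "\n"), "\n"),
       variants = data.frame(chrom = contig, pos = pos, ref = ref, alt = alt,
                             stringsAsFactors = FALSE))
}
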