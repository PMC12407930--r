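# Independent oracles used across the suite. These deliberately avoid the
# package's codon tables: translation goes through seqinr and everything is
# enumerated from first principles.

BASES <- c("T", "C", "A", "G")

oracle_translate <- function(codon) {
  toupper(seqinr::translate(strsplit(codon, "")[[1]]))
}

# Brute-force fractional site counts over all 9 single-base changes; each
# alternative weighs 1/3, stop-producing changes are excluded.
oracle_count_sites <- function(codon) {
  aa0 <- oracle_translate(codon)
  stopifnot(aa0 != "*")
  n <- 0; s <- 0
  for (p in 1:3) {
    ref <- substr(codon, p, p)
    for (b in setdiff(BASES, ref)) {
      mut <- codon
      substr(mut, p, p) <- b
      aam <- oracle_translate(mut)
      if (aam == "*") next
      if (aam == aa0) s <- s + 1 / 3 else n <- n + 1 / 3
    }
  }
  c(N = n, S = s)
}

# Brute-force classification of one change.
oracle_classify <- function(codon, pos0, alt) {
  mut <- codon
  substr(mut, pos0 + 1, pos0 + 1) <- alt
  aam <- oracle_translate(mut)
  if (aam == "*") return("nonsense")
  if (aam == oracle_translate(codon)) "synonymous" else "missense"
}

all_codons_oracle <- function() {
  g <- expand.grid(p3 = BASES, p2 = BASES, p1 = BASES, stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
}

sense_codons_oracle <- function() {
  cods <- all_codons_oracle()
  cods[vapply(cods, oracle_translate, "") != "*"]
}

# Write a small VCF body with the given data rows under a minimal header.
write_test_vcf <- function(rows, path, contig = "chr1", length = 100L) {
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", contig, length),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               rows), path)
  path
}
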