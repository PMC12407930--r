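## FASTA / BED / VCF input-output. Parsing goes through Biostrings and
## IRanges; the writers emit the minimal plain-text forms the simulators
## consume (FASTA wrapped at 60 columns, minimal 8-column VCF 4.2, BED3).

IUPAC_CODES <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-")

#' Read a FASTA file
#'
#' Sequences are uppercased and U is mapped to T; record order is preserved.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped lines).
#' @return Named character vector of sequences (names are the FASTA
#'   identifiers, first whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) dnds_input_error(sprintf("FASTA file not found: %s", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) dnds_input_error(
                    sprintf("failed to parse FASTA '%s': %s", path, conditionMessage(e))))
  if (length(set) == 0L)
    dnds_empty_error(sprintf("FASTA file '%s' contains no records", path))
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  for (i in seq_along(seqs)) {
    bad <- setdiff(unique(strsplit(seqs[[i]], "")[[1]]), IUPAC_CODES)
    if (length(bad))
      dnds_input_error(sprintf(
        "record '%s' contains characters outside the IUPAC codes: %s",
        names(seqs)[i], paste(bad, collapse = ", ")))
  }
  chartr("U", "T", seqs)
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path. Lines are wrapped at 60 columns.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path, width = 60L)
  invisible(path)
}

#' Read a BED file of regions
#'
#' Reads the first three tab-separated columns as 0-based half-open
#' intervals, then sorts and merges overlapping or adjacent intervals per
#' contig.
#'
#' @param path Path to a BED3+ file.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), sorted and merged.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) dnds_input_error(sprintf("BED file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0L) dnds_empty_error(sprintf("BED file '%s' has no regions", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L))
    dnds_input_error(sprintf("BED line %d has fewer than 3 tab-separated columns",
                             which(lengths(parts) < 3L)[1]))
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end))
    dnds_input_error("BED start/end columns must be integers")
  bad <- which(start >= end)
  if (length(bad))
    dnds_input_error(sprintf("invalid region on BED line %d: start >= end", bad[1]))
  out <- do.call(rbind, lapply(split(seq_along(chrom), chrom), function(ii) {
    ir <- IRanges::reduce(IRanges::IRanges(start = start[ii] + 1L, end = end[ii]))
    data.frame(chrom = chrom[ii][1],
               start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  }))
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}
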