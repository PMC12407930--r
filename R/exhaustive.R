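## Exhaustive mode: codon-incrementing scan of a coding sequence that
## enumerates every single-base change, aggregates model-weighted mutation
## tallies and uniform site counts, and reports dN/dS.

.check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    dnds_input_error("sequence must be a single non-empty string")
  sequence <- toupper(chartr("U", "T", sequence))
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(chars), DNA_BASES4)
  if (length(bad))
    dnds_input_error(sprintf("sequence contains invalid bases: %s",
                             paste(bad, collapse = ", ")))
  sequence
}

#' Locate the reading frame of a coding sequence
#'
#' The scan starts at the first occurrence of ATG anywhere in the sequence
#' (or at offset 0 with `assume_in_frame = TRUE`, for pre-trimmed CDS). Codons
#' are read in-frame from there; scanning stops at (and excludes) the first
#' in-frame stop codon, or at the last complete codon when no stop occurs. A
#' trailing partial codon is dropped.
#'
#' @param sequence A DNA sequence string (T/C/A/G; U accepted and mapped to T).
#' @param assume_in_frame Skip the ATG search and read from base 0.
#' @return A list: `frame_start` (0-based offset of the first scanned codon),
#'   `codons` (character vector of in-frame sense codons), `codon_starts`
#'   (0-based start of each codon), `stopped_at` (0-based offset of the
#'   terminating stop codon, or `NA`).
#' @examples
#' locate_reading_frame("CCATGAAATGA")  # frame_start 2, codons ATG, AAA
#' @export
locate_reading_frame <- function(sequence, assume_in_frame = FALSE) {
  sequence <- .check_sequence(sequence)
  if (assume_in_frame) {
    fs <- 0L
  } else {
    fs <- as.integer(regexpr("ATG", sequence, fixed = TRUE)) - 1L
    if (fs < 0L)
      dnds_input_error("no start codon (ATG) found in sequence; use assume_in_frame for pre-trimmed CDS")
  }
  n <- nchar(sequence)
  if (fs > n - 3L)
    dnds_empty_error("no complete codon downstream of the start position")
  starts <- seq.int(fs, n - 3L, by = 3L)
  codons <- substring(sequence, starts + 1L, starts + 3L)
  aa <- codon_tables()$aa[match(codons, codon_tables()$codons)]
  stopped_at <- NA_integer_
  first_stop <- which(aa == "*")[1]
  if (!is.na(first_stop)) {
    stopped_at <- starts[first_stop]
    if (first_stop < length(codons) && !is.na(stopped_at))
      warning(sprintf("scan truncated at in-frame stop codon at 0-based offset %d (%d codons retained)",
                      stopped_at, first_stop - 1L), call. = FALSE)
    codons <- codons[seq_len(first_stop - 1L)]
    starts <- starts[seq_len(first_stop - 1L)]
  }
  if (length(codons) == 0L)
    dnds_empty_error("no sense codons to scan after frame trimming")
  list(frame_start = fs, codons = codons, codon_starts = as.integer(starts),
       stopped_at = stopped_at)
}

## Restrict codons to those whose 3 bases all fall inside the (merged)
## regions for the given contig/record name. Straddling codons are dropped.
.restrict_codons <- function(frame, regions, id) {
  reg <- regions[regions$chrom == id, , drop = FALSE]
  if (nrow(reg) == 0L) return(integer(0))
  keep <- vapply(frame$codon_starts, function(s) {
    any(reg$start <= s & (s + 3L) <= reg$end)
  }, logical(1))
  n_straddle <- sum(!keep & vapply(frame$codon_starts, function(s) {
    any(reg$start < (s + 3L) & s < reg$end)
  }, logical(1)))
  if (n_straddle > 0L)
    message(sprintf("%d codon(s) straddling a region boundary were skipped", n_straddle))
  which(keep)
}

#' Exhaustive model-weighted scan of a coding sequence
#'
#' For each in-frame sense codon (optionally restricted to codons fully
#' contained in a region), accumulates the uniform fractional site counts
#' ([count_sites()]) and the model-weighted mutation tallies
#' ([weighted_mutation_counts()]), and computes dN/dS from the aggregates.
#'
#' @inheritParams locate_reading_frame
#' @param model A `substitution_model`.
#' @param regions Optional `data.frame` with columns `chrom`, `start`, `end`
#'   (0-based half-open, as from [read_bed()]); codons with any base outside
#'   every region are skipped.
#' @param id Record identifier; matched against `regions$chrom`.
#' @return A list of class `exhaustive_scan`: `per_codon` (data.frame with
#'   codon index, codon, N, S, n_N, n_S), `sites` (`n_sites`, `s_sites`),
#'   `mutations` (`n_nonsyn`, `n_syn`), `dnds` (see [compute_dnds()]),
#'   `frame_start`, `model_name`.
#' @examples
#' exhaustive_scan("ATGTTTTAA", build_model("JC69"))
#' @export
exhaustive_scan <- function(sequence, model, regions = NULL, id = "seq",
                            assume_in_frame = FALSE) {
  .check_model(model)
  frame <- locate_reading_frame(sequence, assume_in_frame = assume_in_frame)
  idx <- seq_along(frame$codons)
  if (!is.null(regions)) {
    idx <- .restrict_codons(frame, regions, id)
    if (length(idx) == 0L)
      dnds_empty_error("region restriction excludes every codon in the scan")
  }
  codons <- frame$codons[idx]
  tbl <- codon_tables()
  wt <- model_weight_table(model)
  ci <- match(codons, tbl$codons)
  per_codon <- data.frame(
    index = idx,
    start = frame$codon_starts[idx],
    codon = codons,
    n_sites = rowSums(tbl$site_n)[ci],
    s_sites = rowSums(tbl$site_s)[ci],
    n_nonsyn = wt$n_nonsyn[ci],
    n_syn = wt$n_syn[ci],
    row.names = NULL
  )
  sites <- list(n_sites = sum(per_codon$n_sites),
                s_sites = sum(per_codon$s_sites))
  mutations <- list(n_nonsyn = sum(per_codon$n_nonsyn),
                    n_syn = sum(per_codon$n_syn))
  structure(
    list(per_codon = per_codon, sites = sites, mutations = mutations,
         dnds = compute_dnds(sites, mutations),
         frame_start = frame$frame_start, model_name = model$name, id = id),
    class = "exhaustive_scan"
  )
}

#' @method print exhaustive_scan
#' @export
print.exhaustive_scan <- function(x, ...) {
  cat(sprintf("<exhaustive_scan> %s | model %s | %d codons\n",
              x$id, x$model_name, nrow(x$per_codon)))
  cat(sprintf("  N = %.4f  S = %.4f  n_N = %.4f  n_S = %.4f\n",
              x$sites$n_sites, x$sites$s_sites,
              x$mutations$n_nonsyn, x$mutations$n_syn))
  d <- x$dnds
  cat(sprintf("  dN = %s  dS = %s  omega = %s%s\n",
              format(d$d_n), format(d$d_s), format(d$omega),
              if (d$degenerate) "  [degenerate]" else ""))
  invisible(x)
}

#' Compute dN, dS and omega from aggregate counts
#'
#' `dN = n_N / N`, `dS = n_S / S`, `omega = dN / dS`. Degenerate denominators
#' (S = 0, N = 0, or n_S = 0) set `degenerate` and leave `omega` undefined
#' (`NA`) rather than raising an error.
#'
#' @param sites List with `n_sites` (N) and `s_sites` (S).
#' @param mutations List with `n_nonsyn` (n_N) and `n_syn` (n_S).
#' @return A list of class `dnds_result`: `d_n`, `d_s`, `omega`,
#'   `degenerate` (logical).
#' @examples
#' compute_dnds(list(n_sites = 17/3, s_sites = 1/3),
#'              list(n_nonsyn = 16/3, n_syn = 2/3))  # omega = 8/17
#' @export
compute_dnds <- function(sites, mutations) {
  N <- sites$n_sites; S <- sites$s_sites
  nN <- mutations$n_nonsyn; nS <- mutations$n_syn
  degenerate <- (S == 0 || N == 0 || nS == 0)
  d_n <- if (N > 0) nN / N else NA_real_
  d_s <- if (S > 0) nS / S else NA_real_
  omega <- if (!is.na(d_s) && d_s > 0 && !is.na(d_n)) d_n / d_s else NA_real_
  structure(list(d_n = d_n, d_s = d_s, omega = omega, degenerate = degenerate),
            class = "dnds_result")
}

#' Scan every record of a FASTA file and pool
#'
#' Each record is scanned independently; a pooled result sums the per-record
#' aggregates (aggregation is linear in codons).
#'
#' @param fasta Path to a FASTA file of protein-coding sequences.
#' @param model A `substitution_model`.
#' @param regions Optional region `data.frame` (see [read_bed()]).
#' @param assume_in_frame Read each record from base 0 without searching for ATG.
#' @return List with `per_record` (named list of `exhaustive_scan`) and
#'   `pooled` (sites, mutations, dnds over all records).
#' @export
scan_fasta <- function(fasta, model, regions = NULL, assume_in_frame = FALSE) {
  seqs <- read_fasta(fasta)
  scans <- vector("list", length(seqs))
  names(scans) <- names(seqs)
  for (i in seq_along(seqs)) {
    scans[[i]] <- exhaustive_scan(seqs[[i]], model, regions = regions,
                                  id = names(seqs)[i],
                                  assume_in_frame = assume_in_frame)
  }
  sites <- list(
    n_sites = sum(vapply(scans, function(s) s$sites$n_sites, 0)),
    s_sites = sum(vapply(scans, function(s) s$sites$s_sites, 0)))
  mutations <- list(
    n_nonsyn = sum(vapply(scans, function(s) s$mutations$n_nonsyn, 0)),
    n_syn = sum(vapply(scans, function(s) s$mutations$n_syn, 0)))
  list(per_record = scans,
       pooled = list(sites = sites, mutations = mutations,
                     dnds = compute_dnds(sites, mutations)))
}
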