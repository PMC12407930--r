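## Context mode: for each VCF variant, build a codon from the reference
## flanking bases with the variant at a random codon position, draw one
## mutation from the substitution model, classify it, and aggregate
## replicate-level null dN/dS values.

.check_reference <- function(reference) {
  if (is.character(reference) && length(reference) >= 1L && !is.null(names(reference)))
    return(reference)
  dnds_input_error("'reference' must be a named character vector of contig sequences (see read_fasta)")
}

#' Load usable SNVs from a VCF against a reference
#'
#' Keeps biallelic single-nucleotide variants whose REF allele matches the
#' reference base at (CHROM, POS). Indels, multiallelic records, records with
#' symbolic alleles, and REF/reference mismatches are skipped and counted by
#' category. Only CHROM, POS, REF and ALT are consulted.
#'
#' @param vcf Path to a VCF file (plain or bgzip/gzip compressed).
#' @param reference Named character vector of contig sequences, as returned
#'   by [read_fasta()].
#' @return A list: `variants` (data.frame with `chrom`, `pos` (1-based),
#'   `ref`, `alt`), `skipped` (named integer vector of skip counts by
#'   category), `n_records` (total VCF data rows).
#' @export
load_variants <- function(vcf, reference) {
  reference <- .check_reference(reference)
  if (!file.exists(vcf)) dnds_input_error(sprintf("VCF file not found: %s", vcf))
  v <- tryCatch(
    suppressWarnings(vcfR::read.vcfR(vcf, verbose = FALSE)),
    error = function(e) dnds_input_error(sprintf("failed to parse VCF '%s': %s",
                                                 vcf, conditionMessage(e))))
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0L)
    dnds_empty_error("VCF contains no variant records")
  chrom <- as.character(fix[, "CHROM"])
  pos <- as.integer(fix[, "POS"])
  ref <- toupper(as.character(fix[, "REF"]))
  alt <- toupper(as.character(fix[, "ALT"]))
  alt[is.na(alt)] <- "."

  missing_contig <- setdiff(unique(chrom), names(reference))
  if (length(missing_contig))
    dnds_input_error(sprintf("contig '%s' named in VCF is absent from the reference FASTA",
                             missing_contig[1]))

  skipped <- c(multiallelic = 0L, symbolic = 0L, indel = 0L, ref_mismatch = 0L)
  is_multi <- grepl(",", alt, fixed = TRUE)
  is_symbolic <- !is_multi & (grepl("[][<>*]", alt) | alt == "." | ref == ".")
  is_indel <- !is_multi & !is_symbolic & (nchar(ref) != 1L | nchar(alt) != 1L)
  is_snv <- !is_multi & !is_symbolic & !is_indel &
    ref %in% DNA_BASES4 & alt %in% DNA_BASES4
  # non-ACGT single-base alleles (e.g. N) are counted with symbolic records
  is_symbolic <- is_symbolic | (!is_multi & !is_indel & !is_symbolic & !is_snv)

  ref_at <- rep(NA_character_, length(pos))
  ok_pos <- is_snv & pos >= 1L &
    pos <= nchar(reference)[match(chrom, names(reference))]
  ref_at[ok_pos] <- substring(reference[chrom[ok_pos]], pos[ok_pos], pos[ok_pos])
  is_mismatch <- is_snv & (!ok_pos | ref_at != ref)
  keep <- is_snv & !is_mismatch

  skipped["multiallelic"] <- sum(is_multi)
  skipped["symbolic"] <- sum(is_symbolic)
  skipped["indel"] <- sum(is_indel)
  skipped["ref_mismatch"] <- sum(is_mismatch)

  if (!any(keep))
    dnds_empty_error("no usable biallelic SNVs remain after filtering the VCF")
  list(variants = data.frame(chrom = chrom[keep], pos = pos[keep],
                             ref = ref[keep], alt = alt[keep],
                             stringsAsFactors = FALSE),
       skipped = skipped, n_records = length(pos))
}

#' Build a context codon around a variant
#'
#' Places the variant's reference base at `frame_index` within a codon whose
#' remaining bases are the immediately adjacent reference bases:
#' frame 0 gives (ref, +1, +2), frame 1 gives (-1, ref, +1), frame 2 gives
#' (-2, -1, ref), offsets in reference coordinates.
#'
#' @param reference Named character vector of contig sequences.
#' @param variant One-row data.frame (or list) with `chrom`, `pos` (1-based),
#'   `ref`.
#' @param frame_index Position of the variant base within the codon (0, 1, 2).
#' @return A list of class `context_codon`: `codon`, `frame_index`, `chrom`,
#'   `pos`. Flanks past the contig end raise an out-of-bounds input error;
#'   ambiguity codes in a flank raise an ambiguous-flank input error.
#' @examples
#' ref <- c(chr1 = "TACGATTGCA")
#' build_context_codon(ref, list(chrom = "chr1", pos = 5, ref = "A"), 1)
#' @export
build_context_codon <- function(reference, variant, frame_index) {
  reference <- .check_reference(reference)
  if (!frame_index %in% 0:2)
    dnds_parameter_error("'frame_index' must be 0, 1, or 2")
  chrom <- as.character(variant$chrom); pos <- as.integer(variant$pos)
  if (!chrom %in% names(reference))
    dnds_input_error(sprintf("contig '%s' absent from reference", chrom))
  contig <- reference[[chrom]]
  start <- pos - frame_index
  if (start < 1L || start + 2L > nchar(contig))
    dnds_input_error(sprintf("flank out of bounds for variant %s:%d at frame %d",
                             chrom, pos, frame_index))
  codon <- substring(contig, start, start + 2L)
  if (!all(strsplit(codon, "")[[1]] %in% DNA_BASES4))
    dnds_input_error(sprintf("ambiguous flank base near %s:%d", chrom, pos))
  if (!is.null(variant$ref) &&
      substring(codon, frame_index + 1L, frame_index + 1L) != variant$ref)
    dnds_input_error(sprintf("reference base mismatch at %s:%d", chrom, pos))
  structure(list(codon = codon, frame_index = as.integer(frame_index),
                 chrom = chrom, pos = pos),
            class = "context_codon")
}

#' Mutate a context codon once under the model
#'
#' Draws an alternative base for the variant position from
#' [sample_substitution()] and classifies the resulting codon change.
#'
#' @param context A `context_codon` (must be a sense codon).
#' @param model A `substitution_model`.
#' @return List with `class` (`"synonymous"`, `"missense"`, `"nonsense"`) and
#'   `alt` (the drawn base).
#' @export
simulate_variant <- function(context, model) {
  if (!inherits(context, "context_codon"))
    dnds_parameter_error("'context' must be a context_codon (see build_context_codon)")
  if (translate_codon(context$codon) == "*")
    dnds_input_error(sprintf("context codon '%s' is a stop codon", context$codon))
  ref <- substring(context$codon, context$frame_index + 1L, context$frame_index + 1L)
  alt <- sample_substitution(model, ref)
  list(class = classify_change(context$codon, context$frame_index, alt), alt = alt)
}

## Precompute, per variant, the three possible context codons (one per frame
## index) as indices into the 64-codon table; NA marks frames skipped for
## out-of-bounds, ambiguous-flank, or stop-codon contexts. Shared by the
## simulator and the analytic oracle.
context_precompute <- function(variants, reference) {
  reference <- .check_reference(reference)
  tbl <- codon_tables()
  n <- nrow(variants)
  ctx <- matrix(NA_integer_, n, 3L)
  contig <- reference[variants$chrom]
  clen <- nchar(contig)
  for (f in 0:2) {
    start <- variants$pos - f
    ok <- start >= 1L & (start + 2L) <= clen
    codon <- rep(NA_character_, n)
    codon[ok] <- substring(contig[ok], start[ok], start[ok] + 2L)
    ci <- match(codon, tbl$codons)          # NA for ambiguity codes
    ci[!is.na(ci) & tbl$aa[ci] == "*"] <- NA_integer_
    ctx[, f + 1L] <- ci
  }
  ref_idx <- match(variants$ref, DNA_BASES4)
  if (anyNA(ref_idx))
    dnds_input_error("variant reference alleles must be one of T, C, A, G")
  list(ctx = ctx, ref_idx = ref_idx, n = n)
}

## One replicate given precomputed contexts. Site counts cover the variant
## position only (uniform 1/3 per alternative, stop-producing changes
## excluded); exactly one mutation is drawn per usable variant and adds
## weight 1 to n_N or n_S by its class (nonsense draws add nothing).
.replicate_counts <- function(pre, P) {
  tbl <- codon_tables()
  n <- pre$n
  f <- sample.int(3L, n, replace = TRUE)           # frame_index + 1
  ci <- pre$ctx[cbind(seq_len(n), f)]
  keep <- which(!is.na(ci))
  n_skipped <- n - length(keep)
  if (length(keep) == 0L)
    return(list(n_sites = 0, s_sites = 0, n_nonsyn = 0, n_syn = 0,
                n_used = 0L, n_skipped = n_skipped))
  ciu <- ci[keep]; fu <- f[keep]
  N <- sum(tbl$site_n[cbind(ciu, fu)])
  S <- sum(tbl$site_s[cbind(ciu, fu)])
  # draw one substitution per kept variant, grouped by reference base
  refu <- pre$ref_idx[keep]
  alt <- integer(length(keep))
  for (b in 1:4) {
    g <- which(refu == b)
    if (length(g))
      alt[g] <- sample.int(4L, length(g), replace = TRUE, prob = P[b, ])
  }
  k <- tbl$cls[cbind(ciu, fu, alt)]
  list(n_sites = N, s_sites = S,
       n_nonsyn = sum(k == 2L, na.rm = TRUE),
       n_syn = sum(k == 1L, na.rm = TRUE),
       n_used = length(keep), n_skipped = n_skipped)
}

#' Run a single context-mode replicate
#'
#' For each variant, a frame index is drawn uniformly from \{0, 1, 2\}, the
#' context codon is built (variants whose context is out of bounds,
#' ambiguous, or a stop codon are skipped), the variant position's fractional
#' site counts are accumulated, and one mutation is drawn from the model.
#' Uses the current RNG state; seed with [set.seed()].
#'
#' @param variants Variant data.frame (see [load_variants()]).
#' @param reference Named character vector of contig sequences.
#' @param model A `substitution_model`.
#' @return A list: `sites`, `mutations`, `dnds`, `n_used`, `n_skipped`. When
#'   every variant is skipped the result is empty with `dnds$degenerate` set.
#' @export
run_replicate <- function(variants, reference, model) {
  .check_model(model)
  pre <- context_precompute(variants, reference)
  r <- .replicate_counts(pre, prob_matrix(model))
  sites <- list(n_sites = r$n_sites, s_sites = r$s_sites)
  mutations <- list(n_nonsyn = r$n_nonsyn, n_syn = r$n_syn)
  list(sites = sites, mutations = mutations,
       dnds = compute_dnds(sites, mutations),
       n_used = r$n_used, n_skipped = r$n_skipped)
}

## Deterministic per-replicate seed stream (Lehmer step) so replicates are
## reproducible independently of each other.
.replicate_seed <- function(master_seed, r) {
  as.integer((as.numeric(master_seed) %% 2147483647 * 48271 + r) %% 2147483647)
}

#' Simulate a null dN/dS distribution from VCF contexts
#'
#' Runs `reps` independent context-mode replicates (see [run_replicate()]),
#' with per-replicate seeds derived deterministically from `seed`, and
#' collects the replicate omega values into a null distribution.
#'
#' @param vcf Path to a VCF file, or a variant data.frame from
#'   [load_variants()].
#' @param reference Named character vector of contig sequences, or a path to
#'   a reference FASTA.
#' @param model A `substitution_model`.
#' @param reps Number of replicates (>= 1).
#' @param seed Master seed (integer).
#' @return An object of class `null_distribution`: `values` (omega per
#'   replicate, `NA` for degenerate replicates), `reps`, `seed`,
#'   `model_name`, `replicates` (data.frame with per-replicate counts and
#'   rates), `skipped` (VCF record skip counts by category, when `vcf` is a
#'   path), `n_variants`.
#' @examples
#' fx <- generate_reference_and_vcf(n_variants = 50, contig_length = 500, seed = 1)
#' vcf <- tempfile(fileext = ".vcf"); writeLines(fx$vcf, vcf)
#' run_context(vcf, fx$reference, build_model("JC69"), reps = 10, seed = 7)
#' @export
run_context <- function(vcf, reference, model, reps, seed) {
  .check_model(model)
  if (!is.numeric(reps) || length(reps) != 1L || is.na(reps) || reps < 1)
    dnds_parameter_error("'reps' must be a positive integer")
  reps <- as.integer(reps)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    dnds_parameter_error("'seed' must be a single integer")
  if (is.character(reference) && length(reference) == 1L && is.null(names(reference)))
    reference <- read_fasta(reference)
  skipped <- NULL
  if (is.character(vcf)) {
    loaded <- load_variants(vcf, reference)
    variants <- loaded$variants
    skipped <- loaded$skipped
  } else {
    variants <- vcf
  }
  pre <- context_precompute(variants, reference)
  P <- prob_matrix(model)
  rows <- vector("list", reps)
  for (r in seq_len(reps)) {
    set.seed(.replicate_seed(seed, r))
    rc <- .replicate_counts(pre, P)
    d <- compute_dnds(list(n_sites = rc$n_sites, s_sites = rc$s_sites),
                      list(n_nonsyn = rc$n_nonsyn, n_syn = rc$n_syn))
    rows[[r]] <- data.frame(
      replicate = r, n_used = rc$n_used, n_skipped = rc$n_skipped,
      n_nonsyn = rc$n_nonsyn, n_syn = rc$n_syn,
      n_sites = rc$n_sites, s_sites = rc$s_sites,
      d_n = d$d_n, d_s = d$d_s, omega = d$omega, degenerate = d$degenerate)
  }
  replicates <- do.call(rbind, rows)
  structure(
    list(values = replicates$omega, reps = reps, seed = as.integer(seed),
         model_name = model$name, replicates = replicates,
         skipped = skipped, n_variants = nrow(variants)),
    class = "null_distribution"
  )
}

#' @method print null_distribution
#' @export
print.null_distribution <- function(x, ...) {
  nd <- sum(!is.na(x$values))
  cat(sprintf("<null_distribution> model %s | %d replicates (%d defined) | %d variants | seed %d\n",
              x$model_name, x$reps, nd, x$n_variants, x$seed))
  if (nd) cat(sprintf("  omega: median %.4f  mean %.4f\n",
                      stats::median(x$values, na.rm = TRUE),
                      mean(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Exact expected replicate counts (analytic oracle)
#'
#' Marginalizes a context-mode replicate analytically over the uniform frame
#' draw and the model's alternative-base distribution: for each variant it
#' sums `(1/3) * P(alt) * 1[class]` over the three frames and three
#' alternatives (skipped frames contribute nothing), giving the exact
#' expectation of a replicate's aggregate counts.
#'
#' @inheritParams run_replicate
#' @return List with expected `n_sites`, `s_sites`, `n_nonsyn`, `n_syn`.
#' @export
exact_expected_counts <- function(variants, reference, model) {
  .check_model(model)
  pre <- context_precompute(variants, reference)
  tbl <- codon_tables()
  P <- prob_matrix(model)
  eN <- 0; eS <- 0; enN <- 0; enS <- 0
  for (f in 1:3) {
    ci <- pre$ctx[, f]
    keep <- which(!is.na(ci))
    if (!length(keep)) next
    ciu <- ci[keep]
    eN <- eN + sum(tbl$site_n[cbind(ciu, f)]) / 3
    eS <- eS + sum(tbl$site_s[cbind(ciu, f)]) / 3
    for (a in 1:4) {
      k <- tbl$cls[cbind(ciu, f, a)]
      w <- P[cbind(pre$ref_idx[keep], a)]
      enN <- enN + sum(w * (!is.na(k) & k == 2L)) / 3
      enS <- enS + sum(w * (!is.na(k) & k == 1L)) / 3
    }
  }
  list(n_sites = eN, s_sites = eS, n_nonsyn = enN, n_syn = enS)
}
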