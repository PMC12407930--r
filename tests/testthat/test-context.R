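ref10 <- c(chr1 = "TACGATTGCA")

test_that("VCF loading keeps ref-consistent biallelic SNVs and counts skips", {
  vcf <- tempfile(fileext = ".vcf")
  write_test_vcf(c("chr1\t5\t.\tA\tG\t.\t.\t.",      # good SNV
                   "chr1\t3\t.\tCG\tC\t.\t.\t.",     # deletion
                   "chr1\t4\t.\tG\tA,T\t.\t.\t.",    # multiallelic
                   "chr1\t6\t.\tG\tC\t.\t.\t.",      # REF mismatch (ref is T)
                   "chr1\t7\t.\tT\t<DEL>\t.\t.\t."), # symbolic
                 vcf, length = 10L)
  got <- load_variants(vcf, ref10)
  expect_equal(nrow(got$variants), 1L)
  expect_equal(got$variants$pos, 5L)
  expect_equal(got$variants$ref, "A")
  expect_equal(unname(got$skipped[c("indel", "multiallelic", "ref_mismatch", "symbolic")]),
               c(1L, 1L, 1L, 1L))
  # skip accounting: kept + skipped = total records
  expect_equal(nrow(got$variants) + sum(got$skipped), got$n_records)

  write_test_vcf("chr9\t5\t.\tA\tG\t.\t.\t.", vcf)
  expect_error(load_variants(vcf, ref10), class = "dnds_input_error")

  write_test_vcf(character(0), vcf)
  expect_error(load_variants(vcf, ref10), class = "dnds_empty_error")
})

test_that("context codons place the variant at the requested frame index", {
  v <- list(chrom = "chr1", pos = 5, ref = "A")
  expect_equal(build_context_codon(ref10, v, 0)$codon, "ATT")
  expect_equal(build_context_codon(ref10, v, 1)$codon, "GAT")
  expect_equal(build_context_codon(ref10, v, 2)$codon, "CGA")
  # flank past the contig start/end is an out-of-bounds skip
  expect_error(build_context_codon(ref10, list(chrom = "chr1", pos = 1, ref = "T"), 2),
               class = "dnds_input_error")
  expect_error(build_context_codon(ref10, list(chrom = "chr1", pos = 10, ref = "A"), 0),
               class = "dnds_input_error")
  # ambiguity code in a flank is a skip
  refN <- c(chr1 = "TACGNTTGCA")
  expect_error(build_context_codon(refN, list(chrom = "chr1", pos = 4, ref = "G"), 0),
               class = "dnds_input_error")
})

test_that("a simulated mutation is classified against the context codon", {
  ctx <- build_context_codon(ref10, list(chrom = "chr1", pos = 5, ref = "A"), 1)
  m <- build_model("JC69")
  # GAT with the variant at frame 1: GCT/GGT/GTT are all missense
  set.seed(3)
  for (i in 1:20) {
    r <- simulate_variant(ctx, m)
    expect_equal(r$class, "missense")
    expect_true(r$alt %in% c("C", "G", "T"))
  }
  # stop-codon contexts are rejected
  stop_ctx <- structure(list(codon = "TAA", frame_index = 0L,
                             chrom = "chr1", pos = 1L), class = "context_codon")
  expect_error(simulate_variant(stop_ctx, m), class = "dnds_input_error")
})

test_that("null distributions are deterministic in the master seed", {
  fx <- generate_reference_and_vcf(n_variants = 100, contig_length = 1000, seed = 5)
  vcf <- tempfile(fileext = ".vcf"); writeLines(fx$vcf, vcf)
  m <- build_model("K2P", alpha = 2, beta = 1)
  a <- run_context(vcf, fx$reference, m, reps = 50, seed = 99)
  b <- run_context(vcf, fx$reference, m, reps = 50, seed = 99)
  expect_identical(a$values, b$values)
  expect_identical(a$replicates, b$replicates)
  c <- run_context(vcf, fx$reference, m, reps = 50, seed = 100)
  expect_false(identical(a$values, c$values))
  expect_equal(length(a$values), 50L)
  expect_true(all(a$values[!is.na(a$values)] >= 0))
  expect_error(run_context(vcf, fx$reference, m, reps = 0, seed = 1),
               class = "dnds_parameter_error")
})

test_that("the analytic oracle matches brute-force enumeration on one variant", {
  # variant at pos 5 of TACGATTGCA; context codons ATT (frame 0), GAT (1),
  # CGA (2). Expected synonymous mutation mass = (1/3) * sum over frames of
  # P(syn | codon, frame), enumerated against the standard code.
  v <- data.frame(chrom = "chr1", pos = 5L, ref = "A", alt = "G")
  m <- build_model("HKY85", kappa = 2, pi = c(0.1, 0.2, 0.3, 0.4))
  probs <- substitution_probabilities(m, "A")
  exp_syn <- 0; exp_non <- 0; exp_N <- 0; exp_S <- 0
  for (f in 0:2) {
    codon <- build_context_codon(ref10, v, f)$codon
    for (b in names(probs)) {
      k <- oracle_classify(codon, f, b)
      if (k == "synonymous") exp_syn <- exp_syn + probs[[b]] / 3
      if (k == "missense") exp_non <- exp_non + probs[[b]] / 3
      if (k == "synonymous") exp_S <- exp_S + 1 / 9
      if (k == "missense") exp_N <- exp_N + 1 / 9
    }
  }
  got <- exact_expected_counts(v, ref10, m)
  expect_equal(got$n_syn, exp_syn, tolerance = 1e-12)
  expect_equal(got$n_nonsyn, exp_non, tolerance = 1e-12)
  expect_equal(got$s_sites, exp_S, tolerance = 1e-12)
  expect_equal(got$n_sites, exp_N, tolerance = 1e-12)
})

test_that("replicate means converge to the analytic expectation", {
  fx <- generate_reference_and_vcf(n_variants = 200, contig_length = 2000, seed = 8)
  m <- build_model("K3P", alpha = 2, beta = 1, gamma = 0.5)
  nd <- run_context(fx$variants, fx$reference, m, reps = 1000, seed = 21)
  ex <- exact_expected_counts(fx$variants, fx$reference, m)
  for (col in c("n_nonsyn", "n_syn", "n_sites", "s_sites")) {
    obs <- nd$replicates[[col]]
    se <- stats::sd(obs) / sqrt(length(obs))
    expect_lt(abs(mean(obs) - ex[[col]]), 4 * se)
  }
})

test_that("single-replicate and degenerate inputs are handled", {
  fx <- generate_reference_and_vcf(n_variants = 20, contig_length = 200, seed = 2)
  m <- build_model("JC69")
  nd <- run_context(fx$variants, fx$reference, m, reps = 1, seed = 4)
  expect_length(nd$values, 1L)
  # a replicate where every variant is skipped: variant whose every frame
  # is out of bounds on a tiny contig
  tiny <- c(c1 = "AAAA")
  v <- data.frame(chrom = "c1", pos = 1L, ref = "A", alt = "G")
  set.seed(1)
  r <- run_replicate(v, tiny, m)
  # pos 1 leaves frames 1 and 2 out of bounds; frame 0 codon AAA is usable,
  # so force full skipping with pos 4 instead (frames 0/1 out of bounds,
  # frame 2 codon AAA usable) -- use a contig of length 2 for true skipping
  tiny2 <- c(c1 = "AA")
  v2 <- data.frame(chrom = "c1", pos = 1L, ref = "A", alt = "G")
  r2 <- run_replicate(v2, tiny2, m)
  expect_true(r2$dnds$degenerate)
  expect_equal(r2$n_used, 0L)
})
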