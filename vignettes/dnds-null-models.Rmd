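---
title: "Model-explicit null distributions for dN/dS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-explicit null distributions for dN/dS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dndsim)
```

## The model

`dndsim` estimates and simulates ω = dN/dS, the ratio of the nonsynonymous
substitution rate (nonsynonymous changes per nonsynonymous site) to the
synonymous rate. The expectation under neutrality depends on the mutational
process: a transition-biased process hits the (transition-rich) synonymous
third-position changes more often and depresses ω below 1 even without
selection. The package therefore makes the mutation model explicit and lets
you compute the ω an *unselected* process would produce.

### Substitution models

All five supported models are relative-rate matrices over the bases in
(T, C, A, G) order:

| model | off-diagonal rate r(i→j) | parameters |
|-------|--------------------------|------------|
| JC69  | μ for every pair | μ |
| K2P   | α transitions, β transversions | α, β |
| K3P   | α transitions; β for A↔T, C↔G; γ for A↔C, G↔T | α, β, γ |
| F81   | π_j | π |
| HKY85 | κ·π_j transitions, π_j transversions | κ, π |

Only rate *ratios* matter: every use of a model first normalizes out of a
fixed base, P(j | i) = r(i→j) / Σ_k r(i→k), so no global matrix scaling (to
unit expected rate, say) is performed. Diagonal entries are stored as the
negative row sum purely for display. The K3P transversion-class assignment
(β to A↔T and C↔G, γ to A↔C and G↔T) follows the common K3ST convention; the
two classes are interchangeable by swapping β and γ. Omitted parameters
default to the JC69-equivalent values (μ = 1, α = β = κ = 1, γ = β, uniform
π), so an unset parameter can never silently bias a result.

### Site and mutation counting

For each sense codon, the nine single-base changes are classified against
the standard genetic code (translation table 1, taken from
`Biostrings::GENETIC_CODE`) as synonymous, missense, or nonsense.

* **Sites** use uniform weights: each alternative contributes 1/3 to N
  (missense) or S (synonymous). Nonsense changes are excluded from both —
  the Nei–Gojobori convention — so N + S ≤ 3 per codon, with equality only
  for codons with no stop-adjacent change.
* **Mutation tallies** n_N, n_S use the model's normalized per-base
  probabilities as weights instead of 1/3; nonsense weights are again
  discarded.

This asymmetry — uniform sites, model-weighted mutations — is the package's
central accounting choice. It is what makes ω responsive to the model at
all: if sites were model-weighted too, every model would return ω = 1
identically. Under JC69 the model weights *are* uniform, so n_N = N and
n_S = S codon-by-codon and the exhaustive ω is exactly 1 for any coding
sequence. That identity is used throughout the tests as an analytic anchor,
and is the quantity `scripts/acceptance.R` recomputes.

## Exhaustive mode

`exhaustive_scan()` locates the reading frame at the first ATG anywhere in
the sequence (set `assume_in_frame = TRUE` to read from base 0 for
pre-trimmed CDS), then walks codon-by-codon, aggregating site counts and
model-weighted tallies, and finally forms dN = n_N/N, dS = n_S/S, ω = dN/dS.

Numerical and edge-case choices:

* Scanning stops at (and excludes) the first in-frame stop codon. An
  *internal* stop truncates the scan with a warning naming the offset; stop
  codons have no defined site counts, so silently continuing past one would
  mix frames.
* A trailing partial codon is dropped.
* BED region restriction keeps only codons whose three bases all lie inside
  a merged region; codons straddling a boundary are skipped (and counted in
  a message) because fractional-codon accounting is not defined.
* Degenerate aggregates (S = 0, N = 0, or n_S = 0) are returned flagged
  with ω = NA, never raised as errors: a short or stop-poor region can
  legitimately produce them.
* Counts are accumulated in double precision; assertions in the test suite
  use a 1e-9 tolerance (the per-codon weights are small rationals, so
  round-off is far below that).

## Context mode

`run_context()` builds a null ω distribution anchored at observed variant
*positions*. Per replicate, for each usable VCF SNV:

1. a frame index is drawn uniformly from {0, 1, 2};
2. a codon is built from the reference flanks with the variant base at that
   index; out-of-bounds, ambiguous-flank, and stop-codon contexts are
   skipped (not resampled — resampling would bias the frame distribution
   conditional on sequence content);
3. the variant position's site counts (1/3 per alternative, stops excluded)
   are accumulated;
4. one substitution is drawn from the model and adds weight 1 to n_N or n_S
   by its class; nonsense draws add nothing.

Interpretive choices, made once and documented here:

* **The recorded ALT allele is ignored** for simulation; the VCF supplies
  positions and contexts, the model supplies the mutation. ALT is retained
  in the variant table for audit.
* **Site counting covers the variant position only**, not the whole
  constructed codon, mirroring the fact that exactly one mutation is
  simulated per variant. With whole-codon sites the JC69 null would no
  longer center on 1.
* The frame index is re-randomized per variant per replicate.
* Coordinates: VCF positions are 1-based; all internal offsets 0-based;
  the conversion lives in the VCF reader only. Only the forward strand is
  considered.
* Per-replicate seeds derive from the master seed by a fixed integer
  recurrence, so any replicate can be reproduced in isolation and results
  are independent of execution order.

`exact_expected_counts()` is the analytic companion: it marginalizes one
replicate over the uniform frame draw and the model's alternative
distribution, Σ_frames Σ_alt (1/3)·P(alt)·1[class]. The test suite checks
that replicate means converge to it within Monte-Carlo error for all five
models — a simulation-versus-closed-form cross-validation that does not
reuse the simulation code path.

## Statistics

* `summarize_null()` reports moments and the 2.5/25/50/75/97.5 percentiles
  over *defined* ω values; degenerate replicates are counted separately and
  never silently dropped.
* `empirical_percentile()` uses add-one (pseudo-count) p-values,
  p = (1 + #{null ≥ obs}) / (1 + n) for the "greater" alternative, so a
  finite simulation never returns p = 0; the two-sided p doubles the
  smaller tail and caps at 1.
* `compare_models()` applies a Kruskal–Wallis omnibus test across the
  defined values of two or more null distributions. The choice of a
  distribution-free k-group rank test is this package's; the test name is
  recorded in the output so downstream reports are unambiguous.

## Synthetic data

The fixture generators exist so that every mode is testable without any
external sequence:

* `generate_cds()` emits ATG + n sense codons (base-wise draws from a
  frequency vector, stop codons rejected and resampled) + one uniform stop.
  It emulates a clean single-frame CDS; it does *not* emulate codon-usage
  bias, GC skew along the gene, splice structure, or homopolymer artifacts.
* `generate_reference_and_vcf()` emits one uniform-composition contig and
  REF-consistent SNVs at distinct interior positions (≥3 bases from each
  end so every frame index has full flanks), with a minimal VCF 4.2 header.
  Ambiguity codes are excluded by construction; the skip paths for N-flanks
  and malformed records are exercised by dedicated hand-built fixtures in
  the tests instead of by chance.

Consequently a passing suite shows the *algorithms* are correct under the
stated conventions; it does not show that any particular biological
sequence is neutral, nor calibrate the biased models' parameters, which are
user-supplied.

## Problem sizes

The packaged checks run at sizes chosen to make Monte-Carlo error small
relative to the tolerances they assert: 20 × 500-codon sequences for the
JC69 anchor; 100 × 300-codon sequences for the bias-direction ordering
(transition bias α:β = 4:1 gives ω < 1, transversion bias 1:4 gives ω > 1);
2000 replicates × 500 variants on a 10 kb contig for oracle convergence
(within 4 standard errors, per model); 200 replicates × 1000 variants for
JC69 neutrality of the context null (median in [0.9, 1.1]); and 100 trials
of paired 200-replicate JC69 nulls for Kruskal–Wallis calibration.

## Known limitations

* No pairwise-alignment dN/dS between two real sequences, no multiple-hit
  correction, no codon models with ω as a free parameter (this package
  simulates nulls; it does not maximize likelihoods).
* Standard genetic code only; single-nucleotide changes only.
* No time-dependent transition probabilities (matrix exponentials): the
  models act as single-event substitution kernels.
* No trinucleotide (96-class) signatures or strand asymmetry in context
  mode; the context is exactly the two flanking bases that complete the
  codon.
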