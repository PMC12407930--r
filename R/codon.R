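## Codon-level machinery: the standard genetic code, classification of
## single-base changes, and fractional synonymous/nonsynonymous site
## counting (Nei-Gojobori style, stop-producing changes excluded).

## Package-local cache for the codon lookup tables.
.dnds_cache <- new.env(parent = emptyenv())

#' All 64 codons in T, C, A, G order
#' @return Character vector of the 64 codons (third position varying fastest).
#' @export
all_codons <- function() {
  g <- expand.grid(p3 = DNA_BASES4, p2 = DNA_BASES4, p1 = DNA_BASES4,
                   stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
}

#' The 61 sense codons of the standard genetic code
#' @return Character vector of length 61.
#' @export
sense_codons <- function() {
  cods <- all_codons()
  cods[vapply(cods, translate_codon, "") != "*"]
}

.check_codon <- function(codon) {
  if (!is.character(codon) || length(codon) != 1L || nchar(codon) != 3L)
    dnds_parameter_error("'codon' must be a single 3-letter string")
  codon <- toupper(codon)
  if (!all(strsplit(codon, "")[[1]] %in% DNA_BASES4))
    dnds_input_error(sprintf("codon '%s' contains a base outside {T, C, A, G}", codon))
  codon
}

#' Translate a codon under the standard genetic code
#'
#' @param codon A 3-letter codon string over T, C, A, G.
#' @return One-letter amino acid symbol, or `"*"` for the three stop codons
#'   (TAA, TAG, TGA).
#' @examples
#' translate_codon("ATG")  # "M"
#' translate_codon("TAA")  # "*"
#' @export
translate_codon <- function(codon) {
  codon <- .check_codon(codon)
  unname(Biostrings::GENETIC_CODE[[codon]])
}

#' Classify a single-base codon change
#'
#' A change is synonymous when the amino acid is unchanged (and neither codon
#' is a stop), nonsense when the mutated codon is a stop, and missense
#' otherwise.
#'
#' @param codon A sense codon (3-letter string).
#' @param position 0-based position within the codon (0, 1, or 2).
#' @param alt The substituted base; must differ from the base at `position`.
#' @return One of `"synonymous"`, `"missense"`, `"nonsense"`.
#' @examples
#' classify_change("AAA", 2, "G")  # synonymous (Lys -> Lys)
#' classify_change("TGG", 2, "A")  # nonsense (TGA is a stop)
#' @export
classify_change <- function(codon, position, alt) {
  codon <- .check_codon(codon)
  if (!position %in% 0:2)
    dnds_parameter_error("'position' must be 0, 1, or 2")
  .check_base(alt, "alt")
  if (translate_codon(codon) == "*")
    dnds_input_error(sprintf("codon '%s' is a stop codon; changes are undefined", codon))
  ref <- substr(codon, position + 1L, position + 1L)
  if (alt == ref)
    dnds_parameter_error(sprintf("alt base '%s' equals the reference base at position %d", alt, position))
  mutated <- codon
  substr(mutated, position + 1L, position + 1L) <- alt
  aa_new <- translate_codon(mutated)
  if (aa_new == "*") return("nonsense")
  if (aa_new == translate_codon(codon)) "synonymous" else "missense"
}

## Build (once per session) the lookup tables driving both simulation modes:
##  aa      named char[64]                 amino acid / "*"
##  cls     int[64 x 3 x 4]                1 syn, 2 mis, 3 non; NA for
##                                         same-base cells and stop codons
##  site_n  num[64 x 3]                    per-position missense site weight
##  site_s  num[64 x 3]                    per-position synonymous site weight
## Site weights give each of the 3 alternatives weight 1/3; stop-producing
## changes contribute 0 (excluded, not reassigned).
codon_tables <- function() {
  if (!is.null(.dnds_cache$tbl)) return(.dnds_cache$tbl)
  cods <- all_codons()
  aa <- vapply(cods, function(cd) unname(Biostrings::GENETIC_CODE[[cd]]), "")
  cls <- array(NA_integer_, dim = c(64L, 3L, 4L),
               dimnames = list(cods, NULL, DNA_BASES4))
  site_n <- matrix(NA_real_, 64L, 3L, dimnames = list(cods, NULL))
  site_s <- matrix(NA_real_, 64L, 3L, dimnames = list(cods, NULL))
  for (i in seq_along(cods)) {
    if (aa[i] == "*") next
    for (p in 1:3) {
      ref <- substr(cods[i], p, p)
      n_w <- 0; s_w <- 0
      for (b in DNA_BASES4) {
        if (b == ref) next
        mut <- cods[i]
        substr(mut, p, p) <- b
        aam <- aa[match(mut, cods)]
        if (aam == "*") {
          cls[i, p, b] <- 3L
        } else if (aam == aa[i]) {
          cls[i, p, b] <- 1L
          s_w <- s_w + 1 / 3
        } else {
          cls[i, p, b] <- 2L
          n_w <- n_w + 1 / 3
        }
      }
      site_n[i, p] <- n_w
      site_s[i, p] <- s_w
    }
  }
  .dnds_cache$tbl <- list(codons = cods, aa = aa, cls = cls,
                          site_n = site_n, site_s = site_s)
  .dnds_cache$tbl
}

#' Fractional synonymous and nonsynonymous site counts for a codon
#'
#' Each of the nine possible single-base changes contributes weight 1/3 to the
#' nonsynonymous site count N if missense, 1/3 to the synonymous count S if
#' synonymous, and nothing if it creates a stop codon. N + S = 3 exactly when
#' no change yields a stop.
#'
#' @param codon A sense codon.
#' @return A list with numeric elements `n_sites` (N) and `s_sites` (S).
#' @examples
#' count_sites("TTT")  # N = 8/3, S = 1/3
#' count_sites("TGG")  # N = 7/3, S = 0 (two stop-producing changes excluded)
#' @export
count_sites <- function(codon) {
  codon <- .check_codon(codon)
  tbl <- codon_tables()
  i <- match(codon, tbl$codons)
  if (tbl$aa[i] == "*")
    dnds_input_error(sprintf("codon '%s' is a stop codon; site counts are undefined", codon))
  list(n_sites = sum(tbl$site_n[i, ]), s_sites = sum(tbl$site_s[i, ]))
}

#' Model-weighted mutation tallies for a codon
#'
#' For each codon position, each alternative base receives the model's
#' normalized substitution probability out of the reference base at that
#' position. Missense weights sum into `n_nonsyn`, synonymous weights into
#' `n_syn`; weights of stop-producing changes are discarded. Under JC69 the
#' weights are uniform and the tallies equal [count_sites()] exactly.
#'
#' @param codon A sense codon.
#' @param model A `substitution_model`.
#' @return A list with numeric elements `n_nonsyn` and `n_syn`.
#' @examples
#' weighted_mutation_counts("TTT", build_model("K2P", alpha = 4, beta = 1))
#' @export
weighted_mutation_counts <- function(codon, model) {
  codon <- .check_codon(codon)
  .check_model(model)
  tbl <- codon_tables()
  i <- match(codon, tbl$codons)
  if (tbl$aa[i] == "*")
    dnds_input_error(sprintf("codon '%s' is a stop codon; tallies are undefined", codon))
  P <- prob_matrix(model)
  n_w <- 0; s_w <- 0
  for (p in 1:3) {
    ref <- substr(codon, p, p)
    w <- P[ref, ]
    k <- tbl$cls[i, p, ]
    s_w <- s_w + sum(w[which(k == 1L)])
    n_w <- n_w + sum(w[which(k == 2L)])
  }
  list(n_nonsyn = n_w, n_syn = s_w)
}

## Per-model 64-row weight table (n_N, n_S per codon) used by the exhaustive
## scan so a long CDS reduces to a table lookup. Stop rows are NA.
model_weight_table <- function(model) {
  tbl <- codon_tables()
  P <- prob_matrix(model)
  n <- rep(NA_real_, 64L); s <- rep(NA_real_, 64L)
  for (i in seq_len(64L)) {
    if (tbl$aa[i] == "*") next
    nv <- 0; sv <- 0
    for (p in 1:3) {
      ref <- substr(tbl$codons[i], p, p)
      w <- P[ref, ]
      k <- tbl$cls[i, p, ]
      sv <- sv + sum(w[which(k == 1L)])
      nv <- nv + sum(w[which(k == 2L)])
    }
    n[i] <- nv; s[i] <- sv
  }
  data.frame(codon = tbl$codons, n_nonsyn = n, n_syn = s)
}
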