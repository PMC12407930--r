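## Nucleotide substitution models: named 4x4 relative-rate matrices over
## (T, C, A, G) plus per-base normalized substitution probabilities and
## sampling. Rates are relative: every downstream use normalizes per
## from-base, so only ratios matter.

#' Canonical nucleotide ordering
#'
#' The four DNA bases in the row/column order used by every rate matrix in
#' this package: T, C, A, G.
#' @format Character vector of length 4.
#' @export
DNA_BASES4 <- c("T", "C", "A", "G")

## Transitions are the purine<->purine and pyrimidine<->pyrimidine pairs.
.is_transition <- function(from, to) {
  (from == "A" & to == "G") | (from == "G" & to == "A") |
    (from == "C" & to == "T") | (from == "T" & to == "C")
}

## K3P transversion classes (K3ST convention): beta for A<->T and C<->G,
## gamma for A<->C and G<->T.
.is_beta_transversion <- function(from, to) {
  pair <- paste(pmin(from, to), pmax(from, to))
  pair %in% c("A T", "C G")
}

SUPPORTED_MODELS <- c("JC69", "K2P", "K3P", "F81", "HKY85")

.check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    dnds_parameter_error(sprintf("parameter '%s' must be a single positive number", name))
  as.numeric(x)
}

.check_pi <- function(pi) {
  if (is.null(pi)) pi <- rep(0.25, 4L)
  if (!is.numeric(pi) || length(pi) != 4L || anyNA(pi) || any(pi < 0))
    dnds_parameter_error("parameter 'pi' must be 4 non-negative frequencies over (T, C, A, G)")
  if (abs(sum(pi) - 1) > 1e-9)
    dnds_parameter_error("parameter 'pi' must sum to 1 (tolerance 1e-9)")
  pi <- as.numeric(pi)
  names(pi) <- DNA_BASES4
  pi
}

#' Build a nucleotide substitution model
#'
#' Constructs one of the five supported relative-rate matrices. Off-diagonal
#' entries are indexed (from-base row, to-base column) in T, C, A, G order:
#'
#' * `JC69`: every substitution has rate `mu`.
#' * `K2P`: transitions (A<->G, C<->T) have rate `alpha`, transversions `beta`.
#' * `K3P`: transitions `alpha`; transversions A<->T and C<->G `beta`;
#'   transversions A<->C and G<->T `gamma`.
#' * `F81`: rate into base j equals the equilibrium frequency `pi[j]`.
#' * `HKY85`: `kappa * pi[j]` for transitions, `pi[j]` for transversions.
#'
#' Unset parameters default to the JC69-equivalent values (`mu = 1`,
#' `alpha = beta = kappa = 1`, `gamma = beta`, uniform `pi`) so that omitted
#' parameters never silently bias results. Diagonal entries are stored as the
#' negative row sum for display only; no operation reads them.
#'
#' @param name Model name, one of `"JC69"`, `"K2P"`, `"K3P"`, `"F81"`,
#'   `"HKY85"` (case-insensitive).
#' @param alpha Transition rate (K2P, K3P). Positive.
#' @param beta Transversion rate (K2P); A<->T / C<->G transversion rate (K3P).
#' @param gamma A<->C / G<->T transversion rate (K3P). Defaults to `beta`.
#' @param kappa Transition/transversion ratio (HKY85). Positive.
#' @param mu Uniform substitution rate (JC69). Positive.
#' @param pi Equilibrium base frequencies over (T, C, A, G), non-negative,
#'   summing to 1 (F81, HKY85). Defaults to uniform.
#' @return An object of class `substitution_model`: a list with elements
#'   `name`, `rates` (4x4 numeric matrix), and `params`.
#' @examples
#' build_model("JC69")
#' build_model("K2P", alpha = 4, beta = 1)
#' build_model("HKY85", kappa = 2, pi = c(0.1, 0.2, 0.3, 0.4))
#' @export
build_model <- function(name, alpha = NULL, beta = NULL, gamma = NULL,
                        kappa = NULL, mu = NULL, pi = NULL) {
  if (!is.character(name) || length(name) != 1L)
    dnds_parameter_error("model name must be a single string")
  name <- toupper(name)
  if (!name %in% SUPPORTED_MODELS)
    dnds_parameter_error(sprintf(
      "unsupported model '%s' (supported: %s)", name,
      paste(SUPPORTED_MODELS, collapse = ", ")))

  mu    <- if (is.null(mu)) 1 else .check_positive(mu, "mu")
  alpha <- if (is.null(alpha)) 1 else .check_positive(alpha, "alpha")
  beta  <- if (is.null(beta)) 1 else .check_positive(beta, "beta")
  gamma <- if (is.null(gamma)) beta else .check_positive(gamma, "gamma")
  kappa <- if (is.null(kappa)) 1 else .check_positive(kappa, "kappa")
  pi    <- .check_pi(pi)

  from <- matrix(DNA_BASES4, 4L, 4L)
  to <- t(from)
  ts <- .is_transition(from, to)
  rates <- switch(name,
    JC69 = matrix(mu, 4L, 4L),
    K2P = ifelse(ts, alpha, beta),
    K3P = ifelse(ts, alpha, ifelse(.is_beta_transversion(from, to), beta, gamma)),
    F81 = matrix(pi, 4L, 4L, byrow = TRUE),
    HKY85 = ifelse(ts, kappa, 1) * matrix(pi, 4L, 4L, byrow = TRUE)
  )
  dimnames(rates) <- list(from = DNA_BASES4, to = DNA_BASES4)
  diag(rates) <- 0
  if (any(rates[row(rates) != col(rates)] <= 0))
    dnds_parameter_error("all off-diagonal rates must be strictly positive; check 'pi'")
  diag(rates) <- -rowSums(rates)

  structure(
    list(name = name, rates = rates,
         params = list(alpha = alpha, beta = beta, gamma = gamma,
                       kappa = kappa, mu = mu, pi = pi)),
    class = "substitution_model"
  )
}

#' @method print substitution_model
#' @export
print.substitution_model <- function(x, ...) {
  cat(sprintf("<substitution_model> %s\n", x$name))
  print(round(x$rates, 6))
  invisible(x)
}

.check_model <- function(model) {
  if (!inherits(model, "substitution_model"))
    dnds_parameter_error("'model' must be a substitution_model (see build_model)")
  model
}

.check_base <- function(base, arg = "base") {
  if (!is.character(base) || length(base) != 1L || !base %in% DNA_BASES4)
    dnds_parameter_error(sprintf("'%s' must be one of T, C, A, G", arg))
  base
}

## 4x4 matrix of per-from-base substitution probabilities (diagonal 0,
## rows sum to 1). The fast path used throughout the simulators.
prob_matrix <- function(model) {
  r <- .check_model(model)$rates
  diag(r) <- 0
  r / rowSums(r)
}

#' Substitution probability distribution from one base
#'
#' Normalizes the model's off-diagonal rates out of `from` into a probability
#' distribution over the three alternative bases:
#' `P(alt) = rate(from -> alt) / sum(rate(from -> alt'))`.
#'
#' @param model A `substitution_model`.
#' @param from A single base, one of `"T"`, `"C"`, `"A"`, `"G"`.
#' @return Named numeric vector of length 3 over the alternatives (T, C, A, G
#'   order, `from` excluded), summing to 1.
#' @examples
#' substitution_probabilities(build_model("K2P", alpha = 2, beta = 1), "C")
#' @export
substitution_probabilities <- function(model, from) {
  .check_base(from, "from")
  p <- prob_matrix(model)[from, ]
  p[names(p) != from]
}

#' Sample a substitution from the model
#'
#' Draws one (or `n`) alternative base(s) for `from` with probabilities given
#' by [substitution_probabilities()]. Uses R's global random number stream:
#' seed with [set.seed()] for reproducibility. Never returns `from` itself.
#'
#' @inheritParams substitution_probabilities
#' @param n Number of draws.
#' @return Character vector of length `n` of bases distinct from `from`.
#' @examples
#' set.seed(1)
#' sample_substitution(build_model("JC69"), "A", n = 5)
#' @export
sample_substitution <- function(model, from, n = 1L) {
  p <- substitution_probabilities(model, from)
  sample(names(p), size = n, replace = TRUE, prob = p)
}

#' Read model parameters from a key=value config file
#'
#' Plain-text configuration with one `key=value` per line; recognized keys are
#' `model`, `alpha`, `beta`, `gamma`, `kappa`, `mu`, `pi_T`, `pi_C`, `pi_A`,
#' `pi_G`. Blank lines and lines starting with `#` are ignored.
#'
#' @param path Path to the config file.
#' @return A `substitution_model` built from the file's parameters.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) dnds_input_error(sprintf("config file not found: %s", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad))
    dnds_input_error(sprintf("config line not of the form key=value: '%s'",
                             lines[which(bad)[1]]))
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  known <- c("model", "alpha", "beta", "gamma", "kappa", "mu",
             "pi_T", "pi_C", "pi_A", "pi_G")
  if (any(!keys %in% known))
    dnds_input_error(sprintf("unknown config key '%s'", keys[!keys %in% known][1]))
  get_num <- function(k) if (k %in% keys) as.numeric(vals[match(k, keys)]) else NULL
  if (!"model" %in% keys) dnds_parameter_error("config file must set 'model'")
  pik <- c("pi_T", "pi_C", "pi_A", "pi_G")
  pi <- if (any(pik %in% keys)) {
    if (!all(pik %in% keys))
      dnds_parameter_error("all four of pi_T, pi_C, pi_A, pi_G must be set together")
    vapply(pik, get_num, 0)
  } else NULL
  build_model(vals[match("model", keys)],
              alpha = get_num("alpha"), beta = get_num("beta"),
              gamma = get_num("gamma"), kappa = get_num("kappa"),
              mu = get_num("mu"), pi = pi)
}
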