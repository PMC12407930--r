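test_that("build_model constructs the five rate matrices correctly", {
  off <- function(m) m$rates[row(m$rates) != col(m$rates)]

  jc <- build_model("JC69", mu = 1)
  expect_true(all(off(jc) == 1))

  k2 <- build_model("K2P", alpha = 3, beta = 0.5)
  expect_equal(k2$rates["A", "G"], 3)   # transition
  expect_equal(k2$rates["C", "T"], 3)
  expect_equal(k2$rates["A", "C"], 0.5) # transversion
  expect_length(unique(off(k2)), 2L)

  k3 <- build_model("K3P", alpha = 2, beta = 0.5, gamma = 0.25)
  expect_equal(k3$rates["A", "T"], 0.5)  # beta class: A<->T, C<->G
  expect_equal(k3$rates["C", "G"], 0.5)
  expect_equal(k3$rates["A", "C"], 0.25) # gamma class: A<->C, G<->T
  expect_equal(k3$rates["G", "T"], 0.25)
  expect_equal(k3$rates["G", "A"], 2)

  f81 <- build_model("F81", pi = c(0.1, 0.2, 0.3, 0.4))
  expect_equal(unname(f81$rates["C", "A"]), 0.3)  # rate into j is pi_j
  expect_equal(unname(f81$rates["A", "T"]), 0.1)

  hky <- build_model("HKY85", kappa = 2, pi = c(0.1, 0.2, 0.3, 0.4))
  expect_equal(unname(hky$rates["A", "G"]), 2 * 0.4)  # transition
  expect_equal(unname(hky$rates["A", "C"]), 0.2)      # transversion
})

test_that("build_model validates its parameters", {
  expect_error(build_model("GTR"), class = "dnds_parameter_error")
  expect_error(build_model("K2P", alpha = -1), class = "dnds_parameter_error")
  expect_error(build_model("F81", pi = c(0.5, 0.5, 0.5, 0.5)),
               class = "dnds_parameter_error")
  expect_error(build_model("F81", pi = c(1, 0, 0)), class = "dnds_parameter_error")
  # zero frequency makes an off-diagonal rate zero, which is rejected
  expect_error(build_model("F81", pi = c(1, 0, 0, 0)), class = "dnds_parameter_error")
})

test_that("substitution probabilities are normalized rates", {
  expect_equal(substitution_probabilities(build_model("JC69"), "C"),
               c(T = 1/3, A = 1/3, G = 1/3))
  # K2P(alpha=2, beta=1) from C: raw rates (T,A,G) = (2,1,1), sum 4
  expect_equal(substitution_probabilities(build_model("K2P", alpha = 2, beta = 1), "C"),
               c(T = 0.5, A = 0.25, G = 0.25))
  # F81: normalize target frequencies excluding pi_T
  p <- substitution_probabilities(build_model("F81", pi = c(0.1, 0.2, 0.3, 0.4)), "T")
  expect_equal(p, c(C = 0.2 / 0.9, A = 0.3 / 0.9, G = 0.4 / 0.9))
})

test_that("probabilities sum to one for every model and from-base", {
  models <- list(build_model("JC69", mu = 0.7),
                 build_model("K2P", alpha = 5, beta = 2),
                 build_model("K3P", alpha = 3, beta = 2, gamma = 0.5),
                 build_model("F81", pi = c(0.15, 0.35, 0.3, 0.2)),
                 build_model("HKY85", kappa = 4, pi = c(0.4, 0.1, 0.2, 0.3)))
  for (m in models) for (b in DNA_BASES4) {
    p <- substitution_probabilities(m, b)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_false(b %in% names(p))
    expect_true(all(p > 0))
  }
})

test_that("model reduction identities hold at the matrix level", {
  off <- function(m) m$rates[row(m$rates) != col(m$rates)]
  expect_equal(off(build_model("K2P", alpha = 2, beta = 2)),
               off(build_model("JC69", mu = 2)), tolerance = 1e-12)
  expect_equal(off(build_model("K3P", alpha = 3, beta = 0.5, gamma = 0.5)),
               off(build_model("K2P", alpha = 3, beta = 0.5)), tolerance = 1e-12)
  # F81 with uniform frequencies is proportional to JC69
  r1 <- off(build_model("F81", pi = rep(0.25, 4)))
  r2 <- off(build_model("JC69", mu = 1))
  expect_equal(r1 / r1[1], r2 / r2[1], tolerance = 1e-12)
  # HKY85 with kappa = 1 collapses to F81
  pi <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(off(build_model("HKY85", kappa = 1, pi = pi)),
               off(build_model("F81", pi = pi)), tolerance = 1e-12)
  # HKY85 with uniform pi is proportional to K2P(alpha = kappa, beta = 1)
  r3 <- off(build_model("HKY85", kappa = 5, pi = rep(0.25, 4)))
  r4 <- off(build_model("K2P", alpha = 5, beta = 1))
  expect_equal(r3 / max(r3), r4 / max(r4), tolerance = 1e-12)
})

test_that("sampling matches the analytic distribution and is reproducible", {
  m <- build_model("K2P", alpha = 1e6, beta = 1)
  set.seed(11)
  draws <- sample_substitution(m, "C", n = 1e4)
  expect_false(any(draws == "C"))
  p_t <- 1e6 / (1e6 + 2)
  expect_lt(abs(mean(draws == "T") - p_t), 3 * sqrt(p_t * (1 - p_t) / 1e4) + 1e-6)

  set.seed(42); a <- sample_substitution(build_model("JC69"), "A", n = 100)
  set.seed(42); b <- sample_substitution(build_model("JC69"), "A", n = 100)
  expect_identical(a, b)
  expect_false(any(a == "A"))

  # empirical frequencies match substitution_probabilities within 4 sigma
  models <- list(build_model("K3P", alpha = 2, beta = 1, gamma = 0.5),
                 build_model("HKY85", kappa = 3, pi = c(0.1, 0.2, 0.3, 0.4)))
  n <- 1e5
  for (m in models) for (b in c("T", "G")) {
    p <- substitution_probabilities(m, b)
    set.seed(7)
    d <- sample_substitution(m, b, n = n)
    for (alt in names(p)) {
      se <- sqrt(p[[alt]] * (1 - p[[alt]]) / n)
      expect_lt(abs(mean(d == alt) - p[[alt]]), 4 * se)
    }
  }
})

test_that("model parameters are read from key=value config files", {
  cfg <- tempfile(fileext = ".cfg")
  writeLines(c("# config", "model=hky85", "kappa=2.5",
               "pi_T=0.1", "pi_C=0.2", "pi_A=0.3", "pi_G=0.4"), cfg)
  m <- read_model_config(cfg)
  expect_equal(m$name, "HKY85")
  expect_equal(m$params$kappa, 2.5)
  expect_equal(unname(m$params$pi), c(0.1, 0.2, 0.3, 0.4))

  writeLines(c("model=jc69", "bogus=1"), cfg)
  expect_error(read_model_config(cfg), class = "dnds_input_error")
  writeLines("alpha=2", cfg)
  expect_error(read_model_config(cfg), class = "dnds_parameter_error")
})
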