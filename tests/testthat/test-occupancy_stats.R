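# Moments, variance, and truncated distribution of the set occupancy time.

test_that("fulmar breeding-attempt occupancy means match the analytic values", {
  an <- set_analysis(fulmar_chain(), c(3, 4))
  mt <- occupancy_moments(an$sub, an$absorption)
  expect_equal(unname(mt$mean), c(1.944769, 7.161245, 9.992979, 9.454716),
               tolerance = 1e-5)
  expect_true(all(mt$variance >= 0))
})

test_that("a single-state set recovers the geometric distribution", {
  for (u in c(0.2, 0.5, 0.9)) {
    an <- set_analysis(geom_chain(u), 1)
    mt <- occupancy_moments(an$sub, an$absorption)
    expect_equal(unname(mt$mean), 1 / (1 - u), tolerance = 1e-12)
    expect_equal(unname(mt$variance), u / (1 - u)^2, tolerance = 1e-10)
    pmf <- occupancy_distribution(an$sub, an$absorption, truncation_tol = 1e-9)
    n_show <- 2:6
    expect_equal(unname(pmf$probs[1, n_show]), (1 - u) * u^(n_show - 2),
                 tolerance = 1e-12)
  }
})

test_that("both variance routes agree", {
  set.seed(31)
  for (i in 1:50) {
    chain <- random_chain(sample(2:8, 1))
    B <- random_set(chain$omega)
    an <- set_analysis(chain, B)
    mt <- occupancy_moments(an$sub, an$absorption)
    vd <- occupancy_variance(an$sub, an$absorption)
    expect_equal(mt$variance, vd, tolerance = 1e-9)
  }
})

test_that("the PMF is normalised with a certified tail and consistent moments", {
  an <- set_analysis(fulmar_chain(), c(3, 4))
  pmf <- occupancy_distribution(an$sub, an$absorption, truncation_tol = 1e-11)
  expect_true(all(pmf$probs >= -1e-15))
  expect_true(all(pmf$tail_mass <= 1e-11))
  expect_equal(unname(rowSums(pmf$probs) + pmf$tail_mass), rep(1, 4),
               tolerance = 1e-9)
  # a start outside B has P(tau = 0) = 1 - pa
  expect_equal(unname(pmf$probs[1, 1]), 1 - 0.2, tolerance = 1e-10)
  # tabulated mean matches the closed-form mean within the truncated tail
  mt <- occupancy_moments(an$sub, an$absorption)
  s <- pmf_summary(pmf)
  expect_equal(s$mean, mt$mean, tolerance = 1e-6)
  expect_equal(s$variance, mt$variance, tolerance = 1e-4)
})

test_that("PMF normalisation holds over random chains and sets", {
  set.seed(32)
  for (i in 1:100) {
    chain <- random_chain(sample(2:7, 1))
    B <- random_set(chain$omega)
    an <- set_analysis(chain, B)
    pmf <- occupancy_distribution(an$sub, an$absorption, truncation_tol = 1e-10)
    expect_true(all(pmf$tail_mass <= 1e-10))
    expect_equal(unname(rowSums(pmf$probs) + pmf$tail_mass),
                 rep(1, chain$omega), tolerance = 1e-9)
  }
})

test_that("means add over disjoint sets even though variances do not", {
  set.seed(33)
  found_nonadditive_var <- FALSE
  for (i in 1:30) {
    chain <- random_chain(sample(3:8, 1))
    idx <- sample(chain$omega, min(chain$omega, 4))
    B1 <- idx[1:2]
    B2 <- idx[-(1:2)]
    set_mv <- function(B) {
      an <- set_analysis(chain, B)
      occupancy_moments(an$sub, an$absorption)
    }
    a <- set_mv(B1); b <- set_mv(B2); u <- set_mv(union(B1, B2))
    expect_equal(a$mean + b$mean, u$mean, tolerance = 1e-9)
    if (max(abs(a$variance + b$variance - u$variance)) > 1e-6) {
      found_nonadditive_var <- TRUE
    }
  }
  expect_true(found_nonadditive_var)
})

test_that("singleton sets reproduce the classical N and V rows", {
  set.seed(34)
  for (i in 1:20) {
    chain <- random_chain(sample(2:8, 1))
    N <- fundamental_matrix(chain$U)
    V <- single_state_occupancy_variance(chain)
    for (s in seq_len(chain$omega)) {
      an <- set_analysis(chain, s)
      mt <- occupancy_moments(an$sub, an$absorption)
      expect_equal(unname(mt$mean), unname(N[s, ]), tolerance = 1e-9)
      expect_equal(unname(mt$variance), unname(V[s, ]), tolerance = 1e-9)
    }
  }
})

test_that("invalid moment orders and tolerances are rejected", {
  an <- set_analysis(fulmar_chain(), c(3, 4))
  expect_error(occupancy_moments(an$sub, an$absorption, k_max = 0),
               class = "ParseError")
  expect_error(occupancy_moments(an$sub, an$absorption, k_max = 11),
               class = "ParseError")
  expect_error(occupancy_distribution(an$sub, an$absorption,
                                      truncation_tol = 0.5),
               class = "ParseError")
})
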