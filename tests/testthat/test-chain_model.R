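# Chain validation, partitioning, and classical fundamental-matrix results.

test_that("validation derives mortality and rejects impossible chains", {
  chain <- fulmar_chain()
  expect_equal(unname(chain$m), c(0.08, 0.10, 0.07, 0.09), tolerance = 1e-12)

  # immediate death
  expect_equal(unname(demographic_chain(matrix(0), "a")$m), 1)
  # no absorption possible
  expect_error(demographic_chain(matrix(1), "a"), class = "NotConvergent")
  # a closed recurrent pair inside a larger chain is also non-convergent
  U <- matrix(0, 3, 3); U[1, 2] <- 1; U[2, 1] <- 1; U[3, 3] <- 0.5
  expect_error(demographic_chain(U), class = "NotConvergent")

  expect_error(demographic_chain(matrix(-0.1)), class = "NegativeEntry")
  U2 <- fulmar_U; U2[3, 2] <- 0.5
  expect_error(demographic_chain(U2, fulmar_labels),
               class = "ColumnSumExceedsOne")
  expect_error(demographic_chain(fulmar_U, c("a", "b")),
               class = "LabelMismatch")
  expect_error(demographic_chain(fulmar_U, rep("a", 4)),
               class = "LabelMismatch")
})

test_that("partitioning extracts the printed fulmar blocks", {
  part <- partition_chain(fulmar_chain(), c(3, 4))
  expect_equal(unname(part$UK), diag(c(0.90, 0.63)), tolerance = 1e-12)
  expect_equal(unname(part$K), matrix(c(0.01, 0.18, 0.01, 0.09), 2,
                                      byrow = TRUE), tolerance = 1e-12)
  expect_equal(unname(part$L), matrix(c(0, 0, 0.07, 0.18), 2, byrow = TRUE),
               tolerance = 1e-12)
  expect_equal(unname(part$Q), matrix(c(0.67, 0.49, 0.19, 0.24), 2,
                                      byrow = TRUE), tolerance = 1e-12)
  expect_equal(unname(part$m_alpha), c(0.08, 0.10), tolerance = 1e-12)
  # target sets accept labels too, in any order
  part2 <- partition_chain(fulmar_chain(),
                           c("failed breeder", "successful breeder"))
  expect_identical(part2$B, part$B)
})

test_that("partitioning the whole state space is the degenerate case", {
  chain <- fulmar_chain()
  part <- partition_chain(chain, 1:4)
  expect_equal(part$alpha, 0L)
  expect_identical(unname(part$Q), unname(chain$U))
  expect_equal(dim(part$UK), c(0L, 0L))
  expect_error(partition_chain(chain, integer(0)), class = "EmptyTargetSet")
  expect_error(partition_chain(chain, 5), class = "IndexOutOfRange")
})

test_that("partition then reassemble reproduces U bit-exactly", {
  set.seed(11)
  for (i in 1:30) {
    chain <- random_chain(sample(2:8, 1))
    B <- random_set(chain$omega)
    part <- partition_chain(chain, B)
    expect_identical(reassemble_chain(part), chain$U)
  }
})

test_that("fundamental matrix agrees with the Neumann-series oracle", {
  UK <- diag(c(0.90, 0.63))
  N <- fundamental_matrix(UK)
  expect_equal(unname(N), diag(c(10, 1 / 0.37)), tolerance = 1e-10)
  expect_equal(unname(N), unname(neumann_fundamental(UK)), tolerance = 1e-10)

  expect_equal(fundamental_matrix(matrix(0, 2, 2)), diag(2))
  expect_equal(fundamental_matrix(matrix(0.5)), matrix(2), tolerance = 1e-12)
})

test_that("N solves N = I + U N for random substochastic matrices", {
  set.seed(12)
  for (i in 1:100) {
    chain <- random_chain(sample(1:8, 1))
    N <- fundamental_matrix(chain$U)
    expect_lt(max(abs(N - (diag(chain$omega) + chain$U %*% N))), 1e-10)
    expect_true(all(N >= -1e-12))
    expect_true(all(diag(N) >= 1 - 1e-12))
  }
})

test_that("single-state occupancy variance matches the geometric law", {
  V <- single_state_occupancy_variance(geom_chain(0.5))
  expect_equal(as.vector(V), 2, tolerance = 1e-12)   # u/(1-u)^2
  Vf <- single_state_occupancy_variance(fulmar_chain())
  expect_true(all(Vf >= -1e-10))
})

test_that("longevity moments match the linear-solve oracle and the set route", {
  chain <- fulmar_chain()
  lon <- longevity_moments(chain)
  # oracle: mean longevity solves (I - U)' x = 1
  x <- solve(t(diag(4) - chain$U), rep(1, 4))
  expect_equal(unname(lon$mean), unname(x), tolerance = 1e-10)

  # dies after exactly one step
  l0 <- longevity_moments(geom_chain(0))
  expect_equal(unname(l0$mean), 1)
  expect_equal(unname(l0$variance), 0)

  # definitional identity: longevity = occupancy of the full set
  an <- set_analysis(chain, 1:4)
  mt <- occupancy_moments(an$sub, an$absorption)
  expect_equal(lon$mean, mt$mean, tolerance = 1e-10)
  expect_equal(lon$variance, mt$variance, tolerance = 1e-10)
})

test_that("mean occupancy is additive over any partition of the state space", {
  set.seed(13)
  for (i in 1:20) {
    chain <- random_chain(sample(3:8, 1))
    # random partition of the transient set into 2-3 blocks
    grp <- sample(1:3, chain$omega, replace = TRUE)
    grp <- match(grp, unique(grp))
    total <- Reduce(`+`, lapply(unique(grp), function(g) {
      an <- set_analysis(chain, which(grp == g))
      occupancy_moments(an$sub, an$absorption, 1L)$mean
    }))
    expect_equal(total, longevity_moments(chain, 1L)$mean, tolerance = 1e-9)
  }
})
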