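# Killed, conditional, and sub-Markov chain construction.

fulmar_analysis <- function(B = c(3, 4)) set_analysis(fulmar_chain(), B)

test_that("killed chain stacks target entry over mortality", {
  an <- fulmar_analysis()
  kc <- an$killed
  expect_equal(unname(kc$MK["dead", ]), c(0.08, 0.10), tolerance = 1e-12)
  expect_equal(unname(colSums(rbind(kc$UK, kc$MK))), c(1, 1),
               tolerance = 1e-12)
  # other target set: complement is the single pre-breeder state
  kc2 <- fulmar_analysis(c(2, 3, 4))$killed
  expect_equal(unname(kc2$UK), matrix(0.90), tolerance = 1e-12)
})

test_that("absorption summary gives first-hit and reach probabilities", {
  ab <- fulmar_analysis()$absorption
  expect_equal(unname(ab$A),
               matrix(c(0.1, 18 / 37, 0.1, 9 / 37), 2, byrow = TRUE),
               tolerance = 1e-10)
  expect_equal(unname(ab$pa), c(0.2, 27 / 37), tolerance = 1e-10)
  expect_equal(unname(colSums(ab$Astar)), c(1, 1), tolerance = 1e-10)
  expect_equal(colSums(ab$A), ab$pa, tolerance = 1e-12)
})

test_that("unreachable targets give zero reach probability", {
  # state 1 loops on itself and cannot reach state 3
  U <- matrix(0, 3, 3)
  U[1, 1] <- 0.5; U[3, 2] <- 0.4; U[2, 3] <- 0.1
  chain <- demographic_chain(U)
  ab <- set_analysis(chain, 3)$absorption
  expect_equal(unname(ab$pa), c(0, 0.4), tolerance = 1e-14)
})

test_that("conditional chain conditions on reaching the target set", {
  an <- fulmar_analysis()
  cc <- an$conditional
  expect_equal(unname(cc$UC), diag(c(0.90, 0.63)), tolerance = 1e-10)
  expect_equal(unname(colSums(rbind(cc$UC, cc$MC))), c(1, 1),
               tolerance = 1e-10)

  # conditioning on a null event is masked, not divided by zero
  U <- matrix(0, 3, 3)
  U[1, 1] <- 0.5; U[3, 2] <- 0.4; U[2, 3] <- 0.1
  cc2 <- set_analysis(demographic_chain(U), 3)$conditional
  expect_identical(cc2$defined, c(s1 = FALSE, s2 = TRUE))
  expect_true(all(is.na(cc2$UC[, 1])))
  expect_equal(unname(colSums(rbind(cc2$UC, cc2$MC))[2]), 1, tolerance = 1e-10)

  # all-losers complement raises NoWinners
  U3 <- matrix(0, 2, 2); U3[1, 1] <- 0.5; U3[2, 2] <- 0.5
  part <- partition_chain(demographic_chain(U3), 2)
  kc <- killed_chain(part)
  expect_error(conditional_chain(kc, absorption_summary(kc)),
               class = "NoWinners")
})

test_that("conditional chain is similar to the killed chain", {
  # UC = Da UK Da^{-1} is a similarity transform: same eigenvalues
  set.seed(21)
  checked <- 0
  for (i in 1:50) {
    chain <- random_chain(sample(3:8, 1))
    B <- random_set(chain$omega, sample(chain$omega - 1, 1))
    an <- set_analysis(chain, B)
    if (is.null(an$conditional) || !all(an$conditional$defined)) next
    ev_K <- sort(Mod(eigen(an$killed$UK, only.values = TRUE)$values))
    ev_C <- sort(Mod(eigen(an$conditional$UC, only.values = TRUE)$values))
    expect_equal(ev_C, ev_K, tolerance = 1e-8)
    checked <- checked + 1
  }
  expect_gt(checked, 10)
})

test_that("sub-chain combines direct moves and excursions", {
  an <- fulmar_analysis()
  sc <- an$sub
  expect_equal(round(unname(sc$US), 2),
               matrix(c(0.70, 0.58, 0.21, 0.28), 2, byrow = TRUE))
  expect_equal(round(unname(sc$mS[1]), 2), 0.09)
  expect_equal(sc$pr, colSums(sc$US), tolerance = 1e-14)

  # watching everything reproduces the original chain
  scT <- set_analysis(fulmar_chain(), 1:4)$sub
  expect_equal(unname(scT$US), unname(fulmar_U), tolerance = 1e-14)

  # conditional first-step split sums to one: pr = pa' L + 1' Q columnwise
  w <- colSums(sc$Win) + colSums(sc$Wout)
  expect_equal(unname(w), c(1, 1), tolerance = 1e-10)
})

test_that("induced-chain invariants hold over random chains and sets", {
  set.seed(22)
  for (i in 1:100) {
    chain <- random_chain(sample(2:8, 1))
    B <- random_set(chain$omega)
    an <- set_analysis(chain, B)
    if (an$part$alpha > 0) {
      expect_equal(unname(colSums(an$absorption$Astar)),
                   rep(1, an$part$alpha), tolerance = 1e-10)
      expect_true(all(an$absorption$pa >= -1e-12 &
                        an$absorption$pa <= 1 + 1e-12))
    }
    expect_true(all(colSums(an$sub$US) <= 1 + 1e-12))
    expect_true(all(an$sub$mS >= -1e-12 & an$sub$mS <= 1 + 1e-12))
    d <- an$sub$defined_r
    if (any(d)) {
      w <- colSums(an$sub$Win[, d, drop = FALSE])
      if (an$part$alpha > 0) {
        w <- w + colSums(an$sub$Wout[, d, drop = FALSE])
      }
      expect_equal(unname(w), rep(1, sum(d)), tolerance = 1e-10)
    }
  }
})
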