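# Winners and losers: the probability of ever reaching the target set, the
# conditional distribution of the reaching time t_B (winners only), and the
# conditional distribution of the return time mu (returners only).

#' Reaching the target set: winner probabilities and reaching-time statistics
#'
#' A "winner" is an individual that enters the target set at least once; its
#' reaching time `t_B` is the number of steps until first entry. The winner
#' probabilities are the reach probabilities `pa`; conditional on winning,
#' `t_B` is the total transient occupancy of the conditional chain, so
#' `E[t_B'] = 1' NC`, higher moments follow the same recursion as occupancy
#' moments applied to `NC`, and `P(t_B = n) = 1'(I - UC) UC^(n-1)` for
#' `n >= 1`. States that cannot reach the set get `NA` (the conditional law
#' is undefined), with `p_win = 0`.
#'
#' @param cond a [conditional_chain()].
#' @param ab the matching [absorption_summary()].
#' @param k_max highest moment of the reaching time (1..10).
#' @param truncation_tol maximum untabulated tail mass of the PMF.
#' @return Object of class `reach_result`: `p_win`, `p_lose` (named over
#'   complement states), `time_moments` (a `moment_table` with `NA` for
#'   non-winner states), `time_pmf` (a `pmf_table`, support from 1), and
#'   logical `defined`.
#' @examples
#' fx <- fulmar_fixture()
#' an <- set_analysis(fx$chain, fx$Bb)
#' reach_statistics(an$conditional, an$absorption)$time_moments$mean
#' @export
reach_statistics <- function(cond, ab, k_max = 2L, truncation_tol = 1e-9) {
  stopifnot(inherits(cond, "conditional_chain"),
            inherits(ab, "absorption_summary"))
  part <- cond$part
  a <- part$alpha
  if (a == 0L) soc_stop("NoWinners", "target set is the whole transient set")
  k_max <- as.integer(k_max)
  if (k_max < 1L || k_max > 10L) {
    soc_stop("ParseError", "k_max must be between 1 and 10")
  }
  defined <- cond$defined
  w <- which(defined)
  mom <- matrix(NA_real_, k_max, a)
  mom[, w] <- moment_recursion(cond$NC, k_max)
  mt <- new_moment_table(mom, part$labels_Bc,
                         paste0("t_B -> {", paste(part$labels_B, collapse = ", "), "}"))

  # PMF over winners: iterate s_n = 1' UC^n; P(t_B = n) = s_{n-1} - s_n.
  UCw <- cond$UC[w, w, drop = FALSE]
  nw <- length(w)
  s <- rep(1, nw)
  rows <- list()
  n <- 0L
  while (max(c(s, 0)) > truncation_tol) {
    if (n >= .n_cap) {
      soc_stop("TailNotCertified",
               sprintf("tail mass not below %g within %g support points",
                       truncation_tol, .n_cap))
    }
    n <- n + 1L
    s_new <- as.vector(s %*% UCw)
    rows[[n]] <- s - s_new
    s <- s_new
  }
  if (n == 0L) { rows[[1]] <- rep(0, nw); n <- 1L }
  probs <- matrix(NA_real_, a, n)
  probs[w, ] <- do.call(cbind, rows)
  tails <- rep(NA_real_, a)
  tails[w] <- s
  pmf <- new_pmf_table(seq_len(n), probs, tails, truncation_tol,
                       part$labels_Bc)
  structure(list(p_win = ab$pa, p_lose = 1 - ab$pa,
                 time_moments = mt, time_pmf = pmf, defined = defined,
                 part = part),
            class = "reach_result")
}

#' Returning to the target set: return probabilities and return-time statistics
#'
#' After a visit to the target set an individual either re-enters it later
#' (possibly after an excursion outside) or dies first. The return
#' probabilities are `pr = colSums(US)`. Conditional on returning, the
#' return time `mu` equals 1 if the first step stays inside the set
#' (probabilities `colSums(Win)`), and `1 + t_B` from the exit state
#' otherwise (exit-state weights `Wout`), giving
#' `P(mu = n) = 1'(I - UC) UC^(n-2) Wout` for `n >= 2`,
#' `E[mu] = 1 + Wout' t_B^1` and
#' `Var(mu) = Wout' t_B^2 - (Wout' t_B^1)^2`. Higher moments use
#' `E[mu^k] = 1' Win + Wout' sum_r choose(k, r) t_B^r` (with `t_B^0 = 1`),
#' which reduces to the mean/variance formulas at k = 1, 2.
#'
#' @param sub a [sub_chain()].
#' @param cond the matching [conditional_chain()] (may be `NULL` when the
#'   target set is the whole transient set, in which case `mu == 1`).
#' @param reach optionally a precomputed [reach_statistics()] result (its
#'   moments are reused; otherwise they are recomputed).
#' @param k_max highest moment of the return time (1..10).
#' @param truncation_tol maximum untabulated tail mass of the PMF.
#' @return Object of class `return_result`: `p_return` (named over target
#'   states), `time_moments` (`moment_table`, `NA` where `pr = 0`),
#'   `time_pmf` (support from 1), and logical `defined`.
#' @examples
#' fx <- fulmar_fixture()
#' an <- set_analysis(fx$chain, fx$Bb)
#' return_statistics(an$sub, an$conditional)$time_moments$mean
#' @export
return_statistics <- function(sub, cond = NULL, reach = NULL, k_max = 2L,
                              truncation_tol = 1e-9) {
  stopifnot(inherits(sub, "sub_chain"))
  part <- sub$part
  b <- part$beta
  defined <- sub$defined_r
  if (!any(defined)) soc_stop("NoReturners", "no target state can return")
  k_max <- as.integer(k_max)
  if (k_max < 1L || k_max > 10L) {
    soc_stop("ParseError", "k_max must be between 1 and 10")
  }

  d <- which(defined)
  p1 <- colSums(sub$Win)[d]                       # P(mu = 1), Win columns sum
  has_out <- part$alpha > 0 && !is.null(cond)
  if (has_out) {
    w <- which(cond$defined)
    Woutw <- sub$Wout[w, d, drop = FALSE]
    Woutw[is.na(Woutw)] <- 0
    tB <- moment_recursion(cond$NC, k_max)        # k_max x n_winners
  } else {
    w <- integer(0)
    Woutw <- matrix(0, 0, length(d))
    tB <- matrix(0, k_max, 0)
  }

  # Moments: E[mu^k] = 1'Win + Wout' sum_{r=0..k} choose(k,r) tB^r, tB^0 = 1.
  mom <- matrix(NA_real_, k_max, b)
  for (k in seq_len(k_max)) {
    acc <- rep(1, length(w))                      # r = 0 term
    for (r in seq_len(k)) acc <- acc + choose(k, r) * tB[r, ]
    mom[k, d] <- p1 + as.vector(crossprod(Woutw, acc))
  }
  mt <- new_moment_table(mom, part$labels_B,
                         paste0("mu -> {", paste(part$labels_B, collapse = ", "), "}"))
  # Mean and variance also via the closed forms, as the canonical fields.
  tB1 <- if (ncol(tB) > 0) tB[1, ] else numeric(0)
  tB2 <- if (k_max >= 2 && ncol(tB) > 0) tB[2, ] else numeric(0)
  mean_mu <- rep(NA_real_, b)
  mean_mu[d] <- 1 + as.vector(crossprod(Woutw, tB1))
  var_mu <- rep(NA_real_, b)
  if (k_max >= 2) {
    a1 <- as.vector(crossprod(Woutw, tB1))
    var_mu[d] <- as.vector(crossprod(Woutw, tB2)) - a1^2
  }
  names(mean_mu) <- names(var_mu) <- part$labels_B

  # PMF: P(mu = 1) = 1'Win; P(mu = n) = [1'(I-UC) UC^(n-2)] Wout, n >= 2.
  rows <- list()
  rows[[1]] <- { p <- rep(NA_real_, b); p[d] <- p1; p }
  if (has_out && nrow(Woutw) > 0) {
    UCw <- cond$UC[w, w, drop = FALSE]
    s <- rep(1, length(w))                        # s_m = 1' UC^m
    n <- 1L
    repeat {
      tail_now <- as.vector(s %*% Woutw)          # P(mu > n) per defined state
      if (max(c(tail_now, 0)) <= truncation_tol) break
      if (n >= .n_cap) {
        soc_stop("TailNotCertified",
                 sprintf("tail mass not below %g within %g support points",
                         truncation_tol, .n_cap))
      }
      n <- n + 1L
      s_new <- as.vector(s %*% UCw)
      p <- rep(NA_real_, b)
      p[d] <- as.vector((s - s_new) %*% Woutw)
      rows[[n]] <- p
      s <- s_new
    }
    tails <- rep(NA_real_, b)
    tails[d] <- as.vector(s %*% Woutw)
  } else {
    tails <- rep(NA_real_, b)
    tails[d] <- 0
    n <- 1L
  }
  probs <- do.call(cbind, rows)
  pmf <- new_pmf_table(seq_len(n), probs, tails, truncation_tol,
                       part$labels_B)
  structure(list(p_return = sub$pr, time_moments = mt, time_pmf = pmf,
                 mean = mean_mu, variance = var_mu,
                 defined = defined, part = part),
            class = "return_result")
}
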