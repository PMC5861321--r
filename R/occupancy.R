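# Occupancy time in the target set: tau_B counts the time steps spent in B
# over a lifetime. For a start inside B it is the number of transient steps
# of the sub-chain; for a start outside B it is 0 if the set is never
# reached, otherwise (strong Markov property) the occupancy of the first
# target state hit, mixed with weights A.

# k-th moments of the number of transient steps of an absorbing chain with
# fundamental matrix N, per starting state:
#   m1 = N' 1,   mk = (N' - I) sum_{r<k} choose(k,r) mr + m1.
moment_recursion <- function(N, k_max) {
  n <- nrow(N)
  out <- matrix(0, k_max, n)
  if (n == 0L) return(out)
  Nt <- t(N)
  m1 <- as.vector(Nt %*% rep(1, n))
  out[1, ] <- m1
  if (k_max >= 2) {
    NtI <- Nt - diag(n)
    for (k in 2:k_max) {
      acc <- rep(0, n)
      for (r in seq_len(k - 1)) acc <- acc + choose(k, r) * out[r, ]
      out[k, ] <- as.vector(NtI %*% acc) + m1
    }
  }
  out
}

new_moment_table <- function(moments, labels, set) {
  colnames(moments) <- labels
  rownames(moments) <- paste0("k", seq_len(nrow(moments)))
  mean <- stats::setNames(as.vector(moments[1, ]), labels)
  variance <- if (nrow(moments) >= 2) as.vector(moments[2, ]) - mean^2 else
    rep(NA_real_, length(mean))
  variance <- stats::setNames(pmax(variance, 0), labels)  # clip round-off
  sd <- sqrt(variance)
  cv <- ifelse(mean > 0, sd / mean, NA_real_)
  structure(list(k_max = nrow(moments), moments = moments, mean = mean,
                 variance = variance, sd = sd, cv = cv,
                 labels = labels, set = set),
            class = "moment_table")
}

#' @export
print.moment_table <- function(x, digits = 4, ...) {
  cat(sprintf("Moments of occupancy-type time (set: %s)\n", x$set))
  tab <- rbind(mean = x$mean, variance = x$variance, sd = x$sd, cv = x$cv)
  print(round(tab, digits))
  invisible(x)
}

#' Moments of the occupancy time in the target set
#'
#' Computes the k-th moments of `tau_B`, the number of time steps spent in
#' the target set over a lifetime, for every initial state. Starts inside
#' the set use the sub-chain fundamental matrix `NS`; starts outside mix the
#' inside moments with the first-hit probabilities `A` (losers contribute
#' occupancy 0). Results are reported in the original state order.
#'
#' @param sub a [sub_chain()].
#' @param ab the matching [absorption_summary()].
#' @param k_max highest moment (1..10; the binomial weights in the recursion
#'   grow factorially, so higher orders are not supported).
#' @return A `moment_table`: list with `moments` (`k_max` x omega matrix),
#'   `mean`, `variance`, `sd`, `cv`, all named by state.
#' @examples
#' fx <- fulmar_fixture()
#' an <- set_analysis(fx$chain, fx$Bb)
#' occupancy_moments(an$sub, an$absorption)$mean
#' @export
occupancy_moments <- function(sub, ab, k_max = 2L) {
  stopifnot(inherits(sub, "sub_chain"), inherits(ab, "absorption_summary"))
  k_max <- as.integer(k_max)
  if (k_max < 1L || k_max > 10L) {
    soc_stop("ParseError", "k_max must be between 1 and 10")
  }
  part <- sub$part
  min_k <- moment_recursion(sub$NS, k_max)            # k_max x beta
  mout_k <- if (part$alpha > 0) min_k %*% ab$A else
    matrix(0, k_max, 0)                                # tau_out^k = A' tau_in^k
  moments <- matrix(0, k_max, part$alpha + part$beta)
  # column k of cbind(out, in) belongs to original state perm[k]
  moments[, part$perm] <- cbind(mout_k, min_k)
  new_moment_table(moments, part$chain$labels,
                   paste0("{", paste(part$labels_B, collapse = ", "), "}"))
}

#' Variance of the occupancy time (direct route)
#'
#' Computes `Var(tau_B)` directly from the sub-chain fundamental matrix:
#' `1' NS (2 NS - I) - (1' NS) o (1' NS)` for starts inside the set, and the
#' same expression post-multiplied by `A` for starts outside. Algebraically
#' identical to the second-moment route of [occupancy_moments()]; both are
#' exposed because their agreement is a useful numerical check.
#'
#' @inheritParams occupancy_moments
#' @return Named variance vector over all initial states, original order.
#' @export
occupancy_variance <- function(sub, ab) {
  stopifnot(inherits(sub, "sub_chain"), inherits(ab, "absorption_summary"))
  part <- sub$part
  NS <- sub$NS
  v <- colSums(NS)                                   # 1' NS
  w <- as.vector(v %*% (2 * NS - diag(part$beta)))   # 1' NS (2 NS - I)
  var_in <- w - v^2
  if (part$alpha > 0) {
    vo <- as.vector(v %*% ab$A)
    var_out <- as.vector(w %*% ab$A) - vo^2
  } else var_out <- numeric(0)
  out <- numeric(part$alpha + part$beta)
  out[part$perm] <- c(var_out, var_in)
  names(out) <- part$chain$labels
  pmax(out, 0)
}

new_pmf_table <- function(support, probs, tail_mass, truncation_tol, labels) {
  dimnames(probs) <- list(labels, paste0("n", support))
  names(tail_mass) <- labels
  structure(list(support = support, probs = probs, tail_mass = tail_mass,
                 truncation_tol = truncation_tol, labels = labels),
            class = "pmf_table")
}

#' @export
print.pmf_table <- function(x, max_cols = 8, digits = 4, ...) {
  cat(sprintf("Truncated PMF, support %d..%d (certified tail <= %.3g)\n",
              min(x$support), max(x$support), max(x$tail_mass, na.rm = TRUE)))
  k <- min(max_cols, ncol(x$probs))
  print(round(x$probs[, seq_len(k), drop = FALSE], digits))
  if (ncol(x$probs) > k) cat("...", ncol(x$probs) - k, "more support points\n")
  invisible(x)
}

#' Mean and variance implied by a truncated PMF
#'
#' Summaries computed from the tabulated mass only; accurate to within the
#' certified tail bound. Mainly used to cross-check the closed-form moments.
#'
#' @param pmf a `pmf_table`.
#' @return List with named vectors `mean` and `variance`.
#' @export
pmf_summary <- function(pmf) {
  stopifnot(inherits(pmf, "pmf_table"))
  n <- pmf$support
  m1 <- as.vector(pmf$probs %*% n)
  m2 <- as.vector(pmf$probs %*% n^2)
  names(m1) <- names(m2) <- pmf$labels
  list(mean = m1, variance = m2 - m1^2)
}

.n_cap <- 1e6  # hard cap on PMF support length

#' Distribution of the occupancy time in the target set
#'
#' Exact probability mass function of `tau_B`, truncated once the certified
#' tail mass drops below `truncation_tol`. For a start inside the set,
#' `P(tau = n) = 1'(I - US) US^(n-1)` for `n >= 1`; for a start outside,
#' `P(tau = 0) = 1 - pa` and `P(tau = n) = 1'(I - US) US^(n-1) A`. The tail
#' beyond the last tabulated `n` is exactly `1' US^n` (inside starts) and
#' `1' US^n A` (outside starts), both tracked during the iteration, so the
#' reported `tail_mass` is exact, not a bound.
#'
#' @inheritParams occupancy_moments
#' @param truncation_tol maximum tail mass left untabulated (in (0, 0.01]).
#' @return A `pmf_table` with support `0..n_max`, rows in original state
#'   order, and per-state `tail_mass`.
#' @examples
#' fx <- fulmar_fixture()
#' an <- set_analysis(fx$chain, fx$Bb)
#' pmf <- occupancy_distribution(an$sub, an$absorption, truncation_tol = 1e-6)
#' pmf$probs[, 1:5]
#' @export
occupancy_distribution <- function(sub, ab, truncation_tol = 1e-9) {
  stopifnot(inherits(sub, "sub_chain"), inherits(ab, "absorption_summary"))
  if (truncation_tol <= 0 || truncation_tol > 0.01) {
    soc_stop("ParseError", "truncation_tol must be in (0, 0.01]")
  }
  part <- sub$part
  US <- sub$US
  A <- ab$A
  beta <- part$beta
  s <- rep(1, beta)                     # s_n = 1' US^n, starts at n = 0
  p_in <- list(); p_out <- list()
  p_in[[1]] <- rep(0, beta)             # P(tau_in = 0) = 0
  p_out[[1]] <- if (part$alpha > 0) 1 - ab$pa else numeric(0)
  n <- 0L
  repeat {
    tail_in <- s
    tail_out <- if (part$alpha > 0) as.vector(s %*% A) else numeric(0)
    if (max(c(tail_in, tail_out, 0)) <= truncation_tol) break
    if (n >= .n_cap) {
      soc_stop("TailNotCertified",
               sprintf("tail mass not below %g within %g support points",
                       truncation_tol, .n_cap))
    }
    n <- n + 1L
    s_new <- as.vector(s %*% US)
    d <- s - s_new
    p_in[[n + 1L]] <- d
    p_out[[n + 1L]] <- if (part$alpha > 0) as.vector(d %*% A) else numeric(0)
    s <- s_new
  }
  tail_out <- if (part$alpha > 0) as.vector(s %*% A) else numeric(0)
  probs <- matrix(0, part$alpha + part$beta, n + 1L)
  for (i in seq_len(n + 1L)) {
    probs[part$perm, i] <- c(p_out[[i]], p_in[[i]])
  }
  tails <- numeric(part$alpha + part$beta)
  tails[part$perm] <- c(tail_out, s)
  new_pmf_table(0:n, probs, tails, truncation_tol, part$chain$labels)
}
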