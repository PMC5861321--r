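#' @keywords internal
"_PACKAGE"

# Classed conditions so callers can distinguish failure modes programmatically.
soc_stop <- function(class, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "setoccupancy_error", "error", "condition")))
}

.tol_prob <- 1e-12

#' Define and validate a demographic absorbing Markov chain
#'
#' A demographic chain is specified by its transient transition matrix `U`,
#' column-oriented: entry `(i, j)` is the probability that an individual in
#' state `j` is in state `i` one time step later. Columns sum to at most 1;
#' the deficit of column `j` is the one-step probability of death from state
#' `j`, so the mortality vector is `m = 1 - colSums(U)`. Validation requires
#' absorption to be certain (spectral radius of `U` strictly below 1), which
#' guarantees that `I - U` is invertible with a nonnegative inverse.
#'
#' @param U square numeric matrix of one-step transition probabilities among
#'   transient states (column = source state).
#' @param labels character vector of distinct state names; defaults to the
#'   dimnames of `U` or `"s1", "s2", ...`.
#' @param tol numeric tolerance on the probability constraints.
#' @return An object of class `demographic_chain`: a list with elements `U`
#'   (with labels as dimnames), `labels`, `m` (named mortality vector), and
#'   `omega` (number of transient states).
#' @examples
#' fx <- fulmar_fixture()
#' chain <- fx$chain
#' chain$m
#' @export
demographic_chain <- function(U, labels = NULL, tol = .tol_prob) {
  if (!is.matrix(U) || !is.numeric(U)) {
    U <- try(as.matrix(U), silent = TRUE)
    if (inherits(U, "try-error") || !is.numeric(U)) {
      soc_stop("ParseError", "`U` must be a numeric matrix")
    }
  }
  if (nrow(U) != ncol(U)) soc_stop("ParseError", "`U` must be square")
  if (any(!is.finite(U))) soc_stop("ParseError", "`U` has non-finite entries")
  omega <- nrow(U)

  if (is.null(labels)) {
    labels <- colnames(U)
    if (is.null(labels)) labels <- paste0("s", seq_len(omega))
  }
  labels <- as.character(labels)
  if (length(labels) != omega || anyDuplicated(labels) > 0) {
    soc_stop("LabelMismatch",
             sprintf("need %d distinct state labels, got %d (%d duplicated)",
                     omega, length(labels), sum(duplicated(labels))))
  }

  if (any(U < -tol)) {
    bad <- which(U < -tol, arr.ind = TRUE)[1, ]
    soc_stop("NegativeEntry",
             sprintf("negative transition probability at (%s, %s)",
                     labels[bad[1]], labels[bad[2]]))
  }
  if (any(U > 1 + tol)) {
    bad <- which(U > 1 + tol, arr.ind = TRUE)[1, ]
    soc_stop("NegativeEntry",
             sprintf("transition probability > 1 at (%s, %s)",
                     labels[bad[1]], labels[bad[2]]))
  }
  cs <- colSums(U)
  if (any(cs > 1 + tol)) {
    j <- which.max(cs)
    soc_stop("ColumnSumExceedsOne",
             sprintf("column '%s' sums to %.12g > 1", labels[j], cs[j]))
  }

  if (!is_convergent(U)) {
    soc_stop("NotConvergent",
             "absorption is not certain: spectral radius of U is not < 1")
  }

  dimnames(U) <- list(labels, labels)
  m <- 1 - cs
  m[m < 0] <- 0  # clip round-off only; true violations were rejected above
  names(m) <- labels
  structure(list(U = U, labels = labels, m = m, omega = omega),
            class = "demographic_chain")
}

# Certain absorption <=> spectral radius < 1. Checked by repeated squaring of
# U (the 1-norm of U^(2^k) must eventually drop below 1), which is robust for
# reducible matrices, then confirmed by a residual check on solve(I - U, 1).
is_convergent <- function(U, max_doublings = 64L) {
  if (nrow(U) == 0L) return(TRUE)
  M <- U
  ok <- FALSE
  for (k in seq_len(max_doublings)) {
    nrm <- max(colSums(abs(M)))
    if (nrm < 1 - .tol_prob) { ok <- TRUE; break }
    if (!is.finite(nrm)) return(FALSE)
    M <- M %*% M
  }
  if (!ok) return(FALSE)
  I <- diag(nrow(U))
  x <- try(solve(I - U, rep(1, nrow(U))), silent = TRUE)
  if (inherits(x, "try-error")) return(FALSE)
  resid <- max(abs((I - U) %*% x - 1))
  is.finite(resid) && resid < 1e-8
}

#' @export
print.demographic_chain <- function(x, ...) {
  cat(sprintf("Demographic absorbing Markov chain: %d transient states\n",
              x$omega))
  cat("States:", paste(x$labels, collapse = ", "), "\n")
  cat("Mortality m = 1 - colSums(U):\n")
  print(round(x$m, 4))
  invisible(x)
}

# Resolve a target set given as labels or indices to sorted 0ne-based indices.
resolve_set <- function(chain, B) {
  if (length(B) == 0L) soc_stop("EmptyTargetSet", "target set is empty")
  if (is.character(B)) {
    idx <- match(B, chain$labels)
    if (any(is.na(idx))) {
      soc_stop("LabelMismatch",
               sprintf("unknown state label(s): %s",
                       paste(B[is.na(idx)], collapse = ", ")))
    }
  } else {
    idx <- as.integer(B)
    if (any(is.na(idx)) || any(idx < 1L) || any(idx > chain$omega)) {
      soc_stop("IndexOutOfRange",
               sprintf("target indices must be in 1..%d", chain$omega))
    }
  }
  if (anyDuplicated(idx) > 0) soc_stop("IndexOutOfRange",
                                       "duplicated states in target set")
  sort(idx)
}

#' Partition a chain by a target set
#'
#' Reorders the states so that the complement of the target set comes first
#' and splits `U` into the four blocks `UK` (within-complement transitions),
#' `K` (complement to target), `L` (target to complement) and `Q` (within
#' target). The permutation is recorded so downstream results can always be
#' reported in the user's original state order.
#'
#' @param chain a [demographic_chain()].
#' @param B target set: state labels or indices (any nonempty subset, in any
#'   order; renumbering is internal).
#' @return An object of class `partitioned_chain` with elements `UK`
#'   (alpha x alpha), `K` (beta x alpha), `L` (alpha x beta), `Q`
#'   (beta x beta), `m_alpha` (deaths from complement states), the index sets
#'   `B`, `Bc`, sizes `alpha`, `beta`, and the permutation `perm` such that
#'   `U[perm, perm]` is the reordered matrix.
#' @examples
#' fx <- fulmar_fixture()
#' part <- partition_chain(fx$chain, fx$Bb)
#' part$Q
#' @export
partition_chain <- function(chain, B) {
  stopifnot(inherits(chain, "demographic_chain"))
  Bidx <- resolve_set(chain, B)
  Bc <- setdiff(seq_len(chain$omega), Bidx)
  alpha <- length(Bc)
  beta <- length(Bidx)
  perm <- c(Bc, Bidx)
  Ur <- chain$U[perm, perm, drop = FALSE]
  UK <- Ur[seq_len(alpha), seq_len(alpha), drop = FALSE]
  K  <- Ur[alpha + seq_len(beta), seq_len(alpha), drop = FALSE]
  L  <- Ur[seq_len(alpha), alpha + seq_len(beta), drop = FALSE]
  Q  <- Ur[alpha + seq_len(beta), alpha + seq_len(beta), drop = FALSE]
  structure(list(chain = chain, B = Bidx, Bc = Bc,
                 alpha = alpha, beta = beta, perm = perm,
                 UK = UK, K = K, L = L, Q = Q,
                 m_alpha = chain$m[Bc],
                 labels_B = chain$labels[Bidx],
                 labels_Bc = chain$labels[Bc]),
            class = "partitioned_chain")
}

#' Reassemble the original transition matrix from a partition
#'
#' Inverse of [partition_chain()]: puts the four blocks back and undoes the
#' permutation. Used to verify that partitioning is lossless.
#'
#' @param part a `partitioned_chain`.
#' @return The original matrix `U`, bit-identical to `chain$U`.
#' @export
reassemble_chain <- function(part) {
  a <- part$alpha; b <- part$beta
  Ur <- matrix(0, a + b, a + b)
  if (a > 0) {
    Ur[seq_len(a), seq_len(a)] <- part$UK
    Ur[a + seq_len(b), seq_len(a)] <- part$K
    Ur[seq_len(a), a + seq_len(b)] <- part$L
  }
  Ur[a + seq_len(b), a + seq_len(b)] <- part$Q
  inv <- order(part$perm)
  U <- Ur[inv, inv, drop = FALSE]
  dimnames(U) <- dimnames(part$chain$U)
  U
}

#' Fundamental matrix of a substochastic matrix
#'
#' Computes `N = (I - M)^{-1}` by a linear solve. Entry `(i, j)` of `N` is
#' the expected number of visits to state `i`, starting from state `j`,
#' before absorption.
#'
#' @param M square substochastic matrix with spectral radius < 1.
#' @return The fundamental matrix, same dimnames as `M`.
#' @examples
#' fundamental_matrix(matrix(0.5)) # 2: mean geometric number of visits
#' @export
fundamental_matrix <- function(M) {
  n <- nrow(M)
  if (n == 0L) return(matrix(0, 0, 0))
  I <- diag(n)
  N <- try(solve(I - M, I), silent = TRUE)
  if (inherits(N, "try-error")) {
    soc_stop("Singular", "I - M is numerically singular")
  }
  dimnames(N) <- dimnames(M)
  N
}

#' Variance of single-state occupancy times
#'
#' The classical companion to the fundamental matrix: entry `(i, j)` of `V`
#' is the variance of the number of visits to state `i` for an individual
#' starting in state `j`, computed as
#' `V = (2 I \%*\% diag(N) - I) N - N o N` where `o` is the Hadamard product.
#'
#' @param chain a [demographic_chain()].
#' @return omega x omega variance matrix with state labels.
#' @export
single_state_occupancy_variance <- function(chain) {
  stopifnot(inherits(chain, "demographic_chain"))
  N <- fundamental_matrix(chain$U)
  I <- diag(chain$omega)
  V <- (2 * (I * N) - I) %*% N - N * N
  dimnames(V) <- dimnames(N)
  V
}

#' Moments of longevity
#'
#' Longevity is the occupancy time of the entire transient set: the number
#' of time steps from the initial state to death. The mean is the column sum
#' of the fundamental matrix; variance and higher moments are obtained by
#' treating the whole transient set as the target set, so the set-occupancy
#' machinery and the classical result coincide.
#'
#' @param chain a [demographic_chain()].
#' @param k_max highest moment to compute (default 2).
#' @return A `moment_table` (see [occupancy_moments()]) over initial states.
#' @examples
#' fx <- fulmar_fixture()
#' longevity_moments(fx$chain)$mean
#' @export
longevity_moments <- function(chain, k_max = 2L) {
  stopifnot(inherits(chain, "demographic_chain"))
  an <- set_analysis(chain, seq_len(chain$omega))
  mt <- occupancy_moments(an$sub, an$absorption, k_max = k_max)
  mt$set <- "T (all transient states)"
  mt
}
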