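# Fixtures built in code.

# The Southern Fulmar ordinary-condition matrix, written out explicitly so
# tests of the file reader have an independent copy to compare against.
fulmar_U <- matrix(c(
  0.90, 0.00, 0.00, 0.00,
  0.00, 0.63, 0.07, 0.18,
  0.01, 0.18, 0.67, 0.49,
  0.01, 0.09, 0.19, 0.24), nrow = 4, byrow = TRUE)
fulmar_labels <- c("pre-breeder", "non-breeder",
                   "successful breeder", "failed breeder")

fulmar_chain <- function() demographic_chain(fulmar_U, fulmar_labels)

# Random substochastic chain with certain absorption (column sums <= 0.95).
random_chain <- function(omega, sparsity = 0.3) {
  U <- matrix(stats::runif(omega^2), omega)
  U[matrix(stats::runif(omega^2) < sparsity, omega)] <- 0
  cs <- colSums(U)
  target <- stats::runif(omega, 0.2, 0.95)
  for (j in seq_len(omega)) {
    if (cs[j] > 0) U[, j] <- U[, j] * (target[j] / cs[j])
  }
  demographic_chain(U)
}

random_set <- function(omega, size = sample(omega, 1)) {
  sort(sample(omega, size))
}

# Independent oracle for the fundamental matrix: truncated Neumann series
# sum_n M^n, stopped when the increment is negligible.
neumann_fundamental <- function(M, tol = 1e-13, max_terms = 1e6) {
  n <- nrow(M)
  N <- diag(n)
  P <- diag(n)
  for (i in seq_len(max_terms)) {
    P <- P %*% M
    if (max(abs(P)) < tol) break
    N <- N + P
  }
  N
}

# Single-transient-state chain with self-loop u (geometric occupancy).
geom_chain <- function(u) demographic_chain(matrix(u), "s1")
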