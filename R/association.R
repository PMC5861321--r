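# Covariance and correlation between the occupancy times of two sets.
# Means of occupancy times add over disjoint sets, variances do not: the
# cross term is recovered from the polarisation identity
#   Cov(tau_B1, tau_B2) = (Var tau_{B1 u B2} - Var tau_B1 - Var tau_B2) / 2
# for disjoint sets, and overlapping sets are decomposed into the pairwise
# disjoint pieces C1 = B1 \ B2, C2 = B2 \ B1, C3 = B1 n B2.

# Mean and variance vectors of tau_B in original state order.
set_occupancy_mv <- function(chain, Bidx) {
  an <- set_analysis(chain, Bidx)
  mt <- occupancy_moments(an$sub, an$absorption, k_max = 2L)
  list(mean = mt$mean, var = mt$variance)
}

#' Covariance of occupancy times of two disjoint sets
#'
#' Uses the polarisation identity
#' `Cov = (Var tau_{B1 u B2} - Var tau_B1 - Var tau_B2) / 2`, with each
#' variance computed by the set-occupancy machinery. All vectors are aligned
#' to the original state order before combining.
#'
#' @param chain a [demographic_chain()].
#' @param B1,B2 disjoint nonempty target sets (labels or indices).
#' @return Named covariance vector over initial states.
#' @examples
#' fx <- fulmar_fixture()
#' covariance_disjoint(fx$chain, "successful breeder", "failed breeder")
#' @export
covariance_disjoint <- function(chain, B1, B2) {
  stopifnot(inherits(chain, "demographic_chain"))
  i1 <- resolve_set(chain, B1)
  i2 <- resolve_set(chain, B2)
  if (length(intersect(i1, i2)) > 0) {
    soc_stop("SetsOverlap", "B1 and B2 must be disjoint")
  }
  vu <- set_occupancy_mv(chain, union(i1, i2))$var
  v1 <- set_occupancy_mv(chain, i1)$var
  v2 <- set_occupancy_mv(chain, i2)$var
  (vu - v1 - v2) / 2
}

new_association_result <- function(cov, corr, var1, var2, decomposition) {
  structure(list(cov = cov, corr = corr, var1 = var1, var2 = var2,
                 decomposition = decomposition),
            class = "association_result")
}

#' @export
print.association_result <- function(x, digits = 4, ...) {
  tab <- rbind(cov = x$cov, corr = x$corr)
  print(round(tab, digits))
  invisible(x)
}

#' Covariance and correlation of occupancy times of two (possibly
#' overlapping) sets
#'
#' Splits `B1 u B2` into the pairwise disjoint pieces `C1 = B1` minus `B2`,
#' `C2 = B2` minus `B1`, and `C3 = B1 n B2`; then
#' `Cov(tau_B1, tau_B2) = Cov(C1,C2) + Cov(C1,C3) + Cov(C2,C3) + Var(C3)`,
#' with each pairwise covariance from [covariance_disjoint()] and empty
#' pieces contributing zero. The correlation divides by the two standard
#' deviations and is `NA` for initial states where either variance is zero.
#'
#' @param chain a [demographic_chain()].
#' @param B1,B2 nonempty target sets (labels or indices).
#' @return An `association_result`: named vectors `cov` and `corr` over
#'   initial states, the two variance vectors, and the decomposition used.
#' @examples
#' fx <- fulmar_fixture()
#' covariance_sets(fx$chain, fx$Ba, fx$Bb)$corr
#' @export
covariance_sets <- function(chain, B1, B2) {
  stopifnot(inherits(chain, "demographic_chain"))
  i1 <- resolve_set(chain, B1)
  i2 <- resolve_set(chain, B2)
  C1 <- setdiff(i1, i2)
  C2 <- setdiff(i2, i1)
  C3 <- intersect(i1, i2)
  zero <- stats::setNames(numeric(chain$omega), chain$labels)
  cov_pair <- function(a, b) {
    if (length(a) == 0 || length(b) == 0) zero else
      covariance_disjoint(chain, a, b)
  }
  varC3 <- if (length(C3) > 0) set_occupancy_mv(chain, C3)$var else zero
  cv <- cov_pair(C1, C2) + cov_pair(C1, C3) + cov_pair(C2, C3) + varC3
  v1 <- set_occupancy_mv(chain, i1)$var
  v2 <- set_occupancy_mv(chain, i2)$var
  denom <- sqrt(v1 * v2)
  corr <- ifelse(denom > 0, cv / denom, NA_real_)
  new_association_result(cv, corr, v1, v2,
                         list(C1 = chain$labels[C1], C2 = chain$labels[C2],
                              C3 = chain$labels[C3]))
}

#' Correlation between set occupancy time and longevity
#'
#' Longevity is the occupancy time of the whole transient set, so
#' `Corr(tau_B, eta) = (Cov(tau_B, tau_Bc) + Var tau_B) /
#' sqrt(Var tau_B * Var eta)` — the second set in [covariance_sets()]
#' specialised to all transient states. When `B` is the whole set the
#' correlation is 1 wherever `Var(eta) > 0`.
#'
#' @param chain a [demographic_chain()].
#' @param B nonempty target set (labels or indices).
#' @return An `association_result` (see [covariance_sets()]).
#' @examples
#' fx <- fulmar_fixture()
#' correlation_with_longevity(fx$chain, fx$Bb)$corr
#' @export
correlation_with_longevity <- function(chain, B) {
  stopifnot(inherits(chain, "demographic_chain"))
  i1 <- resolve_set(chain, B)
  Bc <- setdiff(seq_len(chain$omega), i1)
  vB <- set_occupancy_mv(chain, i1)$var
  vEta <- set_occupancy_mv(chain, seq_len(chain$omega))$var
  covBBc <- if (length(Bc) > 0) covariance_disjoint(chain, i1, Bc) else
    stats::setNames(numeric(chain$omega), chain$labels)
  cv <- covBBc + vB
  denom <- sqrt(vB * vEta)
  corr <- ifelse(denom > 0, cv / denom, NA_real_)
  new_association_result(cv, corr, vB, vEta,
                         list(C1 = character(0),
                              C2 = chain$labels[Bc],
                              C3 = chain$labels[i1]))
}
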