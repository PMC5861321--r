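# Induced chains: the killed chain (stopped at first entry into B), the
# conditional chain (killed chain conditioned on reaching B), and the
# sub-chain (the original chain watched only while in B; one step = one
# excursion that returns to B, or death).

.tol_pa <- 1e-14  # below this a reach/return probability is a structural zero

#' Killed Markov chain
#'
#' A copy of the original chain stopped as soon as it enters the target set:
#' the target states and death become absorbing, the complement states stay
#' transient. `MK` stacks the target-entry block `K` over the mortality row,
#' so the columns of `rbind(UK, MK)` sum to one.
#'
#' @param part a [partition_chain()] result.
#' @return Object of class `killed_chain`: `UK` (alpha x alpha), `MK`
#'   ((beta+1) x alpha; rows = target states then "dead"), `NK` (fundamental
#'   matrix of `UK`), plus the partition in `$part`. When the complement is
#'   empty (B = all states) all blocks have zero columns.
#' @examples
#' fx <- fulmar_fixture()
#' killed_chain(partition_chain(fx$chain, fx$Bb))$MK
#' @export
killed_chain <- function(part) {
  stopifnot(inherits(part, "partitioned_chain"))
  MK <- rbind(part$K, dead = part$m_alpha)
  rownames(MK) <- c(part$labels_B, "dead")
  NK <- fundamental_matrix(part$UK)
  structure(list(UK = part$UK, MK = MK, NK = NK, part = part),
            class = "killed_chain")
}

#' Absorption probabilities of the killed chain
#'
#' `A = K NK` gives, for each non-target starting state `j`, the probability
#' that the first target state visited is each target state `i`. Its column
#' sums `pa` are the probabilities of ever reaching the target set ("becoming
#' a winner"). `Astar = MK NK` adds the death row, so its columns sum to one.
#'
#' @param kc a [killed_chain()].
#' @return Object of class `absorption_summary`: `A` (beta x alpha), `Astar`
#'   ((beta+1) x alpha), `pa` (named length-alpha vector), `Da = diag(pa)`,
#'   and the partition in `$part`.
#' @examples
#' fx <- fulmar_fixture()
#' absorption_summary(killed_chain(partition_chain(fx$chain, fx$Bb)))$pa
#' @export
absorption_summary <- function(kc) {
  stopifnot(inherits(kc, "killed_chain"))
  part <- kc$part
  A <- kc$part$K %*% kc$NK
  Astar <- kc$MK %*% kc$NK
  pa <- colSums(A)
  names(pa) <- part$labels_Bc
  Da <- diag(pa, nrow = part$alpha)
  structure(list(A = A, Astar = Astar, pa = pa, Da = Da, part = part),
            class = "absorption_summary")
}

#' Conditional Markov chain (winners only)
#'
#' The killed chain conditioned on eventual absorption in the target set.
#' Over the "winner" complement states (those with reach probability
#' `pa > tol_pa`), `UC = Da UK Da^{-1}` and `MC = K Da^{-1}`; the columns of
#' `rbind(UC, MC)` sum to one. States that cannot reach the target set are
#' flagged in `defined` and their columns reported as `NA` — conditioning on
#' a null event is undefined, never silently dropped.
#'
#' @param kc a [killed_chain()].
#' @param ab the matching [absorption_summary()].
#' @param tol_pa reach probabilities at or below this are treated as
#'   structural zeros.
#' @return Object of class `conditional_chain`: `UC`, `MC` (full shapes with
#'   `NA` in undefined columns), `NC` (fundamental matrix of the defined
#'   block of `UC`), logical `defined` over complement states, and `$part`.
#' @examples
#' fx <- fulmar_fixture()
#' part <- partition_chain(fx$chain, fx$Bb)
#' kc <- killed_chain(part)
#' conditional_chain(kc, absorption_summary(kc))$UC
#' @export
conditional_chain <- function(kc, ab, tol_pa = .tol_pa) {
  stopifnot(inherits(kc, "killed_chain"), inherits(ab, "absorption_summary"))
  part <- kc$part
  a <- part$alpha
  defined <- ab$pa > tol_pa
  if (a > 0 && !any(defined)) {
    soc_stop("NoWinners", "no complement state can reach the target set")
  }
  UC <- matrix(NA_real_, a, a, dimnames = list(part$labels_Bc, part$labels_Bc))
  MC <- matrix(NA_real_, part$beta, a,
               dimnames = list(part$labels_B, part$labels_Bc))
  NC <- matrix(0, 0, 0)
  if (a > 0) {
    w <- which(defined)
    paw <- ab$pa[w]
    # UC[i,j] = pa_i * UK[i,j] / pa_j over winners; rows outside the winner
    # set get conditional probability 0 (they cannot lead to B).
    UCw <- (part$UK[w, w, drop = FALSE] * paw) /
      rep(paw, each = length(w))
    UC[, defined] <- 0
    UC[w, w] <- UCw
    MC[, w] <- part$K[, w, drop = FALSE] / rep(paw, each = part$beta)
    NC <- fundamental_matrix(UCw)
  }
  structure(list(UC = UC, MC = MC, NC = NC, defined = defined, part = part),
            class = "conditional_chain")
}

#' Sub-Markov chain on the target set
#'
#' The original chain viewed through a filter that shows only the target
#' states: one sub-chain step is either a direct within-target transition
#' (`Q`) or an excursion through the complement that re-enters the target
#' set (`A L`), so `US = A L + Q`. Death before re-entry absorbs the
#' sub-chain, with probabilities `mS = 1 - colSums(US)`. The column sums
#' `pr = colSums(US)` are the return probabilities; `Win = Q Dr^{-1}` and
#' `Wout = Da L Dr^{-1}` split the first step of a returning excursion into
#' "stayed inside" vs "stepped outside", conditional on return.
#'
#' @param part a [partition_chain()] result.
#' @param ab the matching [absorption_summary()].
#' @param tol_pa return probabilities at or below this are structural zeros;
#'   the corresponding `Win`/`Wout` columns are `NA` (undefined).
#' @return Object of class `sub_chain`: `US`, `mS`, `NS`, `pr`, `Dr`, `Win`
#'   (beta x beta), `Wout` (alpha x beta), logical `defined_r` over target
#'   states, and `$part`.
#' @examples
#' fx <- fulmar_fixture()
#' part <- partition_chain(fx$chain, fx$Bb)
#' sub_chain(part, absorption_summary(killed_chain(part)))$US
#' @export
sub_chain <- function(part, ab, tol_pa = .tol_pa) {
  stopifnot(inherits(part, "partitioned_chain"),
            inherits(ab, "absorption_summary"))
  b <- part$beta
  US <- if (part$alpha > 0) ab$A %*% part$L + part$Q else part$Q
  dimnames(US) <- list(part$labels_B, part$labels_B)
  pr <- colSums(US)
  mS <- 1 - pr
  NS <- fundamental_matrix(US)
  Dr <- diag(pr, nrow = b)
  defined_r <- pr > tol_pa
  Win <- matrix(NA_real_, b, b, dimnames = dimnames(US))
  Wout <- matrix(NA_real_, part$alpha, b,
                 dimnames = list(part$labels_Bc, part$labels_B))
  if (any(defined_r)) {
    d <- defined_r
    Win[, d] <- part$Q[, d, drop = FALSE] / rep(pr[d], each = b)
    if (part$alpha > 0) {
      Wout[, d] <- (ab$pa * part$L[, d, drop = FALSE]) /
        rep(pr[d], each = part$alpha)
    }
  }
  structure(list(US = US, mS = mS, NS = NS, pr = pr, Dr = Dr,
                 Win = Win, Wout = Wout, defined_r = defined_r, part = part),
            class = "sub_chain")
}

#' Build all induced chains for a chain and target set
#'
#' Convenience constructor running [partition_chain()], [killed_chain()],
#' [absorption_summary()], [conditional_chain()] and [sub_chain()] once.
#'
#' @param chain a [demographic_chain()].
#' @param B target set (labels or indices).
#' @param tol_pa structural-zero tolerance for conditioning.
#' @return Object of class `set_analysis` with elements `chain`, `part`,
#'   `killed`, `absorption`, `conditional` (`NULL` when the complement is
#'   empty), and `sub`.
#' @examples
#' fx <- fulmar_fixture()
#' an <- set_analysis(fx$chain, fx$Bb)
#' an$sub$pr
#' @export
set_analysis <- function(chain, B, tol_pa = .tol_pa) {
  part <- partition_chain(chain, B)
  kc <- killed_chain(part)
  ab <- absorption_summary(kc)
  cond <- if (part$alpha > 0 && any(ab$pa > tol_pa)) {
    conditional_chain(kc, ab, tol_pa = tol_pa)
  } else NULL
  sub <- sub_chain(part, ab, tol_pa = tol_pa)
  structure(list(chain = chain, part = part, killed = kc, absorption = ab,
                 conditional = cond, sub = sub),
            class = "set_analysis")
}

#' @export
print.set_analysis <- function(x, digits = 4, ...) {
  cat(sprintf("Set analysis: B = {%s}, complement = {%s}\n",
              paste(x$part$labels_B, collapse = ", "),
              paste(x$part$labels_Bc, collapse = ", ")))
  if (x$part$alpha > 0) {
    cat("Reach probabilities pa:\n"); print(round(x$absorption$pa, digits))
  }
  cat("Sub-chain US:\n"); print(round(x$sub$US, digits))
  cat("Return probabilities pr:\n"); print(round(x$sub$pr, digits))
  invisible(x)
}
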