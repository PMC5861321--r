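---
title: "Occupancy times in sets of states: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Occupancy times in sets of states: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(setoccupancy)
```

## The model

A demographic absorbing Markov chain follows one individual through a finite
set of living (transient) states `T = {1, ..., omega}` until death, the
single absorbing state. The only free input is the transient transition
matrix `U`, column-oriented as is standard in demography: `U[i, j]` is the
probability that an individual in state `j` is in state `i` one step later.
Because death is the only other outcome, the mortality vector is determined
by `U`: `m = 1 - colSums(U)`. Certain absorption — every individual dies
eventually — is equivalent to the spectral radius of `U` being strictly
below one, and it is what makes the fundamental matrix
`N = (I - U)^{-1}` exist with nonnegative entries: `N[i, j]` is the expected
number of time steps spent in state `i` by an individual born in state `j`.

The classical theory gives every moment and the distribution of the
occupancy time of a *single* state, and of longevity (the occupancy of the
whole transient set). The quantity this package targets is the occupancy
time `tau_B` of an arbitrary *set* `B` of states — lifetime breeding
attempts, time spent in a habitat block, healthy life years. Means add
across the states of `B`, so the mean is classical; variances and the
distribution do not, because single-state occupancy times are correlated.

## Induced chains

All results flow from three chains constructed from `U` and `B`
(`set_analysis()` builds them all at once). Write `alpha = |Bc|`,
`beta = |B|`, and split the (internally reordered) matrix into blocks
`UK` (within `Bc`), `K` (`Bc` to `B`), `L` (`B` to `Bc`), `Q` (within `B`).

* **Killed chain** (`killed_chain()`): the original chain stopped at first
  entry into `B`. Its transient block is `UK`; its absorption block `MK`
  stacks `K` over the complement mortalities. From its fundamental matrix
  `NK`, the first-hit matrix is `A = K NK` (`A[i, j]` = probability that the
  first state of `B` visited from complement state `j` is target state `i`)
  and the reach probabilities are `pa = colSums(A)`.
* **Conditional chain** (`conditional_chain()`): the killed chain
  conditioned on reaching `B` ("winners"). With `Da = diag(pa)`,
  `UC = Da UK Da^{-1}` and `MC = K Da^{-1}`. The conditional reaching time
  `t_B` is the total transient occupancy of this chain, so its moments and
  distribution are classical again (`reach_statistics()`).
* **Sub-chain** (`sub_chain()`): the original chain watched only while in
  `B`. One sub-chain step is either a direct within-`B` move (`Q`) or an
  excursion through `Bc` that re-enters `B` (`A L`), hence `US = A L + Q`.
  Death before re-entry absorbs it: `mS = 1 - colSums(US)`. The return
  probabilities are `pr = colSums(US)`; `Win = Q Dr^{-1}` and
  `Wout = Da L Dr^{-1}` split the first step of a returning excursion.

Because `tau_B` counts exactly the transient steps of the sub-chain, its
moments for a start inside `B` come from the sub-chain fundamental matrix
`NS` via the classical recursion with binomial weights
(`occupancy_moments()`), and for a start outside `B` by mixing with the
first-hit weights `A` (the strong Markov property); a start outside that
never reaches `B` contributes occupancy zero with probability `1 - pa`.
The exact distribution is `P(tau = n) = 1'(I - US) US^(n-1)` inside
(post-multiplied by `A` outside), evaluated by accumulating one
matrix-vector product per support point (`occupancy_distribution()`).

The return time `mu` is handled as a two-part mixture, conditional on
return: it equals 1 when the first step stays in `B` (mass `colSums(Win)`),
and `1 + t_B` from the exit state otherwise (weights `Wout`). This
reproduces the closed forms `E[mu] = 1 + Wout' t_B^1` and
`Var(mu) = Wout' t_B^2 - (Wout' t_B^1)^2` at orders one and two, extends to
any order through the binomial expansion of `E[(1 + t_B)^k]`, and is
cross-checked against the return-time distribution in the test suite.

Covariances between two set-occupancy times use the polarisation identity
for disjoint sets,
`Cov = (Var tau_{B1 u B2} - Var tau_B1 - Var tau_B2) / 2`, and for
overlapping sets the decomposition into the pairwise disjoint pieces
`B1 \ B2`, `B2 \ B1`, `B1 n B2` (`covariance_sets()`). A general
cross-covariance formula for arbitrary disjoint pairs exists in the
literature; since the three decomposition pieces are pairwise disjoint, the
polarisation route suffices for every covariance this package reports, and
the Monte-Carlo suite enforces its correctness. Correlation with longevity
is the special case `B2 = T` (`correlation_with_longevity()`).

## Parameters and defaults

* `k_max` (default 2, allowed 1–10): highest moment computed. The moment
  recursion weights are binomial coefficients, which grow factorially; past
  order ~10 they dominate floating-point precision, so higher orders are
  refused rather than returned inaccurately.
* `truncation_tol` (default `1e-9`, allowed up to `0.01`): maximum
  probability mass left untabulated by a distribution. The tail beyond the
  last support point `n` is available in closed form (`1' US^n`, times `A`
  for outside starts), so the reported `tail_mass` is exact, not an upper
  bound; support is extended until it drops below the tolerance, with a
  hard cap of 1e6 support points (`TailNotCertified` beyond it).
* `tol_pa = 1e-14`: reach or return probabilities at or below this are
  treated as structural zeros. Conditional objects for such starting states
  are reported as `NA` with a `defined` mask — conditioning on a null event
  has no value, and masking is preferred to silent dropping or division by
  zero. The threshold sits near the double-precision noise floor so that
  only true structural zeros (no path exists) are masked.
* Validation tolerance `1e-12` on probability constraints: entries outside
  `[0, 1]` or column sums above 1 by more than this raise errors
  (`NegativeEntry`, `ColumnSumExceedsOne`); inputs are never silently
  clipped. Certain absorption is tested by repeated squaring of `U` (the
  1-norm of `U^(2^k)` must fall below 1 within 64 doublings) plus a
  residual check on the solve — robust for reducible matrices, where a
  dominant-eigenvalue iteration can stall.

## Numerical choices

All "inverse" formulas are evaluated by LAPACK linear solves
(`solve(I - M, .)`), never by forming an explicit inverse; the results agree
with the inverse formulas to at least `1e-10`, which the test suite checks
against a truncated Neumann-series oracle. Matrix powers inside
distributions are accumulated one multiplication at a time because the
whole support is needed anyway. Target sets may be given in any order, as
labels or indices; the reordering that puts `B` last is internal, recorded
as a permutation, and every user-facing vector is returned in the original
label order. Variances computed as `m2 - m1^2` are clipped at zero when
round-off makes them negative by less than the tolerance. Degenerate
inputs are defined rather than rejected: `B` equal to the whole state space
makes the killed and conditional chains empty and the sub-chain the
original chain (so longevity is the `B = T` special case of the same code
path), a one-state chain with `U = 0` dies after exactly one step, and an
unreachable target set yields `pa = 0` with the conditional law masked.

## The simulator and what passing tests show

`simulate_paths()` is the package's independent oracle and a user-facing
feature. It draws each step among the `omega + 1` outcomes given by a
column of `U` and the corresponding mortality, counts the birth state as
one occupied step, and records full paths in long format so that
`empirical_statistics()` can recover reach/return frequencies, occupancy
moments, and inter-visit gaps with standard errors (binomial for
probabilities, delta method for variances). Randomness comes from R's
global generator seeded once per call with the mandatory `seed` argument;
the stepping is fully serial and vectorised over paths, so identical seeds
give bit-identical results and no scheduling can reorder draws. Analytic
and simulated values are compared on a 4-standard-error band, which keeps
the false-failure rate of the whole suite negligible (about 1 in 16,000
per comparison) without hiding real disagreements.

The simulator emulates exactly the model the formulas assume: homogeneous
Markov transitions, a single absorbing death state, perfect state
observation. Agreement between the two routes therefore validates the
algebra and its implementation — it says nothing about whether a real
population is Markovian, time-homogeneous, or correctly staged, and none of
the demographic caveats of fitting `U` from field data (sampling error,
individual heterogeneity, temporal variation) are addressed here.

## The worked example

The package ships one empirical matrix: the Southern Fulmar
(*Fulmarus glacialoides*) life cycle under ordinary sea-ice conditions,
with states pre-breeder, non-breeder, successful breeder, failed breeder,
and two canonical target sets (`fulmar_fixture()`): *adult* (has bred) and
*breeding attempt* (currently breeding). The published analysis also uses
favourable- and unfavourable-condition matrices distributed as
supplementary files; they are not bundled here (only isolated entries of
them are printed in the main text, which is not enough to reconstruct the
matrices), and `read_chain()` loads them from user-supplied files in the
same labelled-CSV layout.

One published detail deserves a note: the printed conditional-chain
absorption block and two sub-chain entries for the ordinary condition
(`MC`, `US[2,2]`, `mS[2]`) cannot be recovered from the *printed, 2-dp
rounded* transition matrix — they were evidently computed from the
unrounded vital rates behind it. Recomputing from the printed matrix gives
`MC = [[0.05, 0.247], [0.05, 0.123]]`, `US[2,2] = 0.284`, `mS[2] = 0.139`
versus the printed `[[0.061, 0.25], [0.037, 0.12]]`, `0.29`, `0.13`. The
regression tests pin only the entries that are consistent with the printed
matrix; the others are documented here rather than "fixed".

```{r fulmar}
fx <- fulmar_fixture()
an <- set_analysis(fx$chain, fx$Bb)
an
occupancy_moments(an$sub, an$absorption)$mean
```

## Problem sizes in the test suite

Deterministic property checks run over batches of 100 random chains with up
to 8 states (random substochastic columns scaled below 0.95, about 30%
structural zeros) — small enough that a full batch of constructions,
moments, distributions, and cross-route comparisons runs in seconds, large
enough to hit reducible chains, unreachable sets, and zero-mortality
columns. Monte-Carlo comparisons use 2e5 paths per initial state of the
fulmar chain, at which the 4-SE bands are a fraction of a percent of the
quantities checked.

## Limitations

* Only a single absorbing state is modelled; competing causes of death
  require a different absorption structure.
* The fertility side of a projection matrix (`A = U + F`) is out of scope:
  only `U` enters, so lifetime *reproductive output* is approximated by
  breeding-state occupancy only when per-visit fertility is one.
* Discrete time only.
* Conditional reach/return distributions are reported conditional on the
  event; unconditional variants (with an atom at "never") can be formed
  from `p_win`/`p_return` by the user.
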