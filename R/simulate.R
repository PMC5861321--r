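# Seeded path simulator: the independent verification oracle for every
# analytic quantity, and a user-facing feature. Paths are stepped in a
# single vectorised sweep (all live paths advance together), drawing each
# step among the omega + 1 outcomes (columns of U, plus death).

#' Simulate individual life-cycle paths
#'
#' Each path starts in `initial_state` (recycled over paths if a vector) and
#' at every step moves to state `i` with probability `U[i, j]` or dies with
#' probability `m[j]`. The birth state counts as one occupied time step, so
#' a chain with `U = [[0]]` gives every path lifespan 1. Identical seeds
#' give bit-identical output.
#'
#' @param chain a [demographic_chain()].
#' @param n_paths number of paths (>= 1).
#' @param initial_state starting state(s), labels or indices; recycled to
#'   `n_paths`.
#' @param seed mandatory integer seed; there is no implicit randomness.
#' @param max_steps emergency cap on the per-path lifespan; exceeding it
#'   raises `NonTerminating` (an invalid chain slipped through validation).
#' @return Object of class `path_summary`: long-format records `path`, `t`
#'   (age, starting at 0), `state` (index); `visits` (n_paths x omega count
#'   matrix), `lifespan` (per path), `init` (per-path initial state index),
#'   `n_paths`, `seed`, and the chain's labels.
#' @examples
#' fx <- fulmar_fixture()
#' ps <- simulate_paths(fx$chain, 500, "pre-breeder", seed = 1)
#' mean(ps$lifespan)
#' @export
simulate_paths <- function(chain, n_paths, initial_state, seed,
                           max_steps = 1e8) {
  stopifnot(inherits(chain, "demographic_chain"))
  n_paths <- as.integer(n_paths)
  if (is.na(n_paths) || n_paths < 1L) {
    soc_stop("ParseError", "n_paths must be >= 1")
  }
  if (missing(seed) || is.null(seed)) {
    soc_stop("ParseError", "a seed is mandatory: no implicit randomness")
  }
  init <- if (is.character(initial_state)) {
    match(initial_state, chain$labels)
  } else as.integer(initial_state)
  if (any(is.na(init)) || any(init < 1L) || any(init > chain$omega)) {
    soc_stop("LabelMismatch", "unknown initial state")
  }
  init <- rep_len(init, n_paths)

  omega <- chain$omega
  probs <- rbind(chain$U, dead = chain$m)  # column j: outcome distribution

  set.seed(as.integer(seed))
  alive <- seq_len(n_paths)
  state <- init
  rec_path <- vector("list", 64L)
  rec_state <- vector("list", 64L)
  rec_t <- vector("list", 64L)
  t <- 0L
  while (length(alive) > 0L) {
    if (t >= max_steps) {
      soc_stop("NonTerminating",
               sprintf("paths still alive after %g steps", max_steps))
    }
    ti <- t + 1L
    if (ti > length(rec_path)) {  # grow record buffers geometrically
      length(rec_path) <- length(rec_state) <- length(rec_t) <- 2L * ti
    }
    rec_path[[ti]] <- alive
    rec_state[[ti]] <- state
    rec_t[[ti]] <- rep.int(t, length(alive))
    nxt <- integer(length(state))
    for (j in unique(state)) {
      idx <- which(state == j)
      nxt[idx] <- sample.int(omega + 1L, length(idx), replace = TRUE,
                             prob = probs[, j])
    }
    dead <- nxt == omega + 1L
    alive <- alive[!dead]
    state <- nxt[!dead]
    t <- t + 1L
  }
  path <- unlist(rec_path[seq_len(t)], use.names = FALSE)
  st <- unlist(rec_state[seq_len(t)], use.names = FALSE)
  tt <- unlist(rec_t[seq_len(t)], use.names = FALSE)
  visits <- matrix(tabulate((st - 1L) * n_paths + path, n_paths * omega),
                   n_paths, omega)
  colnames(visits) <- chain$labels
  structure(list(path = path, t = tt, state = st, visits = visits,
                 lifespan = tabulate(path, n_paths), init = init,
                 n_paths = n_paths, seed = seed, labels = chain$labels),
            class = "path_summary")
}

#' @export
print.path_summary <- function(x, ...) {
  cat(sprintf("Simulated paths: n = %d, seed = %s, mean lifespan = %.3f\n",
              x$n_paths, format(x$seed), mean(x$lifespan)))
  invisible(x)
}

#' Export simulated paths as a long-format data frame
#'
#' @param ps a [simulate_paths()] result.
#' @return `data.frame` with columns `path_id`, `t` and `state` (label).
#' @export
paths_as_data_frame <- function(ps) {
  stopifnot(inherits(ps, "path_summary"))
  data.frame(path_id = ps$path, t = ps$t, state = ps$labels[ps$state])
}

#' Empirical analogues of the set-occupancy statistics
#'
#' Computes from simulated paths the empirical counterparts of every
#' analytic quantity for one target set: reach probability `pa`, return
#' probability `pr`, occupancy mean/variance and PMF, conditional
#' reaching-time and return-time means, each with a standard error for
#' z-score comparisons (binomial for probabilities, delta method for
#' variances).
#'
#' @param ps a [simulate_paths()] result.
#' @param B target set (labels or indices into the simulated chain's states).
#' @return A list of lists, each with `estimate`, `se`, and `n`:
#'   `pa` (paths ever entering B), `occupancy` (mean), `occupancy_var`,
#'   `reach_time` (mean first-hit age among paths that enter B, counted
#'   only for paths born outside B), `pr` (per-B-state fraction of visits
#'   followed by another B visit), `return_time` (per-B-state mean gap
#'   between consecutive B visits), and `pmf` (occupancy frequencies).
#' @examples
#' fx <- fulmar_fixture()
#' ps <- simulate_paths(fx$chain, 2000, "pre-breeder", seed = 1)
#' empirical_statistics(ps, fx$Bb)$pa$estimate
#' @export
empirical_statistics <- function(ps, B) {
  stopifnot(inherits(ps, "path_summary"))
  if (is.character(B)) {
    Bidx <- match(B, ps$labels)
    if (any(is.na(Bidx))) soc_stop("LabelMismatch", "unknown state label in B")
  } else Bidx <- as.integer(B)
  n <- ps$n_paths
  inB <- ps$state %in% Bidx

  # Occupancy time per path.
  occ <- rowSums(ps$visits[, Bidx, drop = FALSE])
  occ_mean <- mean(occ)
  occ_var <- stats::var(occ)
  se_mean <- stats::sd(occ) / sqrt(n)
  m4 <- mean((occ - occ_mean)^4)
  se_var <- sqrt(max(m4 - occ_var^2, 0) / n)  # delta method

  # First hit: records are appended t-ascending, so the first B record per
  # path is the first hit.
  idxB <- which(inB)
  first <- idxB[!duplicated(ps$path[idxB])]
  fh <- rep(NA_integer_, n)
  fh[ps$path[first]] <- ps$t[first]
  born_out <- !(ps$init %in% Bidx)
  hit <- !is.na(fh)
  pa_hat <- mean(hit[born_out])
  n_out <- sum(born_out)
  se_pa <- sqrt(pa_hat * (1 - pa_hat) / max(n_out, 1))
  rt <- fh[born_out & hit]
  reach_mean <- if (length(rt) > 0) mean(rt) else NA_real_
  se_reach <- if (length(rt) > 1) stats::sd(rt) / sqrt(length(rt)) else NA_real_

  # Return gaps: consecutive B-visit ages within a path; the state at the
  # earlier visit indexes the gap (strong Markov property).
  ob <- idxB[order(ps$path[idxB], ps$t[idxB])]
  same <- diff(ps$path[ob]) == 0L
  gaps <- diff(ps$t[ob])[same]
  from_state <- ps$state[ob][-length(ob)][same]
  nB <- length(Bidx)
  ret_mean <- ret_se <- pr_hat <- pr_se <- rep(NA_real_, nB)
  visitsB <- ps$state[idxB]
  for (k in seq_len(nB)) {
    g <- gaps[from_state == Bidx[k]]
    if (length(g) > 0) {
      ret_mean[k] <- mean(g)
      ret_se[k] <- if (length(g) > 1) stats::sd(g) / sqrt(length(g)) else NA_real_
    }
    n_at_risk <- sum(visitsB == Bidx[k])
    if (n_at_risk > 0) {
      pr_hat[k] <- length(g) / n_at_risk
      pr_se[k] <- sqrt(pr_hat[k] * (1 - pr_hat[k]) / n_at_risk)
    }
  }
  names(ret_mean) <- names(ret_se) <- names(pr_hat) <- names(pr_se) <-
    ps$labels[Bidx]

  # Empirical occupancy PMF (rows sum to one exactly).
  tab <- tabulate(occ + 1L, max(occ) + 1L) / n
  names(tab) <- paste0("n", seq_along(tab) - 1L)

  list(pa = list(estimate = pa_hat, se = se_pa, n = n_out),
       occupancy = list(estimate = occ_mean, se = se_mean, n = n),
       occupancy_var = list(estimate = occ_var, se = se_var, n = n),
       reach_time = list(estimate = reach_mean, se = se_reach, n = length(rt)),
       pr = list(estimate = pr_hat, se = pr_se),
       return_time = list(estimate = ret_mean, se = ret_se, n_gaps = length(gaps)),
       pmf = tab)
}
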