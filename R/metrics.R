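#' Adjusted Rand index between two labelings
#'
#' Chance-corrected pair-counting agreement between two partitions of the same
#' objects; invariant to relabeling either argument, 1 for identical
#' partitions, near 0 for independent ones. The workhorse for scoring an
#' agent's sign assignment against ground-truth components without worrying
#' about label switching.
#'
#' @param a,b integer (or factor) vectors of equal length.
#' @return A scalar in \eqn{[-1, 1]}.
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1))
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) {
    stop("`a` and `b` must have the same length (", length(a), " vs ",
         length(b), ")")
  }
  mclust::adjustedRandIndex(a, b)
}

#' Cohen's kappa between two agents' sign assignments
#'
#' Chance-corrected raw agreement \eqn{(p_o - p_e) / (1 - p_e)} over a shared
#' sign inventory `1..K` — signs are compared literally, with no label
#' matching, because the whole point of the game is that agents use the *same*
#' sign for the same object. Degenerate case: when expected agreement
#' \eqn{p_e = 1} (both agents constant on the same inventory cell pattern),
#' kappa is defined as 1 if the observed agreement is 1 and 0 otherwise.
#'
#' @param a,b integer vectors of signs in `1..K`, equal length.
#' @param K inventory size; defaults to the largest sign seen.
#' @return A scalar, at most 1.
#' @export
cohen_kappa <- function(a, b, K = max(a, b)) {
  if (length(a) != length(b)) {
    stop("`a` and `b` must have the same length")
  }
  D <- length(a)
  po <- mean(a == b)
  pe <- sum(tabulate(a, K) * tabulate(b, K)) / D^2
  if (pe >= 1 - 1e-12) return(if (po >= 1 - 1e-12) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Mean pairwise Cohen's kappa across a population
#'
#' [cohen_kappa()] for every unordered pair of agents, averaged — the
#' population-level sign-sharing score.
#'
#' @param signs N x D integer matrix, one row per agent.
#' @param K sign inventory size; defaults to the largest sign seen.
#' @return Mean kappa over the N(N-1)/2 pairs.
#' @export
mean_pairwise_kappa <- function(signs, K = max(signs)) {
  N <- nrow(signs)
  if (N < 2L) stop("need at least two agents")
  pairs <- utils::combn(N, 2L)
  mean(apply(pairs, 2L, function(ij) {
    cohen_kappa(signs[ij[1], ], signs[ij[2], ], K)
  }))
}

# Empirical per-object sign distributions over the trailing `window`
# iterations of a trace, pooling all agents: a D x K matrix of proportions.
trailing_sign_distribution <- function(trace, window) {
  dm <- dim(trace$signs)
  I <- dm[1]; N <- dm[2]; D <- dm[3]
  if (window < 1L || window > I) {
    stop("`window` must lie in 1..", I, " (the trace length)")
  }
  iters <- (I - window + 1L):I
  K <- trace$K
  p <- matrix(0, D, K)
  for (d in seq_len(D)) {
    p[d, ] <- tabulate(trace$signs[iters, , d], K)
  }
  p / (window * N)
}

# All permutations of 1..n (n! x n matrix); used for exact label alignment.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Agreement between the sign distributions of two traces
#'
#' For every object, forms the empirical distribution over signs in the last
#' `window` iterations of each trace (pooling agents), aligns the two sign
#' inventories with the one-to-one relabeling that maximizes the total overlap
#' \eqn{\sum_d \sum_k \min(\hat p_d(k), \hat q_d(\sigma(k)))}, and returns the
#' mean per-object overlap under that alignment. The global alignment is found
#' exactly, by enumerating permutations (K <= 8). Symmetric in its arguments
#' and bounded in \eqn{[0, 1]}; 1 means the two samplers visit identical sign
#' distributions up to a relabeling.
#'
#' @param trace,reference [sign_trace] objects over the same objects and
#'   inventory size.
#' @param window number of trailing iterations to pool (defaults to 10).
#' @return A scalar in \eqn{[0, 1]}.
#' @export
posterior_agreement <- function(trace, reference, window = 10L) {
  if (dim(trace$signs)[3] != dim(reference$signs)[3]) {
    stop("traces cover different numbers of objects")
  }
  if (trace$K != reference$K) stop("traces use different inventory sizes")
  K <- trace$K
  if (K > 8L) stop("exact label alignment supported for K <= 8 (got K = ", K, ")")
  p <- trailing_sign_distribution(trace, window)
  q <- trailing_sign_distribution(reference, window)
  D <- nrow(p)
  # overlap[k, l] = sum_d min(p_d(k), q_d(l)); best permutation maximizes its trace
  ov <- matrix(0, K, K)
  for (k in seq_len(K)) {
    for (l in seq_len(K)) {
      ov[k, l] <- sum(pmin(p[, k], q[, l]))
    }
  }
  perms <- all_permutations(K)
  scores <- vapply(seq_len(nrow(perms)), function(i) {
    sum(ov[cbind(seq_len(K), perms[i, ])])
  }, 0)
  max(scores) / D
}
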