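#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

new_sign_trace <- function(signs, K, proposals, acceptances,
                           proposals_by_iter, acceptances_by_iter,
                           mode, config = NULL) {
  structure(
    list(signs = signs, K = as.integer(K),
         proposals = as.integer(proposals),
         acceptances = as.integer(acceptances),
         proposals_by_iter = as.integer(proposals_by_iter),
         acceptances_by_iter = as.integer(acceptances_by_iter),
         mode = mode, config = config),
    class = "sign_trace"
  )
}

#' Per-iteration record of a naming game
#'
#' @description
#' A `sign_trace` stores, for every outer iteration, every agent's sign for
#' every object (an I x N x D integer array in `$signs`), together with total
#' and per-iteration proposal/acceptance counts and the generating
#' [game_config()]. Produced by [run_rmhng()] and [run_gibbs()].
#'
#' @section Methods:
#' `tidy()` returns one row per (iteration, agent, object) with the sign;
#' `glance()` a one-row summary; `autoplot()` the per-iteration acceptance
#' rate.
#'
#' @name sign_trace
NULL

#' @export
print.sign_trace <- function(x, ...) {
  dm <- dim(x$signs)
  cat(sprintf("Sign trace (%s): %d iterations x %d agents x %d objects, K = %d\n",
              x$mode, dm[1], dm[2], dm[3], x$K))
  if (x$proposals > 0) {
    cat(sprintf("  %d proposals, %d accepted (%.1f%%)\n", x$proposals,
                x$acceptances, 100 * x$acceptances / x$proposals))
  }
  invisible(x)
}

#' @rdname sign_trace
#' @param x a `sign_trace`.
#' @param ... unused.
#' @export
tidy.sign_trace <- function(x, ...) {
  dm <- dim(x$signs)
  tibble::tibble(
    iteration = rep(seq_len(dm[1]), times = dm[2] * dm[3]),
    agent = rep(rep(seq_len(dm[2]), each = dm[1]), times = dm[3]),
    object = rep(seq_len(dm[3]), each = dm[1] * dm[2]),
    sign = as.integer(x$signs)
  )
}

#' @rdname sign_trace
#' @export
glance.sign_trace <- function(x, ...) {
  dm <- dim(x$signs)
  tibble::tibble(
    mode = x$mode, iterations = dm[1], agents = dm[2], objects = dm[3],
    K = x$K, proposals = x$proposals, acceptances = x$acceptances,
    acceptance_rate = if (x$proposals > 0) x$acceptances / x$proposals else NA_real_
  )
}

#' Signs of all agents at one iteration
#'
#' @param trace a [sign_trace].
#' @param iteration iteration index in `1..I`.
#' @return An N x D integer matrix, one row per agent.
#' @export
signs_at <- function(trace, iteration) {
  if (iteration < 1L || iteration > dim(trace$signs)[1]) {
    stop("iteration ", iteration, " outside 1..", dim(trace$signs)[1])
  }
  matrix(trace$signs[iteration, , ], nrow = dim(trace$signs)[2])
}

#' Per-iteration evaluation of a trace
#'
#' Computes, for every outer iteration, each agent's adjusted Rand index
#' against ground-truth labels (when supplied) and the mean pairwise Cohen's
#' kappa across agents, plus the iteration's acceptance rate.
#'
#' @param trace a [sign_trace].
#' @param labels optional length-D integer vector of ground-truth component
#'   labels; when `NULL` the ARI columns are omitted.
#' @return A tibble with one row per (iteration, agent) holding `ari`, and the
#'   per-iteration `kappa` and `acceptance_rate` repeated across agents.
#' @export
trace_metrics <- function(trace, labels = NULL) {
  dm <- dim(trace$signs)
  I <- dm[1]; N <- dm[2]
  rows <- purrr::map(seq_len(I), function(i) {
    sg <- signs_at(trace, i)
    kp <- mean_pairwise_kappa(sg)
    ar <- if (is.null(labels)) rep(NA_real_, N) else
      vapply(seq_len(N), function(n) adjusted_rand_index(sg[n, ], labels), 0)
    tibble::tibble(
      iteration = i, agent = seq_len(N), ari = ar, kappa = kp,
      acceptance_rate = if (trace$proposals_by_iter[i] > 0)
        trace$acceptances_by_iter[i] / trace$proposals_by_iter[i] else NA_real_
    )
  })
  out <- dplyr::bind_rows(rows)
  if (is.null(labels)) out$ari <- NULL
  out
}
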