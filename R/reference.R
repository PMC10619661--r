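#' Exact posterior over the shared sign given every agent's state
#'
#' Centralized enumeration of
#' \eqn{P(w_d = k \mid x_d^{1:N}, \theta^{1:N}) \propto \gamma_k \prod_n
#' N(x_d^n \mid \mu_k^n, (\Lambda_k^n)^{-1})}, computed in log space. No
#' decentralized agent can evaluate this — it reads every agent's internal
#' state simultaneously — which is what makes it the reference the naming game
#' is measured against.
#'
#' @param agents list of [agent_state()]s with `theta` set.
#' @param hyper an [inter_gmm_hyper()].
#' @param d object index.
#' @return A probability vector of length K.
#' @export
exact_posterior_w <- function(agents, hyper, d) {
  lp <- log(hyper$gamma)
  for (ag in agents) {
    if (is.null(ag$ll)) stop("agent ", ag$index, " has no theta set")
    lp <- lp + ag$ll[d, ]
  }
  lp <- lp - max(lp)
  p <- exp(lp)
  p / sum(p)
}

#' Centralized Gibbs sampler of the shared-sign mixture (topline)
#'
#' Alternates (a) sampling a single shared sign \eqn{w_d} per object from
#' [exact_posterior_w()] — objects scanned in ascending order — and (b) each
#' agent resampling its own component parameters from the conjugate posterior
#' given the shared signs. Agents keep separate parameters
#' \eqn{\theta^n}; only the sign variable is shared, so the pairwise kappa of
#' the resulting trace is 1 by construction.
#'
#' @inheritParams run_rmhng
#' @return A [sign_trace] in which every agent's row repeats the shared sign.
#' @export
run_gibbs <- function(agents, hyper, config) {
  N <- config$N
  D <- config$D
  K <- config$K
  if (length(agents) != N) stop("need ", N, " agents, got ", length(agents))
  set.seed(config$seed)
  init_agents(agents, hyper, config)

  I <- config$I
  signs <- array(0L, dim = c(I, N, D))
  lgam <- log(hyper$gamma)
  for (i in seq_len(I)) {
    # shared posterior over signs for all objects at once: D x K log matrix
    lp <- matrix(lgam, D, K, byrow = TRUE)
    for (n in seq_len(N)) lp <- lp + agents[[n]]$ll
    mx <- lp[, 1L]
    if (K > 1L) for (k in 2:K) mx <- pmax(mx, lp[, k])
    p <- exp(lp - mx)
    cum <- p
    if (K > 1L) for (k in 2:K) cum[, k] <- cum[, k - 1L] + p[, k]
    u <- runif(D) * cum[, K]
    w <- rep(1L, D)
    if (K > 1L) for (k in seq_len(K - 1L)) w <- w + (cum[, k] < u)
    w <- as.integer(w)
    for (n in seq_len(N)) {
      agents[[n]]$w <- w
      set_agent_theta(agents[[n]], update_theta_posterior(agents[[n]], hyper),
                      hyper)
      signs[i, n, ] <- w
    }
  }
  new_sign_trace(signs, K, 0L, 0L, integer(I), integer(I),
                 mode = "gibbs", config = config)
}
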