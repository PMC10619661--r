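#' @importFrom stats rnorm runif rchisq dnorm setNames
NULL

# Wishart draw via the Bartlett decomposition; valid for any df > p - 1
# (including non-integer df, which posterior degrees of freedom nu + n_k
# usually are). scale is the Wishart scale matrix S, so E[W] = df * S.
rwishart_bartlett <- function(df, scale) {
  p <- nrow(scale)
  if (df <= p - 1) {
    stop("Wishart degrees of freedom must exceed p - 1 = ", p - 1,
         " (got ", df, ")")
  }
  if (p == 1L) {
    return(matrix(scale[1L, 1L] * rchisq(1L, df), 1L, 1L))
  }
  A <- matrix(0, p, p)
  diag(A) <- sqrt(rchisq(p, df - seq_len(p) + 1))
  A[lower.tri(A)] <- rnorm(p * (p - 1) / 2)
  L <- t(chol(scale))
  LA <- L %*% A
  LA %*% t(LA)
}

#' Draw component parameters from the Normal-Wishart prior
#'
#' Samples, independently for each of the K signs, a precision matrix
#' \eqn{\Lambda_k \sim W(\nu, \bar\beta)} and a mean
#' \eqn{\mu_k \sim N(m, (\bar\alpha \Lambda_k)^{-1})}.
#'
#' Requires a proper Wishart prior, i.e. `hyper$nu > F - 1`. With the common
#' weakly-informative choice `nu = 1` this holds only for `F = 1`; in higher
#' dimensions initialize assignments some other way (see
#' [game_config()]'s `init`) and rely on posterior sampling, whose degrees of
#' freedom `nu + n_k` become proper as soon as a component holds enough points.
#'
#' @param hyper an [inter_gmm_hyper()] object.
#' @param K number of components to draw (defaults to `hyper$K`).
#' @param F feature dimension.
#' @return A list with `mu` (K x F matrix) and `lam` (list of K F x F
#'   precision matrices), class `agent_theta`.
#' @examples
#' hy <- inter_gmm_hyper(K = 2, nu = 3, beta_bar = 2)
#' th <- sample_theta_prior(hy, F = 1)
#' th$mu
#' @export
sample_theta_prior <- function(hyper, K = hyper$K, F = 1L) {
  hx <- expand_hyper(hyper, F)
  if (hx$nu <= F - 1) {
    stop("prior sampling needs nu > F - 1 (nu = ", hx$nu, ", F = ", F,
         "); the Wishart prior is improper. Use posterior sampling, or a ",
         "different initializer.")
  }
  mu <- matrix(0, K, F)
  lam <- vector("list", K)
  for (k in seq_len(K)) {
    lamk <- rwishart_bartlett(hx$nu, hx$beta_bar)
    lam[[k]] <- lamk
    U <- chol(hx$alpha_bar * lamk)
    mu[k, ] <- hx$m + backsolve(U, rnorm(F))
  }
  structure(list(mu = mu, lam = lam), class = "agent_theta")
}

# Normal-Wishart posterior parameters for one component given its assigned
# points (rows of x). Standard conjugate update:
#   alpha' = alpha + n;  m' = (alpha m + n xbar) / alpha';  nu' = nu + n
#   beta'^-1 = beta^-1 + S + (alpha n / alpha') (xbar - m)(xbar - m)^T
# where S is the scatter about xbar. n = 0 returns the prior itself.
nw_posterior_params <- function(x, hx) {
  n <- nrow(x)
  F <- length(hx$m)
  if (n == 0L) {
    return(list(m = hx$m, alpha = hx$alpha_bar, nu = hx$nu,
                beta = hx$beta_bar))
  }
  xbar <- colMeans(x)
  xc <- sweep(x, 2L, xbar)
  S <- crossprod(xc)
  alpha_post <- hx$alpha_bar + n
  m_post <- (hx$alpha_bar * hx$m + n * xbar) / alpha_post
  dm <- xbar - hx$m
  beta_inv_post <- hx$beta_inv + S +
    (hx$alpha_bar * n / alpha_post) * tcrossprod(dm)
  list(m = m_post, alpha = alpha_post, nu = hx$nu + n,
       beta = chol2inv(chol(beta_inv_post)))
}

#' Resample an agent's component parameters from their conjugate posterior
#'
#' Given the agent's current sign assignments `w`, draws fresh
#' \eqn{(\mu_k, \Lambda_k)} for every sign k from the Normal-Wishart posterior
#' conditioned on the agent's observations currently assigned to k. Components
#' with no assigned objects are drawn from the prior (the conjugate update
#' reduces to it exactly).
#'
#' This is the "internal update of the global parameter" step each agent runs
#' at the end of a naming-game iteration; it only reads the agent's own
#' observations and signs, never another agent's state.
#'
#' @param agent an [agent_state()].
#' @param hyper an [inter_gmm_hyper()].
#' @return A new `agent_theta` (the agent itself is not modified; see
#'   [set_agent_theta()]).
#' @export
update_theta_posterior <- function(agent, hyper) {
  hx <- expand_hyper(hyper, agent$F)
  K <- agent$K
  mu <- matrix(0, K, agent$F)
  lam <- vector("list", K)
  for (k in seq_len(K)) {
    pk <- nw_posterior_params(agent$x[agent$w == k, , drop = FALSE], hx)
    if (pk$nu <= agent$F - 1) {
      stop("posterior Wishart degrees of freedom ", pk$nu,
           " are improper for F = ", agent$F,
           " (component ", k, " holds too few points for this prior)")
    }
    lamk <- rwishart_bartlett(pk$nu, pk$beta)
    lam[[k]] <- lamk
    U <- chol(pk$alpha * lamk)
    mu[k, ] <- pk$m + backsolve(U, rnorm(agent$F))
  }
  structure(list(mu = mu, lam = lam), class = "agent_theta")
}
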