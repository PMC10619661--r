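#' Create an agent for a naming game
#'
#' An agent holds a private, fixed perceptual state (one feature vector per
#' object), per-sign Gaussian parameters \eqn{\theta = \{\mu_k, \Lambda_k\}},
#' and its current sign assignment for every object. Agents are mutable
#' (environment-backed) because the game updates them in place: accepting a
#' sign changes `w`, and the end-of-iteration conjugate update changes `theta`.
#'
#' When `theta` is set (at construction or via [set_agent_theta()]) the agent
#' caches the D x K matrix of per-object, per-sign Gaussian log-likelihoods, so
#' that the acceptance ratio of a single exchange is a table lookup.
#'
#' @param x D x F numeric matrix of perceptual features (rows = objects). A
#'   vector is taken as D observations of a 1-dimensional feature.
#' @param hyper an [inter_gmm_hyper()]; supplies K and the sign prior.
#' @param theta optional `agent_theta`; if `NULL` the agent starts without
#'   parameters and [set_agent_theta()] must be called before play.
#' @param w optional integer vector of initial signs in `1..K`.
#' @param index the agent's position `n` in the population (bookkeeping only).
#' @return An environment of class `agent_state`.
#' @examples
#' hy <- inter_gmm_hyper(K = 3, nu = 3, beta_bar = 1)
#' ag <- agent_state(rnorm(10), hy, theta = sample_theta_prior(hy, F = 1))
#' ag$w
#' @export
agent_state <- function(x, hyper, theta = NULL, w = NULL, index = 1L) {
  if (!is.matrix(x)) x <- matrix(as.numeric(x), ncol = 1L)
  storage.mode(x) <- "double"
  D <- nrow(x)
  K <- hyper$K
  ag <- new.env(parent = emptyenv())
  ag$index <- as.integer(index)
  ag$x <- x
  ag$D <- D
  ag$F <- ncol(x)
  ag$K <- K
  if (is.null(w)) w <- rep(1L, D)
  w <- as.integer(w)
  if (length(w) != D || any(w < 1L | w > K)) {
    stop("`w` must be length ", D, " with entries in 1..", K)
  }
  ag$w <- w
  ag$mu <- NULL
  ag$lam <- NULL
  ag$ll <- NULL
  class(ag) <- "agent_state"
  if (!is.null(theta)) set_agent_theta(ag, theta, hyper)
  ag
}

#' @export
print.agent_state <- function(x, ...) {
  cat(sprintf("Agent %d: D = %d objects, F = %d feature dim, K = %d signs%s\n",
              x$index, x$D, x$F, x$K,
              if (is.null(x$ll)) " (theta unset)" else ""))
  invisible(x)
}

#' Install component parameters on an agent and refresh its caches
#'
#' Sets `theta` and recomputes the cached D x K log-likelihood matrix and the
#' cached cumulative sign-posterior used by [sample_sign()]. The cached
#' posterior is built from `hyper$gamma`; game functions assume all agents in
#' one game share a single hyperparameter object.
#'
#' @param agent an [agent_state()] (modified in place).
#' @param theta an `agent_theta` with K means and precisions of dimension F.
#' @param hyper an [inter_gmm_hyper()].
#' @return The agent, invisibly.
#' @export
set_agent_theta <- function(agent, theta, hyper) {
  K <- agent$K
  F <- agent$F
  if (nrow(theta$mu) != K || ncol(theta$mu) != F || length(theta$lam) != K) {
    stop("theta dimensions do not match the agent (need K = ", K,
         ", F = ", F, ")")
  }
  x <- agent$x
  D <- agent$D
  ll <- matrix(0, D, K)
  if (F == 1L) {
    xv <- x[, 1L]
    for (k in seq_len(K)) {
      lamk <- theta$lam[[k]][1L, 1L]
      if (!is.finite(lamk) || lamk <= 0) {
        stop("precision of component ", k, " is not positive definite")
      }
      ll[, k] <- dnorm(xv, theta$mu[k, 1L], 1 / sqrt(lamk), log = TRUE)
    }
  } else {
    for (k in seq_len(K)) {
      U <- tryCatch(chol(theta$lam[[k]]), error = function(e) {
        stop("precision of component ", k, " is not positive definite: ",
             conditionMessage(e))
      })
      xc <- sweep(x, 2L, theta$mu[k, ])
      quad <- rowSums((xc %*% t(U))^2)
      ll[, k] <- sum(log(diag(U))) - 0.5 * F * log(2 * pi) - 0.5 * quad
    }
  }
  agent$mu <- theta$mu
  agent$lam <- theta$lam
  agent$ll <- ll
  # cached sign posterior and its row-wise cumulative distribution
  lp <- sweep(ll, 2L, log(hyper$gamma), `+`)
  mx <- lp[, 1L]
  if (K > 1L) for (k in 2:K) mx <- pmax(mx, lp[, k])
  p <- exp(lp - mx)
  p <- p / rowSums(p)
  cum <- p
  if (K > 1L) for (k in 2:K) cum[, k] <- cum[, k - 1L] + p[, k]
  cum[, K] <- 1
  agent$post <- p
  agent$cum <- cum
  agent$cache_gamma <- hyper$gamma
  invisible(agent)
}

#' Gaussian log-likelihood of one object under one sign
#'
#' Log-density of the agent's feature vector for object `d` under its current
#' Gaussian for sign `k`, \eqn{\log N(x_d \mid \mu_k, \Lambda_k^{-1})}.
#'
#' @param agent an [agent_state()] with `theta` set.
#' @param d object index in `1..D`.
#' @param k sign index in `1..K`.
#' @return A finite scalar.
#' @export
log_likelihood <- function(agent, d, k) {
  if (is.null(agent$ll)) stop("agent has no theta set; call set_agent_theta()")
  if (d < 1L || d > agent$D) stop("object index d out of range 1..", agent$D)
  if (k < 1L || k > agent$K) stop("sign index k out of range 1..", agent$K)
  agent$ll[d, k]
}

#' Posterior over signs for one object, from one agent's perspective
#'
#' The agent's private belief \eqn{P(w_d = k) \propto \gamma_k
#' N(x_d \mid \mu_k, \Lambda_k^{-1})}, computed in log space with
#' max-subtraction. This is the speaker's utterance distribution.
#'
#' @inheritParams log_likelihood
#' @param hyper an [inter_gmm_hyper()] supplying the sign prior `gamma`.
#' @return A probability vector of length K summing to one.
#' @export
sign_posterior <- function(agent, hyper, d) {
  if (is.null(agent$ll)) stop("agent has no theta set; call set_agent_theta()")
  lp <- agent$ll[d, ] + log(hyper$gamma)
  lp <- lp - max(lp)
  p <- exp(lp)
  p / sum(p)
}

#' Sample a sign (an utterance) from an agent's sign posterior
#'
#' Draws one categorical sample from [sign_posterior()] by inverse-CDF on a
#' single uniform variate. Uses the agent's cached posterior when the cache was
#' built from the same `gamma`.
#'
#' @inheritParams sign_posterior
#' @return An integer sign index in `1..K`.
#' @export
sample_sign <- function(agent, hyper, d) {
  if (identical(agent$cache_gamma, hyper$gamma)) {
    row <- agent$cum[d, ]
  } else {
    p <- sign_posterior(agent, hyper, d)
    row <- cumsum(p)
    row[agent$K] <- 1
  }
  u <- runif(1L)
  s <- 1L
  K <- agent$K
  while (s < K && row[s] < u) s <- s + 1L
  s
}

# Vectorized: resample every object's sign from the cached posterior, one
# uniform per object. Used by the No-communication mode and for
# posterior-based initialization.
resample_signs_from_posterior <- function(agent) {
  u <- runif(agent$D)
  w <- rep(1L, agent$D)
  K <- agent$K
  if (K > 1L) {
    cum <- agent$cum
    for (k in seq_len(K - 1L)) w <- w + (cum[, k] < u)
  }
  agent$w <- as.integer(w)
  invisible(agent)
}
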