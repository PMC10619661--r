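# Shared fixture builders for the unit tests.

# An agent with fully specified 1-D component parameters.
fixed_agent_1d <- function(x, mu, lam, hyper, w = NULL, index = 1L) {
  K <- length(mu)
  th <- structure(
    list(mu = matrix(mu, ncol = 1L),
         lam = lapply(lam, function(l) matrix(l, 1L, 1L))),
    class = "agent_theta")
  agent_state(x, hyper, theta = th, w = w, index = index)
}

# Enumerated posterior over signs given several fixed agents (independent
# reimplementation of the product rule, used as oracle).
enum_posterior <- function(xs, mus, lams, gamma) {
  K <- length(gamma)
  lp <- log(gamma)
  for (n in seq_along(xs)) {
    lp <- lp + dnorm(xs[n], mus[[n]], 1 / sqrt(lams[[n]]), log = TRUE)
  }
  p <- exp(lp - max(lp))
  p / sum(p)
}

total_variation <- function(p, q) 0.5 * sum(abs(p - q))
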