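test_that("hyperparameter construction enforces the prior's invariants", {
  hy <- inter_gmm_hyper(K = 5, m = 0, alpha_bar = 1, nu = 1, beta_bar = 0.01)
  expect_equal(sum(hy$gamma), 1, tolerance = 1e-12)
  expect_error(inter_gmm_hyper(K = 3, gamma = c(0.5, 0.5)), "length")
  expect_error(inter_gmm_hyper(K = 2, gamma = c(0.9, 0.2)), "probability")
  expect_error(inter_gmm_hyper(K = 2, alpha_bar = -1), "positive")
  expect_error(
    inter_gmm_hyper(K = 2, beta_bar = matrix(c(1, 2, 0, 1), 2)), "symmetric")
  expect_error(
    inter_gmm_hyper(K = 2, beta_bar = matrix(c(1, 2, 2, 1), 2)),
    "positive definite")
})

test_that("prior draws of the precision match Wishart moments", {
  set.seed(101)
  hy <- inter_gmm_hyper(K = 50, nu = 3, beta_bar = 2)
  draws <- replicate(2000, {
    th <- sample_theta_prior(hy, F = 1)
    vapply(th$lam, function(l) l[1, 1], 0)
  })
  # E[lambda] = nu * beta_bar = 6, Var = 2 * nu * beta_bar^2 = 24
  n <- length(draws)
  se <- sqrt(24 / n)
  expect_lt(abs(mean(draws) - 6), 3 * se)
})

test_that("a huge mean-precision scaling pins the prior mean draws to m", {
  set.seed(102)
  hy <- inter_gmm_hyper(K = 20, m = 3.5, alpha_bar = 1e12, nu = 3, beta_bar = 1)
  th <- sample_theta_prior(hy, F = 1)
  expect_true(all(abs(th$mu - 3.5) < 1e-4))
})

test_that("bivariate prior precision draws match closed-form Wishart moments", {
  set.seed(103)
  hy <- inter_gmm_hyper(K = 1, nu = 5, beta_bar = diag(2))
  n <- 20000
  draws <- replicate(n, sample_theta_prior(hy, F = 2)$lam[[1]])
  # For W(nu, S): E[W_ij] = nu S_ij, Var(W_ij) = nu (S_ij^2 + S_ii S_jj)
  m11 <- mean(draws[1, 1, ]); m12 <- mean(draws[1, 2, ])
  expect_lt(abs(m11 - 5), 3 * sqrt(10 / n))
  expect_lt(abs(m12 - 0), 3 * sqrt(5 / n))
  expect_lt(abs(stats::var(draws[1, 1, ]) - 10), 0.4)
  expect_lt(abs(stats::var(draws[1, 2, ]) - 5), 0.2)
})

test_that("prior sampling refuses an improper Wishart prior", {
  hy <- inter_gmm_hyper(K = 2, nu = 1, beta_bar = diag(3))
  expect_error(sample_theta_prior(hy, F = 3), "improper")
})

test_that("log_likelihood evaluates the Gaussian density", {
  hy <- inter_gmm_hyper(K = 1)
  ag <- fixed_agent_1d(x = 0, mu = 0, lam = 1, hyper = hy)
  expect_equal(log_likelihood(ag, 1, 1), -0.5 * log(2 * pi), tolerance = 1e-9)

  hy2 <- inter_gmm_hyper(K = 1)
  th2 <- structure(list(mu = matrix(0, 1, 2), lam = list(diag(2))),
                   class = "agent_theta")
  ag2 <- agent_state(matrix(c(1, 1), 1, 2), hy2, theta = th2)
  expect_equal(log_likelihood(ag2, 1, 1), -log(2 * pi) - 1, tolerance = 1e-9)
})

test_that("log_likelihood peaks at the component mean and is shift-invariant", {
  hy <- inter_gmm_hyper(K = 1)
  xs <- c(-2, -0.5, 1.3, 1.5, 4)
  ag <- fixed_agent_1d(x = xs, mu = 1.5, lam = 2, hyper = hy)
  lls <- vapply(seq_along(xs), function(d) log_likelihood(ag, d, 1), 0)
  expect_equal(which.max(lls), 4L)
  shift <- 7.25
  ag2 <- fixed_agent_1d(x = xs + shift, mu = 1.5 + shift, lam = 2, hyper = hy)
  lls2 <- vapply(seq_along(xs), function(d) log_likelihood(ag2, d, 1), 0)
  expect_equal(lls, lls2, tolerance = 1e-9)
})

test_that("a singular precision is rejected loudly", {
  hy <- inter_gmm_hyper(K = 1)
  th <- structure(list(mu = matrix(0, 1, 2),
                       lam = list(matrix(c(1, 1, 1, 1), 2))),
                  class = "agent_theta")
  expect_error(agent_state(matrix(0, 1, 2), hy, theta = th),
               "positive definite")
  expect_error(fixed_agent_1d(0, mu = 0, lam = -1, hyper = hy),
               "positive definite")
})

test_that("sign_posterior is a normalized Bayes rule over signs", {
  # symmetric case: identical components give the uniform posterior
  hy <- inter_gmm_hyper(K = 4)
  ag <- fixed_agent_1d(x = 1.7, mu = rep(0, 4), lam = rep(1, 4), hyper = hy)
  expect_equal(sign_posterior(ag, hy, 1), rep(0.25, 4), tolerance = 1e-12)

  # two-term Bayes rule by hand: x = 0 under means 0 and 8, unit precision
  hy2 <- inter_gmm_hyper(K = 2)
  ag2 <- fixed_agent_1d(x = 0, mu = c(0, 8), lam = c(1, 1), hyper = hy2)
  p <- sign_posterior(ag2, hy2, 1)
  expect_equal(p[2], exp(-32) / (1 + exp(-32)), tolerance = 1e-18)
  expect_equal(p[1], 1 - p[2], tolerance = 1e-12)

  # normalization across many random states
  set.seed(104)
  for (i in 1:200) {
    K <- sample(2:6, 1)
    hyk <- inter_gmm_hyper(K = K, gamma = {
      g <- rexp(K); g / sum(g)
    })
    agk <- fixed_agent_1d(x = rnorm(3, sd = 5), mu = rnorm(K, sd = 5),
                          lam = rexp(K) + 0.1, hyper = hyk)
    for (d in 1:3) expect_equal(sum(sign_posterior(agk, hyk, d)), 1,
                                tolerance = 1e-9)
  }
})

test_that("sample_sign draws from the sign posterior", {
  hy <- inter_gmm_hyper(K = 3)
  ag <- fixed_agent_1d(x = 0.4, mu = c(0, 1, 3), lam = c(1, 1, 1), hyper = hy)
  p <- sign_posterior(ag, hy, 1)
  set.seed(105)
  n <- 100000
  draws <- replicate(n, sample_sign(ag, hy, 1))
  freq <- tabulate(draws, 3) / n
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(freq - p) < 3 * se + 1e-12))

  # degenerate posterior: far-away alternatives never drawn
  agd <- fixed_agent_1d(x = 0, mu = c(0, 50, 80), lam = c(1, 1, 1), hyper = hy)
  drawsd <- replicate(10000, sample_sign(agd, hy, 1))
  expect_gte(mean(drawsd == 1L), 0.999)

  # K = 1 always returns the only sign
  hy1 <- inter_gmm_hyper(K = 1)
  ag1 <- fixed_agent_1d(x = 2, mu = 0, lam = 1, hyper = hy1)
  expect_true(all(replicate(50, sample_sign(ag1, hy1, 1)) == 1L))
})

test_that("an empty component's conjugate update reduces to the prior", {
  set.seed(106)
  hy <- inter_gmm_hyper(K = 2, m = 1, alpha_bar = 2, nu = 4, beta_bar = 0.5)
  # all objects assigned to sign 1; sign 2 is empty
  ag <- fixed_agent_1d(x = rnorm(20), mu = c(0, 0), lam = c(1, 1), hyper = hy,
                       w = rep(1L, 20))
  n <- 30000
  post2 <- replicate(n, {
    th <- update_theta_posterior(ag, hy)
    c(th$mu[2, 1], th$lam[[2]][1, 1])
  })
  prior <- replicate(n, {
    th <- sample_theta_prior(hy, K = 1, F = 1)
    c(th$mu[1, 1], th$lam[[1]][1, 1])
  })
  # matching first two moments of (mu, lambda)
  expect_lt(abs(mean(post2[2, ]) - mean(prior[2, ])),
            3 * sqrt(stats::var(prior[2, ]) * 2 / n))
  expect_lt(abs(stats::var(post2[2, ]) / stats::var(prior[2, ]) - 1), 0.1)
  expect_lt(abs(mean(post2[1, ]) - mean(prior[1, ])), 0.05)
  expect_lt(abs(stats::var(post2[1, ]) / stats::var(prior[1, ]) - 1), 0.15)
})

test_that("the posterior concentrates on the data with many observations", {
  set.seed(107)
  hy <- inter_gmm_hyper(K = 1, m = 0, alpha_bar = 1, nu = 1, beta_bar = 0.01)
  ag <- fixed_agent_1d(x = rep(5, 10000), mu = 0, lam = 1, hyper = hy,
                       w = rep(1L, 10000))
  th <- update_theta_posterior(ag, hy)
  expect_lt(abs(th$mu[1, 1] - 5), 0.05)
})

test_that("the sampled mean's marginal matches brute-force quadrature", {
  # oracle: integrate prior x likelihood over lambda on a mu grid, compare to
  # the Student-t marginal implied by the conjugate-update parameters
  set.seed(108)
  x <- c(0.3, -1.2, 2.1, 0.7, 1.4)
  m0 <- 0.5; a0 <- 2; nu0 <- 3; b0 <- 0.4
  joint <- function(mu, lam) {
    dnorm(mu, m0, 1 / sqrt(a0 * lam)) *
      stats::dgamma(lam, shape = nu0 / 2, rate = 1 / (2 * b0)) *
      prod(dnorm(x, mu, 1 / sqrt(lam)))
  }
  grid <- seq(-1.5, 3, length.out = 181)
  dens_quad <- vapply(grid, function(mu) {
    stats::integrate(function(l) vapply(l, joint, 0, mu = mu), 0, Inf,
                     rel.tol = 1e-10)$value
  }, 0)
  dens_quad <- dens_quad / sum(dens_quad * diff(grid)[1])

  # closed-form marginal from the same update the sampler uses:
  # mu | x ~ t_{nu'}(m', 1 / (alpha' nu' beta'))
  n <- length(x); xb <- mean(x); S <- sum((x - xb)^2)
  ap <- a0 + n; mp <- (a0 * m0 + n * xb) / ap; nup <- nu0 + n
  bp <- 1 / (1 / b0 + S + a0 * n / ap * (xb - m0)^2)
  sc <- 1 / sqrt(ap * nup * bp)
  dens_t <- stats::dt((grid - mp) / sc, df = nup) / sc
  # normalize both densities over the same finite grid so the (analytic)
  # tail mass outside it cancels instead of polluting the comparison
  dens_t <- dens_t / sum(dens_t * diff(grid)[1])
  expect_lt(max(abs(dens_quad - dens_t)), 1e-6)

  # and the sampler itself draws from that marginal (moment check)
  hy <- inter_gmm_hyper(K = 1, m = m0, alpha_bar = a0, nu = nu0, beta_bar = b0)
  ag <- fixed_agent_1d(x = x, mu = 0, lam = 1, hyper = hy,
                       w = rep(1L, length(x)))
  mus <- replicate(40000, update_theta_posterior(ag, hy)$mu[1, 1])
  expect_lt(abs(mean(mus) - mp), 4 * stats::sd(mus) / sqrt(length(mus)))
  expect_lt(abs(stats::var(mus) / (sc^2 * nup / (nup - 2)) - 1), 0.05)
})
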