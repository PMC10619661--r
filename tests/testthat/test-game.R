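make_toy_population <- function(N, D, hyper, seed = 1) {
  set.seed(seed)
  purrr::map(seq_len(N), function(n) {
    fixed_agent_1d(rnorm(D, sd = 2), mu = seq_len(hyper$K) - 1,
                   lam = rep(1, hyper$K), hyper = hyper,
                   w = sample.int(hyper$K, D, replace = TRUE), index = n)
  })
}

test_that("game_config validates its arguments", {
  expect_error(game_config(N = 1, D = 5, K = 2), ">= 2")
  expect_error(game_config(N = 3, D = 5, K = 2, t_inner = 0), "t_inner")
  expect_error(game_config(N = 3, D = 5, K = 2, M = 1), "M")
  expect_error(game_config(N = 3, D = 5, K = 2, M = 4), "M")
  expect_error(game_config(N = 3, D = 5, K = 2, mode = "nope"),
               "should be one of")
  cfg <- game_config(N = 3, D = 5, K = 2, I = 7, t_inner = 2, M = 2,
                     mode = "all_accept", seed = 9)
  expect_s3_class(cfg, "game_config")
  expect_identical(cfg$M, 2L)
})

test_that("mh_receive follows the MH acceptance rule", {
  hy <- inter_gmm_hyper(K = 2)
  # proposed sign strictly better: always adopted
  ag <- fixed_agent_1d(x = 1.8, mu = c(0, 2), lam = c(1, 1), hyper = hy,
                       w = 1L)
  expect_equal(mh_receive(ag, hy, 1, 2L), 2L)
  expect_equal(ag$w[1], 2L)

  # proposed sign worse: accepted with probability = likelihood ratio
  r <- exp(dnorm(0, 1.5518, log = TRUE) - dnorm(0, 0, log = TRUE))
  set.seed(501)
  n <- 20000
  acc <- 0L
  ag2 <- fixed_agent_1d(x = 0, mu = c(0, 1.5518), lam = c(1, 1), hyper = hy,
                        w = 1L)
  for (i in seq_len(n)) {
    ag2$w[1] <- 1L
    if (mh_receive(ag2, hy, 1, 2L) == 2L) acc <- acc + 1L
  }
  expect_lt(abs(acc / n - r), 3 * sqrt(r * (1 - r) / n))

  # an essentially impossible sign is essentially never accepted
  ag3 <- fixed_agent_1d(x = 0, mu = c(0, 8), lam = c(1, 1), hyper = hy, w = 1L)
  set.seed(502)
  res <- replicate(5000, {
    ag3$w[1] <- 1L
    mh_receive(ag3, hy, 1, 2L)
  })
  expect_true(all(res == 1L))  # exp(-32) acceptance

  expect_error(mh_receive(ag3, hy, 1, 3L), "outside")
})

test_that("force_accept adopts everything and consumes no randomness", {
  hy <- inter_gmm_hyper(K = 2)
  ag <- fixed_agent_1d(x = 0, mu = c(0, 8), lam = c(1, 1), hyper = hy, w = 1L)
  cn <- game_counters()
  set.seed(503)
  st <- .Random.seed
  expect_equal(mh_receive(ag, hy, 1, 2L, force_accept = TRUE, counters = cn),
               2L)
  expect_identical(.Random.seed, st)
  expect_equal(cn$proposals, 1L)
  expect_equal(cn$acceptances, 1L)
})

test_that("a singleton group's recursive game is T plain communications", {
  hy <- inter_gmm_hyper(K = 3)
  mk <- function() {
    list(sp = fixed_agent_1d(0.2, mu = 0:2, lam = rep(1, 3), hyper = hy,
                             w = 2L),
         li = fixed_agent_1d(1.1, mu = 0:2, lam = rep(1, 3), hyper = hy,
                             w = 3L, index = 2L))
  }
  for (T in c(1L, 4L)) {
    set.seed(504)
    p1 <- mk()
    rmh_communicate(list(p1$sp), p1$li, hy, 1, t_inner = T)
    st1 <- .Random.seed
    set.seed(504)
    p2 <- mk()
    for (t in seq_len(T)) mh_communicate(p2$sp, p2$li, hy, 1)
    sample.int(2L, 1L)  # the returned-member draw the recursion also makes
    st2 <- .Random.seed
    expect_identical(p1$li$w, p2$li$w)
    expect_identical(st1, st2)
  }
})

test_that("the receiving count follows sum_{i=1}^{M-1} T^i exactly", {
  hy <- inter_gmm_hyper(K = 2)
  for (T in 1:4) {
    for (M in 2:4) {
      ags <- make_toy_population(4, 3, hy, seed = 600 + 10 * T + M)
      cn <- game_counters()
      rmh_communicate(ags[seq_len(M - 1)], ags[[M]], hy, 1, t_inner = T,
                      counters = cn)
      expect_equal(cn$proposals, sum(T^(seq_len(M - 1))),
                   info = sprintf("T=%d M=%d", T, M))
    }
  }
  # headline setting: N = 4 agents, T = 4 -> 4 + 16 + 64 = 84 per object
  ags <- make_toy_population(4, 1, hy)
  cn <- game_counters()
  rmh_communicate(ags[1:3], ags[[4]], hy, 1, t_inner = 4, counters = cn)
  expect_identical(cn$proposals, 84L)
})

test_that("full runs count D * sum T^i proposals per iteration", {
  set.seed(505)
  hy <- inter_gmm_hyper(K = 3, nu = 3, beta_bar = 1)
  ds <- sample_from_generative_model(hy, N = 4, D = 6, F = 1)
  for (spec in list(c(T = 1, M = 2), c(T = 2, M = 3), c(T = 4, M = 4))) {
    ags <- make_agents(ds, hy)
    cfg <- game_config(N = 4, D = 6, K = 3, I = 3, t_inner = spec["T"],
                       M = spec["M"], seed = 2)
    tr <- run_rmhng(ags, hy, cfg)
    per_iter <- 6L * sum(spec[["T"]]^seq_len(spec[["M"]] - 1L))
    expect_true(all(tr$proposals_by_iter == per_iter))
    expect_equal(tr$proposals, 3 * per_iter)
    expect_true(all(tr$acceptances_by_iter <= tr$proposals_by_iter))
  }
})

test_that("the all-accept ablation accepts every proposal", {
  set.seed(506)
  hy <- inter_gmm_hyper(K = 3, nu = 3, beta_bar = 1)
  ds <- sample_from_generative_model(hy, N = 3, D = 8, F = 1)
  ags <- make_agents(ds, hy)
  cfg <- game_config(N = 3, D = 8, K = 3, I = 4, t_inner = 2, M = 3,
                     mode = "all_accept", seed = 3)
  tr <- run_rmhng(ags, hy, cfg)
  expect_gt(tr$proposals, 0L)
  expect_identical(tr$acceptances, tr$proposals)
})

test_that("no-communication mode exchanges no signs at all", {
  set.seed(507)
  hy <- inter_gmm_hyper(K = 3, nu = 3, beta_bar = 1)
  ds <- sample_from_generative_model(hy, N = 3, D = 8, F = 1)
  ags <- make_agents(ds, hy)
  cfg <- game_config(N = 3, D = 8, K = 3, I = 4, mode = "no_comm", seed = 4)
  tr <- run_rmhng(ags, hy, cfg)
  expect_identical(tr$proposals, 0L)
  expect_identical(tr$acceptances, 0L)
  expect_true(all(tr$proposals_by_iter == 0L))
})

test_that("runs are bit-reproducible from (config, data)", {
  set.seed(508)
  hy <- inter_gmm_hyper(K = 3, nu = 3, beta_bar = 1)
  ds <- sample_from_generative_model(hy, N = 3, D = 10, F = 1)
  cfg <- game_config(N = 3, D = 10, K = 3, I = 5, t_inner = 2, M = 3,
                     seed = 42)
  tr1 <- run_rmhng(make_agents(ds, hy), hy, cfg)
  tr2 <- run_rmhng(make_agents(ds, hy), hy, cfg)
  expect_identical(tr1$signs, tr2$signs)
  expect_identical(tr1$acceptances, tr2$acceptances)
  # a different seed gives a different trajectory
  cfg2 <- game_config(N = 3, D = 10, K = 3, I = 5, t_inner = 2, M = 3,
                      seed = 43)
  tr3 <- run_rmhng(make_agents(ds, hy), hy, cfg2)
  expect_false(identical(tr1$signs, tr3$signs))
})

test_that("run_rmhng rejects mismatched agents", {
  hy <- inter_gmm_hyper(K = 2, nu = 3, beta_bar = 1)
  ds <- sample_from_generative_model(hy, N = 2, D = 5, F = 1)
  ags <- make_agents(ds, hy)
  expect_error(run_rmhng(ags[1], hy, game_config(N = 2, D = 5, K = 2)),
               "agents")
  expect_error(run_rmhng(ags, hy, game_config(N = 2, D = 7, K = 2)), "D = 7")
})
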