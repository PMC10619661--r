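#' Configuration of one naming-game run
#'
#' Bundles every knob of a single run: population size, data size, sign
#' inventory, iteration counts, the inner-loop length T, the chain length M of
#' the limited-length approximation, the mode, and the seed.
#'
#' Modes: `"rmhng"` plays the recursive Metropolis-Hastings naming game
#' (set `t_inner = 1` for the one-sample approximation, `M < N` for the
#' limited-length approximation); `"all_accept"` is the ablation in which every
#' listener accepts every proposal (acceptance ratio forced to 1); `"no_comm"`
#' runs N independent per-agent Gibbs mixture samplers with no sign exchange.
#'
#' @param N number of agents (>= 2).
#' @param D number of objects.
#' @param K sign inventory size.
#' @param I outer iterations.
#' @param t_inner inner-loop length T (>= 1); T = 1 is the one-sample (OS)
#'   approximation.
#' @param M communication chain length, `2..N`; `M = N` means no truncation,
#'   `M = 2` is the random-pairing limited-length (LL) approximation.
#' @param mode one of `"rmhng"`, `"all_accept"`, `"no_comm"`.
#' @param seed integer seed; a run is bit-reproducible given `(config, data)`.
#' @param init sign initialization: `"prior"` draws each agent's theta from the
#'   prior and its signs from the resulting posterior (requires a proper prior,
#'   `nu > F - 1`); `"uniform"` draws signs uniformly and enters the first
#'   iteration through the conjugate update.
#' @return A list of class `game_config`.
#' @export
game_config <- function(N, D, K, I = 100L, t_inner = 4L, M = N,
                        mode = c("rmhng", "all_accept", "no_comm"),
                        seed = 1L, init = c("prior", "uniform")) {
  mode <- match.arg(mode)
  init <- match.arg(init)
  N <- as.integer(N); D <- as.integer(D); K <- as.integer(K)
  I <- as.integer(I); t_inner <- as.integer(t_inner); M <- as.integer(M)
  if (N < 2L) stop("`N` must be >= 2")
  if (D < 1L || K < 1L || I < 1L) stop("`D`, `K`, `I` must be positive")
  if (t_inner < 1L) stop("`t_inner` (T) must be >= 1")
  if (M < 2L || M > N) stop("`M` must lie in 2..N")
  structure(
    list(N = N, D = D, K = K, I = I, t_inner = t_inner, M = M, mode = mode,
         seed = as.integer(seed), init = init),
    class = "game_config"
  )
}

#' @export
print.game_config <- function(x, ...) {
  cat(sprintf(
    "Naming-game config: mode = %s, N = %d, D = %d, K = %d, I = %d, T = %d, M = %d, seed = %d\n",
    x$mode, x$N, x$D, x$K, x$I, x$t_inner, x$M, x$seed))
  invisible(x)
}

#' Proposal/acceptance counters
#'
#' A mutable counter passed through the game functions; every elementary
#' MH-receiving step increments `proposals`, every accepted one `acceptances`.
#'
#' @return An environment with integer fields `proposals` and `acceptances`.
#' @export
game_counters <- function() {
  cn <- new.env(parent = emptyenv())
  cn$proposals <- 0L
  cn$acceptances <- 0L
  cn
}

#' MH receiving: a listener decides whether to adopt a proposed sign
#'
#' The listener compares the likelihood of its own percept of object `d` under
#' the proposed sign against the current one and accepts with probability
#' \eqn{r = \min(1, P(x_d \mid \theta, w^\star) / P(x_d \mid \theta, w_d))},
#' the Metropolis-Hastings ratio for the shared sign when the speaker's own
#' posterior is the proposal distribution. On acceptance the listener's sign
#' for `d` is overwritten. With `force_accept = TRUE` (the All-acceptance
#' ablation) the proposal is always adopted and no randomness is consumed.
#'
#' @param listener an [agent_state()] (modified in place).
#' @param hyper an [inter_gmm_hyper()].
#' @param d object index.
#' @param proposed proposed sign index in `1..K`.
#' @param force_accept if `TRUE`, accept unconditionally.
#' @param counters optional [game_counters()] to update.
#' @return The listener's sign for `d` after the decision.
#' @export
mh_receive <- function(listener, hyper, d, proposed, force_accept = FALSE,
                       counters = NULL) {
  if (proposed < 1L || proposed > listener$K) {
    stop("proposed sign ", proposed, " outside 1..", listener$K)
  }
  if (force_accept) {
    accept <- TRUE
  } else {
    logr <- listener$ll[d, proposed] - listener$ll[d, listener$w[d]]
    accept <- logr >= 0 || runif(1L) < exp(logr)
  }
  if (!is.null(counters)) {
    counters$proposals <- counters$proposals + 1L
    if (accept) counters$acceptances <- counters$acceptances + 1L
  }
  if (accept) listener$w[d] <- as.integer(proposed)
  listener$w[d]
}

#' MH communication: one speaker-to-listener exchange
#'
#' The speaker utters a sign for object `d` by sampling its own sign posterior;
#' the listener then runs [mh_receive()] on it. This is the elementary step of
#' the naming game and, with roles alternating, a Metropolis-Hastings sampler
#' of the two-agent sign posterior
#' \eqn{P(w_d \mid x_d^{Sp}, x_d^{Li}, \theta^{Sp}, \theta^{Li})}.
#'
#' @param speaker,listener distinct [agent_state()]s.
#' @inheritParams mh_receive
#' @return The listener's sign for `d` after the exchange.
#' @export
mh_communicate <- function(speaker, listener, hyper, d, force_accept = FALSE,
                           counters = NULL) {
  s <- sample_sign(speaker, hyper, d)
  mh_receive(listener, hyper, d, s, force_accept, counters)
}

#' Recursive MH communication among a chain of agents
#'
#' Extends MH communication to `n + 1` agents: the game among the first `n`
#' agents acts as the proposal distribution for the `(n+1)`-th. Concretely,
#' `t_inner` times: if the group has a single agent, it plays plain
#' [mh_communicate()] with the target; otherwise the group minus its last
#' member plays recursively with that last member, and the resulting sign is
#' offered to the target through [mh_receive()]. After the loop the current
#' sign of one agent drawn uniformly from the group plus target is returned.
#' As `t_inner` grows this converges to an MCMC sampler of
#' \eqn{P(w_d \mid x_d^{1:n+1}, \theta^{1:n+1})}.
#'
#' The number of elementary receiving steps is exactly
#' \eqn{\sum_{i=1}^{n} T^i} for a group of size n — exponential in the chain
#' length, which is what the one-sample (T = 1) and limited-length (smaller
#' chain) approximations curb.
#'
#' @param group non-empty list of [agent_state()]s (the proposal side).
#' @param target an [agent_state()] not in `group`.
#' @inheritParams mh_receive
#' @param t_inner inner-loop length T.
#' @return A sign index in `1..K`.
#' @export
rmh_communicate <- function(group, target, hyper, d, t_inner,
                            force_accept = FALSE, counters = NULL) {
  n <- length(group)
  if (n < 1L) stop("`group` must contain at least one agent")
  if (n == 1L) {
    sp <- group[[1L]]
    for (t in seq_len(t_inner)) {
      mh_communicate(sp, target, hyper, d, force_accept, counters)
    }
  } else {
    sub <- group[-n]
    mid <- group[[n]]
    for (t in seq_len(t_inner)) {
      s <- rmh_communicate(sub, mid, hyper, d, t_inner, force_accept, counters)
      mh_receive(target, hyper, d, s, force_accept, counters)
    }
  }
  j <- sample.int(n + 1L, 1L)
  if (j <= n) group[[j]]$w[d] else target$w[d]
}

#' Play a full recursive MH naming game
#'
#' Runs `config$I` outer iterations. In each iteration, for every object in
#' turn, the agent order is freshly shuffled, the first `M` agents of the
#' shuffle form the communication chain (first `M - 1` as the recursive group,
#' the `M`-th as target), and one [rmh_communicate()] is played. After all
#' objects, every agent resamples its component parameters from the conjugate
#' posterior given its own observations and current signs. The mode
#' `"no_comm"` replaces communication by an independent per-agent Gibbs sweep
#' (resample every sign from the agent's own posterior); `"all_accept"` forces
#' every acceptance.
#'
#' Agents are (re-)initialized at the start according to `config$init`, and are
#' modified in place; the returned trace records every agent's signs after each
#' iteration.
#'
#' @param agents list of N [agent_state()]s over the same objects.
#' @param hyper an [inter_gmm_hyper()].
#' @param config a [game_config()].
#' @return A [sign_trace] object.
#' @examples
#' hy <- inter_gmm_hyper(K = 3, nu = 3, beta_bar = 1)
#' ds <- sample_from_generative_model(hy, N = 2, D = 30, F = 1)
#' ags <- make_agents(ds, hy)
#' tr <- run_rmhng(ags, hy, game_config(N = 2, D = 30, K = 3, I = 5, seed = 1))
#' glance(tr)
#' @export
run_rmhng <- function(agents, hyper, config) {
  N <- config$N
  if (length(agents) != N) stop("need ", N, " agents, got ", length(agents))
  D <- config$D
  K <- config$K
  if (any(vapply(agents, function(a) a$D, 0L) != D)) {
    stop("all agents must hold D = ", D, " objects")
  }
  if (any(vapply(agents, function(a) a$K, 0L) != K) || hyper$K != K) {
    stop("agents and hyper must share the sign inventory size K = ", K)
  }
  set.seed(config$seed)
  init_agents(agents, hyper, config)

  I <- config$I
  M <- config$M
  t_inner <- config$t_inner
  force <- config$mode == "all_accept"
  communicate <- config$mode != "no_comm"
  counters <- game_counters()
  signs <- array(0L, dim = c(I, N, D))
  prop_iter <- integer(I)
  acc_iter <- integer(I)

  for (i in seq_len(I)) {
    p0 <- counters$proposals
    a0 <- counters$acceptances
    if (communicate) {
      for (d in seq_len(D)) {
        ord <- sample.int(N)
        sel <- ord[seq_len(M)]
        rmh_communicate(agents[sel[-M]], agents[[sel[M]]], hyper, d, t_inner,
                        force, counters)
      }
    } else {
      for (n in seq_len(N)) resample_signs_from_posterior(agents[[n]])
    }
    for (n in seq_len(N)) {
      set_agent_theta(agents[[n]], update_theta_posterior(agents[[n]], hyper),
                      hyper)
    }
    for (n in seq_len(N)) signs[i, n, ] <- agents[[n]]$w
    prop_iter[i] <- counters$proposals - p0
    acc_iter[i] <- counters$acceptances - a0
  }
  new_sign_trace(signs, K, counters$proposals, counters$acceptances,
                 prop_iter, acc_iter, mode = config$mode, config = config)
}

# Draw initial theta and signs for every agent per config$init.
init_agents <- function(agents, hyper, config) {
  for (ag in agents) {
    if (config$init == "prior") {
      set_agent_theta(ag, sample_theta_prior(hyper, ag$K, ag$F), hyper)
      resample_signs_from_posterior(ag)
    } else {
      ag$w <- as.integer(sample.int(ag$K, ag$D, replace = TRUE))
      set_agent_theta(ag, update_theta_posterior(ag, hyper), hyper)
    }
  }
  invisible(agents)
}

#' Build one agent per view of a dataset
#'
#' @param dataset a [synthetic_dataset] (or any list with a `features` list of
#'   per-agent D x F matrices).
#' @param hyper an [inter_gmm_hyper()].
#' @return A list of [agent_state()]s.
#' @export
make_agents <- function(dataset, hyper) {
  purrr::imap(dataset$features, function(xn, n) {
    agent_state(xn, hyper, index = n)
  })
}
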