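---
title: "The recursive Metropolis-Hastings naming game"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The recursive Metropolis-Hastings naming game}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(rmhng)
```

## The problem: naming things without a referee

Suppose several agents observe the same set of objects, but each through its
own private sensors. No agent can see another's percepts, and there is no
central coordinator. Can the population nevertheless converge on a *shared*
discrete vocabulary — the same sign attached to the same object by everyone —
and can that vocabulary be *correct*, in the sense of carving the objects
into their true underlying categories?

This package implements a family of naming games in which the answer is yes,
and in which the game itself is a decentralized Markov chain Monte Carlo
sampler of a well-defined Bayesian posterior. Agreement is not imposed; it
emerges because every local speak-and-listen interaction is a
Metropolis-Hastings (MH) step targeting the posterior over signs given
*everyone's* observations.

## The generative model

The model (an inter-agent Gaussian mixture, `inter_gmm_hyper()`) couples N
per-agent Gaussian mixtures through a single shared latent sign per object:

* for each object $d$, a sign $w_d \sim \mathrm{Cat}(\gamma)$ drawn from a
  shared inventory of $K$ signs (uniform $\gamma$ by default);
* each agent $n$ has its own per-sign Gaussian parameters
  $(\mu^n_k, \Lambda^n_k) \sim \mathcal{NW}(m, \bar\alpha, \nu, \bar\beta)$,
  a Normal-Wishart prior;
* agent $n$'s percept of object $d$ is
  $x^n_d \sim \mathcal{N}(\mu^n_{w_d}, (\Lambda^n_{w_d})^{-1})$.

The sign is the *only* shared variable. Conditional on signs, each agent's
parameter posterior is conjugate (`update_theta_posterior()`); conditional on
parameters, the posterior over a sign factorizes over agents,

$$P(w_d = k \mid x^{1:N}_d, \theta^{1:N}) \propto
  \gamma_k \prod_{n=1}^{N} \mathcal{N}(x^n_d \mid \mu^n_k, (\Lambda^n_k)^{-1}),$$

which `exact_posterior_w()` enumerates. Computing it requires reading every
agent's private state simultaneously, which is exactly what decentralized
agents cannot do — it serves as the reference, not as a mechanism.

## The game as a sampler

The elementary interaction (`mh_communicate()`) is: a speaker utters a sign
for object $d$ by sampling its own sign posterior; the listener accepts it
with probability

$$r = \min\!\left(1,
  \frac{P(x^{Li}_d \mid \theta^{Li}, w^\star)}
       {P(x^{Li}_d \mid \theta^{Li}, w^{Li}_d)}\right),$$

its own likelihood ratio. This is an independence MH step: the speaker's
posterior is the proposal, the listener's likelihood the correction, and the
invariant distribution is the *two-agent* sign posterior. Neither agent ever
sees the other's percepts — only signs cross the channel.

The recursive game (`rmh_communicate()`) lifts this to $n + 1$ agents: the
game among $n$ agents acts as the proposal distribution for agent $n + 1$,
who filters it through the same likelihood-ratio rule. One call with a group
of size $n$ and inner-loop length $T$ costs exactly
$\sum_{i=1}^{n} T^i$ elementary receiving steps — exponential in the chain
length, which motivates two approximations:

* **one-sample (OS)**: set $T = 1$;
* **limited-length (LL)**: truncate the chain to $M < N$ randomly chosen
  agents per object.

The full loop (`run_rmhng()`) iterates: for every object, shuffle the agent
order, play one recursive game along the chain; then every agent refreshes
its Gaussian parameters from its conjugate posterior given its current signs.

One property of the recursion is worth stating plainly, because it is easy to
miss: within a *single* call the deepest speaker only ever speaks, so its own
sign assignment is not refreshed. Convergence of the returned sign to the
joint posterior relies on the role rotation supplied by the per-object
shuffle of the outer loop. Our long-run tests verify the sampler in exactly
that rotating-role regime; with roles artificially frozen the returned-sign
distribution is measurably biased, and no amount of inner iteration repairs
it. This is a property of the algorithm, not of the implementation.

## Baselines and topline

Three comparison modes bracket the game (`game_config(mode = ...)` and the
`gibbs` condition):

* **No communication**: each agent runs an independent Gibbs sampler of its
  own mixture; private clustering can be good, but there is no reason for
  sign conventions to align across agents (chance-level pairwise agreement).
* **All acceptance**: every proposal is adopted ($r = 1$). Agents copy each
  other happily, so agreement is easy — but the shared labels are no longer
  filtered against anyone's likelihood, and accuracy collapses.
* **Centralized Gibbs** (`run_gibbs()`): a sampler that reads all private
  states and samples the shared sign exactly — the topline no decentralized
  scheme can beat, used both as a performance ceiling and as the reference
  for the sign-distribution agreement score.

## The synthetic benchmark

`make_experiment1_dataset()` builds the four-agent benchmark: five
4-dimensional Gaussian components (identity covariance), with coordinate $n$
of every point handed to agent $n$ as its private 1-D view. The component
means are chosen so that for agent $n$, components $n$ and $n + 1$ have the
*same* marginal mean: every agent is blind to one specific pair of
categories. No agent can recover the five categories alone; the population
can, but only by communicating.

The benchmark draws 50 points per component (D = 250 objects) by default.
This size is deliberate: large enough that the adjusted Rand index and kappa
are stable across seeds, small enough that a full 100-iteration, five-seed,
seven-condition study runs on one desktop CPU core in minutes. The number of
points per component is a genuine free parameter of the benchmark — the
sharpness of every agent's sign posterior, and with it the ceiling of the
decentralized methods' per-iteration scores, grows with it (see Limitations).

## Evaluation

`trace_metrics()` scores every iteration of a run:

* **ARI** (`adjusted_rand_index()`): each agent's sign assignment against the
  generating labels — correctness of the emergent categories, permutation
  invariant.
* **mean pairwise kappa** (`cohen_kappa()`, `mean_pairwise_kappa()`):
  chance-corrected agreement between agents' assignments — sharedness of the
  convention. Not permutation invariant, deliberately: agents must use the
  *same* labels, not merely isomorphic ones.
* **posterior agreement** (`posterior_agreement()`,
  `compare_to_reference()`): pools each run's final-window sign draws into
  per-object empirical distributions, aligns sign labels to the reference by
  exhaustive one-to-one matching, and reports the mean per-object overlap
  with the centralized Gibbs reference — how close the decentralized sampler
  gets to the true posterior, not just to a point estimate.

Headline numbers average iterations 91–100 of 100 over five seeds.

## A small worked run

```{r worked, fig.width = 6, fig.height = 3}
cfg <- default_experiment_config(conditions = c("rmhng", "no_comm", "gibbs"),
                                 seeds = 1:2)
cfg$dataset$n_per_component <- 10   # keep the vignette quick
cfg$game$I <- 30
res <- run_experiment(cfg, quiet = TRUE)
res$summary
autoplot(res)
```

Even at this reduced scale the structure is visible: the centralized Gibbs
run is the ceiling, the full game tracks it, and without communication the
pairwise kappa sits at chance while the private clustering (ARI) is stuck at
the level a single aliased view permits.

## Numerical choices

* All likelihood and posterior computations are in log space with max
  subtraction before exponentiation.
* Wishart draws use the Bartlett decomposition, valid for non-integer
  degrees of freedom $\nu > F - 1$; an improper prior is rejected with an
  error rather than silently truncated. In one dimension the draw reduces to
  a scaled chi-square.
* Each agent caches its $D \times K$ log-likelihood matrix whenever its
  parameters change, making the inner game loop a table lookup; the full
  benchmark (84 receives per object per iteration) runs in well under a
  minute per seed in pure R.
* Runs are bit-reproducible: one global RNG stream seeded from
  `config$seed`; identical config and data give byte-identical traces.
* Sign-label alignment in `posterior_agreement()` enumerates permutations
  exactly (feasible for $K \le 8$; the benchmark uses $K = 5$, i.e. 120
  permutations) rather than using a heuristic matching.

## Defaults that are choices, not facts

Several knobs of the benchmark have no single canonical value, and the
package exposes all of them:

* the inner-loop length defaults to $T = 4$ and the chain to $M = N$;
* hyperparameters default to $m = 0$, $\bar\alpha = 1$, $\nu = 1$,
  $\bar\beta = 0.01$ (scale parameterization of the Wishart);
* signs initialize from each agent's prior-parameter posterior; a uniform
  initialization is available (`game$init = "uniform"`);
* the evaluation window defaults to the last 10 iterations.

## Limitations

* **Per-iteration churn.** With a fixed uniform sign prior the posterior
  pays no penalty for letting two signs share a category, so even a
  converged run keeps resampling a fraction of borderline objects each
  iteration. Per-iteration ARI/kappa therefore saturate below 1 even when
  the modal assignment is exactly right; the ceiling rises with the number
  of points per component. Treat absolute levels as functions of the data
  size, and prefer the relative ordering of methods, which is stable.
* The recursive game is an *approximate* sampler at finite $T$, and its
  returned-sign distribution carries a small bias even with role rotation.
* Cost grows as $\sum_i T^i$ per object; the OS/LL approximations trade
  accuracy for tractability and their quality degrades in the measured
  order (OS mildest, OS&LL strongest degradation).
* Feature extraction is out of scope: agents consume precomputed feature
  tables (`load_feature_table()`); nothing in the package learns
  representations.
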