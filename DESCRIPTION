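Package: rmhng
Title: Recursive Metropolis-Hastings Naming Games for Decentralized Bayesian Symbol Emergence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates naming games in which a population of agents, each observing
    only a private projection of shared objects, converges on a common categorical
    sign system. Implements the recursive Metropolis-Hastings naming game over a
    multi-agent Gaussian mixture with Normal-Wishart priors, its one-sample (T = 1)
    and limited-length (chain truncation) approximations, All-acceptance and
    No-communication baselines, and a centralized Gibbs sampler topline. Includes
    a synthetic-data generator with deliberately aliased per-agent views, clustering
    agreement metrics (adjusted Rand index, mean pairwise Cohen's kappa, posterior
    sign-distribution agreement), tidy per-iteration metric tables, and ggplot2
    visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    mclust,
    purrr,
    readr,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
Suggests:
    e1071,
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
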