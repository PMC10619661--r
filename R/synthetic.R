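#' Component means of the four-agent benchmark mixture
#'
#' A 5 x 4 matrix: five 4-dimensional Gaussian component means, one column per
#' agent. The columns are deliberately aliased: for agent n, components n and
#' n + 1 share the same marginal mean (and unit variance), so no single agent
#' can separate them from its own view alone — only communication can.
#'
#' @return A 5 x 4 numeric matrix.
#' @export
experiment1_means <- function() {
  matrix(c(
    0, 1, 2, 3,
    0, 5, 6, 7,
    8, 5, 10, 11,
    12, 13, 10, 15,
    16, 17, 18, 15
  ), nrow = 5, byrow = TRUE,
  dimnames = list(component = NULL, agent = NULL))
}

new_synthetic_dataset <- function(features, labels, truth = NULL) {
  structure(list(features = features, labels = as.integer(labels),
                 truth = truth),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic dataset: %d agents, %d objects, feature dims [%s]%s\n",
    length(x$features), nrow(x$features[[1]]),
    paste(vapply(x$features, ncol, 0L), collapse = ", "),
    if (is.null(x$labels) || !length(x$labels)) ", no labels" else
      sprintf(", %d label classes", length(unique(x$labels)))))
  invisible(x)
}

#' Generate the four-agent benchmark dataset
#'
#' Draws `n_per_component` points from each of five 4-dimensional Gaussians
#' with means [experiment1_means()] and identity covariance, then hands the
#' n-th coordinate of every point to agent n as its 1-dimensional observation.
#' Rows are shuffled consistently across agents, so row d is the same object
#' in every agent's view and in `labels`.
#'
#' Because components n and n + 1 look identical to agent n, any single agent
#' clustering alone merges them; the benchmark measures whether the naming
#' game lets the population recover all five components jointly.
#'
#' @param n_per_component points drawn from each component (>= 1).
#' @return A `synthetic_dataset`: `features` is a list of four D x 1 matrices
#'   (D = 5 * n_per_component), `labels` the generating component of each row.
#' @examples
#' set.seed(1)
#' ds <- make_experiment1_dataset(10)
#' table(ds$labels)
#' @export
make_experiment1_dataset <- function(n_per_component = 50L) {
  n_per_component <- as.integer(n_per_component)
  stopifnot(n_per_component >= 1L)
  mu <- experiment1_means()
  K <- nrow(mu)
  N <- ncol(mu)
  D <- K * n_per_component
  labels <- rep(seq_len(K), each = n_per_component)
  pts <- matrix(rnorm(D * N), D, N) + mu[labels, ]
  ord <- sample.int(D)
  pts <- pts[ord, , drop = FALSE]
  labels <- labels[ord]
  features <- purrr::map(seq_len(N), function(n) pts[, n, drop = FALSE])
  new_synthetic_dataset(features, labels)
}

#' Sample a dataset from the multi-agent mixture's own generative process
#'
#' Forward-samples the model itself: a shared sign \eqn{w_d \sim Cat(\gamma)}
#' per object, per-agent component parameters from the Normal-Wishart prior,
#' and per-agent observations \eqn{x_d^n \sim N(\mu_{w_d}^n,
#' (\Lambda_{w_d}^n)^{-1})}. Returns the true per-agent parameters alongside,
#' for parameter-recovery checks.
#'
#' @param hyper an [inter_gmm_hyper()] with a proper prior (`nu > F - 1`).
#' @param N number of agents.
#' @param D number of objects.
#' @param K number of components (defaults to `hyper$K`).
#' @param F feature dimension per agent.
#' @return A `synthetic_dataset` whose `truth` field is the list of true
#'   `agent_theta`s.
#' @export
sample_from_generative_model <- function(hyper, N, D, K = hyper$K, F = 1L) {
  if (K != hyper$K) stop("`K` must match `hyper$K` = ", hyper$K)
  hx <- expand_hyper(hyper, F)
  if (hx$nu <= F - 1) {
    stop("forward sampling needs a proper prior: nu > F - 1 (nu = ",
         hx$nu, ", F = ", F, ")")
  }
  w <- sample.int(K, D, replace = TRUE, prob = hyper$gamma)
  truth <- vector("list", N)
  features <- vector("list", N)
  for (n in seq_len(N)) {
    th <- sample_theta_prior(hyper, K, F)
    truth[[n]] <- th
    x <- matrix(0, D, F)
    for (k in seq_len(K)) {
      idx <- which(w == k)
      if (!length(idx)) next
      U <- chol(th$lam[[k]])
      z <- matrix(rnorm(length(idx) * F), length(idx), F)
      x[idx, ] <- sweep(t(backsolve(U, t(z))), 2L, th$mu[k, ], `+`)
    }
    features[[n]] <- x
  }
  new_synthetic_dataset(features, w, truth = truth)
}

#' Load per-agent feature tables from delimited text files
#'
#' One file per agent; each file holds one row per object and numeric feature
#' columns (header optional, any of comma/tab/whitespace delimiters readable by
#' [utils::read.table()]/readr). All files must describe the same number of
#' objects. Intended for precomputed features standing in for a perception
#' pipeline.
#'
#' @param paths character vector of file paths, one per agent.
#' @param labels optional ground-truth labels: an integer vector or the path of
#'   a JSON/one-column text file holding them.
#' @param delim field delimiter; `NULL` (default) lets readr guess from the
#'   extension (`.csv` comma, `.tsv` tab, otherwise whitespace).
#' @return A `synthetic_dataset` (labels may be absent).
#' @export
load_feature_table <- function(paths, labels = NULL, delim = NULL) {
  stopifnot(length(paths) >= 1L)
  features <- purrr::map(paths, function(p) {
    if (!file.exists(p)) stop("feature table not found: ", p)
    dl <- delim %||% switch(tools::file_ext(p), csv = ",", tsv = "\t", "")
    df <- tryCatch(
      if (identical(dl, "")) utils::read.table(p, header = FALSE)
      else readr::read_delim(p, delim = dl, col_names = FALSE,
                             show_col_types = FALSE, progress = FALSE),
      error = function(e) stop("failed to parse ", p, ": ",
                               conditionMessage(e)))
    bad <- which(!vapply(df, is.numeric, TRUE))
    if (length(bad)) {
      stop("non-numeric cells in ", p, " (column ", bad[1], ")")
    }
    as.matrix(df)
  })
  Ds <- vapply(features, nrow, 0L)
  if (length(unique(Ds)) > 1L) {
    i <- which(Ds != Ds[1])[1]
    stop("inconsistent number of objects across agents: ", paths[1], " has ",
         Ds[1], " rows but ", paths[i], " has ", Ds[i])
  }
  if (is.character(labels)) {
    labels <- if (grepl("\\.json$", labels)) {
      unlist(yaml::read_yaml(labels))  # JSON is a YAML subset
    } else {
      utils::read.table(labels, header = FALSE)[[1]]
    }
  }
  if (!is.null(labels) && length(labels) != Ds[1]) {
    stop("labels have length ", length(labels), " but tables have ",
         Ds[1], " rows")
  }
  new_synthetic_dataset(features, labels %||% integer(0))
}

#' Write a dataset as per-agent delimited feature tables
#'
#' Inverse of [load_feature_table()]: one headerless CSV per agent plus an
#' optional one-column label file.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix; agent n goes to `<prefix>_agent<n>.csv`.
#' @return Invisibly, the written feature-file paths.
#' @export
write_feature_table <- function(dataset, dir, prefix = "features") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- purrr::imap_chr(dataset$features, function(xn, n) {
    p <- file.path(dir, sprintf("%s_agent%d.csv", prefix, n))
    utils::write.table(xn, p, sep = ",", row.names = FALSE, col.names = FALSE)
    p
  })
  if (length(dataset$labels)) {
    utils::write.table(dataset$labels, file.path(dir, paste0(prefix, "_labels.csv")),
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
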