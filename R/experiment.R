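#' Read or write an experiment configuration
#'
#' Experiments are described by one YAML (or JSON — a YAML subset) document
#' with blocks `dataset`, `model`, `game`, a `conditions` list and a `seeds`
#' list; [default_experiment_config()] documents every key with the benchmark
#' defaults. Round-trips through [write_experiment_config()] modulo key order.
#'
#' @param path file to read from / write to.
#' @return `read_experiment_config()` returns the config as a named list.
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_experiment_config(cfg)
}

#' @rdname read_experiment_config
#' @param config a config list.
#' @export
write_experiment_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Default configuration of the synthetic four-agent benchmark
#'
#' Five 4-dimensional Gaussian components observed one coordinate per agent
#' (50 points per component), a 5-sign inventory, hyperparameters
#' \eqn{\bar\alpha = 1, m = 0, \bar\beta = 0.01, \nu = 1}, uniform sign prior,
#' 100 iterations, inner-loop length T = 4, untruncated chain M = N = 4, five
#' seeds per condition.
#'
#' @param conditions character vector of condition presets; any of `"rmhng"`,
#'   `"os"` (T = 1), `"ll"` (M = 2), `"os_ll"`, `"no_comm"`, `"all_accept"`,
#'   `"gibbs"`.
#' @param seeds integer vector of run seeds.
#' @return A config list accepted by [run_experiment()].
#' @export
default_experiment_config <- function(conditions = c("rmhng", "os", "ll",
                                                     "os_ll", "no_comm",
                                                     "all_accept", "gibbs"),
                                      seeds = 1:5) {
  list(
    dataset = list(type = "experiment1", n_per_component = 50L, seed = 1L),
    model = list(K = 5L, m = 0, alpha_bar = 1, nu = 1, beta_bar = 0.01),
    game = list(I = 100L, T = 4L, M = NULL, init = "prior"),
    conditions = as.list(conditions),
    seeds = as.list(as.integer(seeds)),
    eval_window = 10L
  )
}

condition_presets <- c("rmhng", "os", "ll", "os_ll", "no_comm", "all_accept",
                       "gibbs")

validate_experiment_config <- function(cfg) {
  bad <- character(0)
  if (is.null(cfg$dataset) ||
      !identical(cfg$dataset$type, "experiment1") &&
      !identical(cfg$dataset$type, "files")) {
    bad <- c(bad, "dataset.type (must be 'experiment1' or 'files')")
  }
  if (identical(cfg$dataset$type, "files") && is.null(cfg$dataset$paths)) {
    bad <- c(bad, "dataset.paths (required when dataset.type = 'files')")
  }
  if (is.null(cfg$model$K)) bad <- c(bad, "model.K")
  if (is.null(cfg$game$I)) bad <- c(bad, "game.I")
  if (is.null(cfg$seeds) || !length(cfg$seeds)) bad <- c(bad, "seeds")
  conds <- unlist(cfg$conditions)
  if (is.null(conds) || !length(conds)) {
    bad <- c(bad, "conditions")
  } else if (!all(conds %in% condition_presets)) {
    bad <- c(bad, paste0("conditions (unknown: ",
                         paste(setdiff(conds, condition_presets), collapse = ", "),
                         ")"))
  }
  if (length(bad)) {
    stop("invalid experiment config; offending keys: ",
         paste(bad, collapse = "; "))
  }
  cfg
}

# Resolve a condition preset to (mode, T, M, engine).
resolve_condition <- function(name, N, game) {
  t_full <- as.integer(game$T %||% 4L)
  m_full <- as.integer(game$M %||% N)
  switch(name,
    rmhng      = list(mode = "rmhng", t_inner = t_full, M = m_full, gibbs = FALSE),
    os         = list(mode = "rmhng", t_inner = 1L, M = m_full, gibbs = FALSE),
    ll         = list(mode = "rmhng", t_inner = t_full, M = 2L, gibbs = FALSE),
    os_ll      = list(mode = "rmhng", t_inner = 1L, M = 2L, gibbs = FALSE),
    no_comm    = list(mode = "no_comm", t_inner = t_full, M = m_full, gibbs = FALSE),
    all_accept = list(mode = "all_accept", t_inner = t_full, M = m_full, gibbs = FALSE),
    gibbs      = list(mode = "rmhng", t_inner = t_full, M = m_full, gibbs = TRUE),
    stop("unknown condition: ", name)
  )
}

build_dataset <- function(cfg) {
  ds <- cfg$dataset
  if (identical(ds$type, "experiment1")) {
    set.seed(as.integer(ds$seed %||% 1L))
    make_experiment1_dataset(as.integer(ds$n_per_component %||% 50L))
  } else {
    load_feature_table(unlist(ds$paths), labels = ds$labels)
  }
}

build_hyper <- function(cfg, K) {
  md <- cfg$model
  gamma <- md$gamma
  if (is.null(gamma) || identical(gamma, "uniform")) gamma <- NULL
  inter_gmm_hyper(K = K, gamma = gamma, m = md$m %||% 0,
                  alpha_bar = md$alpha_bar %||% 1, nu = md$nu %||% 1,
                  beta_bar = md$beta_bar %||% 1)
}

#' Run a full naming-game experiment
#'
#' Executes every requested condition for every seed on one dataset, computes
#' per-iteration metrics (per-agent adjusted Rand index against ground truth
#' where available, mean pairwise kappa, acceptance rate) and a trailing-window
#' summary (mean and sd across seeds of each agent's ARI and of kappa over the
#' last `eval_window` iterations). Optionally writes everything under `out`:
#' one long CSV per trace, a tidy metrics table, the summary table and the
#' resolved configuration.
#'
#' @param config a config list (see [default_experiment_config()]) or the path
#'   of a YAML file holding one.
#' @param out optional output directory.
#' @param quiet suppress progress messages.
#' @return An object of class `rmhng_experiment`: list with `traces` (nested
#'   list `[[condition]][[seed]]`), `metrics` (tibble), `summary` (tibble),
#'   `dataset`, `hyper`, `config`.
#' @export
run_experiment <- function(config, out = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_experiment_config(config)
  config <- validate_experiment_config(config)
  dataset <- build_dataset(config)
  N <- length(dataset$features)
  D <- nrow(dataset$features[[1]])
  K <- as.integer(config$model$K)
  hyper <- build_hyper(config, K)
  seeds <- as.integer(unlist(config$seeds))
  conds <- unlist(config$conditions)
  I <- as.integer(config$game$I)
  window <- as.integer(config$eval_window %||% 10L)
  labels <- if (length(dataset$labels)) dataset$labels else NULL

  traces <- list()
  metric_rows <- list()
  for (cname in conds) {
    rc <- resolve_condition(cname, N, config$game)
    traces[[cname]] <- list()
    for (si in seq_along(seeds)) {
      if (!quiet) message(sprintf("condition %-10s seed %d", cname, seeds[si]))
      gc_run <- game_config(N = N, D = D, K = K, I = I, t_inner = rc$t_inner,
                            M = rc$M, mode = rc$mode, seed = seeds[si],
                            init = config$game$init %||% "prior")
      agents <- make_agents(dataset, hyper)
      tr <- if (rc$gibbs) run_gibbs(agents, hyper, gc_run)
            else run_rmhng(agents, hyper, gc_run)
      traces[[cname]][[si]] <- tr
      mt <- trace_metrics(tr, labels)
      mt$condition <- cname
      mt$seed <- seeds[si]
      metric_rows[[length(metric_rows) + 1L]] <- mt
    }
  }
  metrics <- dplyr::bind_rows(metric_rows)
  metrics <- dplyr::relocate(metrics, "condition", "seed")
  summary <- summarize_experiment(metrics, I = I, window = window)
  res <- structure(
    list(traces = traces, metrics = metrics, summary = summary,
         dataset = dataset, hyper = hyper, config = config),
    class = "rmhng_experiment"
  )
  if (!is.null(out)) write_experiment(res, out)
  res
}

#' Trailing-window summary of an experiment's metric table
#'
#' @param metrics the tidy per-iteration metric table of [run_experiment()].
#' @param I total iterations in the runs.
#' @param window trailing window length to average over.
#' @return One row per condition: columns `ari_agent<n>` / `ari_agent<n>_sd`
#'   for each agent and `kappa` / `kappa_sd`, means and sds taken across seeds
#'   of the per-seed window means.
#' @export
summarize_experiment <- function(metrics, I = max(metrics$iteration),
                                 window = 10L) {
  iters <- (I - window + 1L):I
  per_seed <- metrics |>
    dplyr::filter(.data$iteration %in% iters) |>
    dplyr::group_by(.data$condition, .data$seed, .data$agent) |>
    dplyr::summarise(ari = mean(.data$ari), kappa = mean(.data$kappa),
                     .groups = "drop")
  ari_wide <- per_seed |>
    dplyr::group_by(.data$condition, .data$agent) |>
    dplyr::summarise(mean = mean(.data$ari), sd = stats::sd(.data$ari),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "agent",
                       values_from = c("mean", "sd"),
                       names_glue = "ari_agent{agent}{ifelse(.value=='sd','_sd','')}")
  kap <- per_seed |>
    dplyr::distinct(.data$condition, .data$seed, .data$kappa) |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(kappa = mean(.data$kappa), kappa_sd = stats::sd(.data$kappa),
                     .groups = "drop")
  out <- dplyr::left_join(ari_wide, kap, by = "condition")
  ari_cols <- sort(grep("^ari_agent[0-9]+$", names(out), value = TRUE))
  sd_cols <- sort(grep("^ari_agent[0-9]+_sd$", names(out), value = TRUE))
  out[, c("condition", as.vector(rbind(ari_cols, sd_cols)), "kappa", "kappa_sd")]
}

#' @export
print.rmhng_experiment <- function(x, ...) {
  cat("Naming-game experiment:",
      paste(names(x$traces), collapse = ", "), "\n")
  cat(sprintf("  %d seeds, %d objects, K = %d\n",
              length(unlist(x$config$seeds)),
              nrow(x$dataset$features[[1]]), x$hyper$K))
  print(x$summary)
  invisible(x)
}

write_experiment <- function(res, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(res$metrics, file.path(out, "metrics.csv"))
  readr::write_csv(res$summary, file.path(out, "summary.csv"))
  write_experiment_config(res$config, file.path(out, "config.yaml"))
  seeds <- as.integer(unlist(res$config$seeds))
  for (cname in names(res$traces)) {
    for (si in seq_along(res$traces[[cname]])) {
      write_trace_csv(res$traces[[cname]][[si]],
                      file.path(out, sprintf("trace_%s_seed%d.csv",
                                             cname, seeds[si])))
    }
  }
  invisible(out)
}

#' Serialize / restore a sign trace as a long CSV
#'
#' Columns `iteration, agent, object, sign` (1-based indices), plus a
#' `# K = <K> mode = <mode>` comment header so a directory of traces is
#' self-describing.
#'
#' @param trace a [sign_trace].
#' @param path CSV file path.
#' @export
write_trace_csv <- function(trace, path) {
  con <- file(path, "w")
  writeLines(sprintf("# K = %d mode = %s", trace$K, trace$mode), con)
  close(con)
  readr::write_csv(tidy(trace), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  K <- as.integer(sub("^# K = ([0-9]+).*$", "\\1", hdr))
  mode <- sub("^.* mode = (.*)$", "\\1", hdr)
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  I <- max(df$iteration); N <- max(df$agent); D <- max(df$object)
  signs <- array(0L, dim = c(I, N, D))
  signs[cbind(df$iteration, df$agent, df$object)] <- as.integer(df$sign)
  new_sign_trace(signs, K, 0L, 0L, integer(I), integer(I), mode = mode)
}

#' Agreement of every condition of a run against a reference run
#'
#' Computes [posterior_agreement()] (trailing-window sign-distribution overlap
#' after exact label alignment) of every trace in `run` against the seed-paired
#' trace of `reference`, and averages over seeds. `run` and `reference` may be
#' `rmhng_experiment` objects or directories written by [run_experiment()];
#' a reference experiment containing several conditions contributes its first.
#'
#' @param run experiment bundle or directory to score.
#' @param reference experiment bundle or directory providing the reference
#'   (typically the Gibbs topline).
#' @param window trailing window length.
#' @param reference_condition which condition of `reference` to use.
#' @return A tibble with one row per condition of `run`: `condition`,
#'   `agreement` (mean over seed pairs), `agreement_sd`.
#' @export
compare_to_reference <- function(run, reference, window = 10L,
                                 reference_condition = NULL) {
  rt <- as_trace_list(run)
  ref <- as_trace_list(reference)
  refname <- reference_condition %||% names(ref)[1]
  if (!refname %in% names(ref)) {
    stop("reference condition '", refname, "' not present")
  }
  ref_traces <- ref[[refname]]
  purrr::map_dfr(names(rt), function(cname) {
    ag <- purrr::map2_dbl(rt[[cname]], ref_traces, posterior_agreement,
                          window = window)
    tibble::tibble(condition = cname, agreement = mean(ag),
                   agreement_sd = stats::sd(ag))
  })
}

# Normalize an experiment bundle / directory / bare list into
# list[[condition]][[seed]] of sign_trace.
as_trace_list <- function(x) {
  if (inherits(x, "rmhng_experiment")) return(x$traces)
  if (is.character(x) && length(x) == 1L && dir.exists(x)) {
    files <- list.files(x, pattern = "^trace_.*_seed[0-9]+\\.csv$",
                        full.names = TRUE)
    if (!length(files)) stop("no trace files found under ", x)
    cond <- sub("^trace_(.*)_seed[0-9]+\\.csv$", "\\1", basename(files))
    seed <- as.integer(sub("^.*_seed([0-9]+)\\.csv$", "\\1", basename(files)))
    out <- list()
    for (cn in unique(cond)) {
      sel <- order(seed[cond == cn])
      out[[cn]] <- purrr::map(files[cond == cn][sel], read_trace_csv)
    }
    return(out)
  }
  if (is.list(x) && all(purrr::map_lgl(x, inherits, "sign_trace"))) {
    return(list(run = x))
  }
  if (inherits(x, "sign_trace")) return(list(run = list(x)))
  stop("cannot interpret `", deparse(substitute(x)), "` as traces")
}
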