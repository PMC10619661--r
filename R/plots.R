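#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot metric trajectories of an experiment
#'
#' One panel per metric (per-agent mean ARI and pairwise kappa), iteration on
#' the x axis, one line per condition averaged over seeds — the standard
#' convergence picture for a naming-game study.
#'
#' @param metrics the tidy metric table of [run_experiment()] (or an
#'   `rmhng_experiment`, whose `$metrics` is used).
#' @return A ggplot object.
#' @export
plot_metric_trajectories <- function(metrics) {
  if (inherits(metrics, "rmhng_experiment")) metrics <- metrics$metrics
  long <- metrics |>
    dplyr::group_by(.data$condition, .data$seed, .data$iteration) |>
    dplyr::summarise(ARI = mean(.data$ari), kappa = mean(.data$kappa),
                     .groups = "drop") |>
    tidyr::pivot_longer(c("ARI", "kappa"), names_to = "metric") |>
    dplyr::group_by(.data$condition, .data$iteration, .data$metric) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(.data$iteration, .data$value,
                                     colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "iteration", y = NULL, colour = "condition") +
    ggplot2::theme_minimal()
}

#' @rdname plot_metric_trajectories
#' @param object an `rmhng_experiment`.
#' @param ... unused.
#' @export
autoplot.rmhng_experiment <- function(object, ...) {
  plot_metric_trajectories(object$metrics)
}

#' Per-iteration acceptance rate of a single trace
#'
#' @param object a [sign_trace].
#' @param ... unused.
#' @return A ggplot object (acceptance rate vs iteration).
#' @export
autoplot.sign_trace <- function(object, ...) {
  df <- tibble::tibble(
    iteration = seq_along(object$proposals_by_iter),
    acceptance_rate = ifelse(object$proposals_by_iter > 0,
                             object$acceptances_by_iter /
                               pmax(object$proposals_by_iter, 1L), NA_real_)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$acceptance_rate)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = "acceptance rate") +
    ggplot2::theme_minimal()
}

#' Plot agreement with the reference sampler per condition
#'
#' Bar chart of the output of [compare_to_reference()].
#'
#' @param agreement tibble with columns `condition` and `agreement`.
#' @return A ggplot object.
#' @export
plot_reference_agreement <- function(agreement) {
  ggplot2::ggplot(agreement,
                  ggplot2::aes(stats::reorder(.data$condition, -.data$agreement),
                               .data$agreement)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "sign-distribution agreement") +
    ggplot2::theme_minimal()
}
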