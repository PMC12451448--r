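#' @export
print.holosim_sim <- function(x, ...) {
  cat("<holosim_sim>\n")
  cat(sprintf("  scenario %s, X = %g, T_M = %g, %d replicate(s), T_H = %g\n",
              x$config$scenario, x$config$X, x$config$T_M,
              max(x$metrics$replicate), x$config$T_H))
  cat(sprintf("  final-generation means: host fitness %.3f, ",
              mean(x$metrics$mean_host_fitness[
                x$metrics$host_generation == x$config$T_H])))
  cat(sprintf("microbe fitness %.3f, alpha %.3f\n",
              mean(x$metrics$mean_microbe_fitness[
                x$metrics$host_generation == x$config$T_H]),
              mean(x$metrics$mean_alpha[
                x$metrics$host_generation == x$config$T_H])))
  invisible(x)
}

#' Tidy a simulation result
#'
#' Returns the per-generation metrics tibble: one row per
#' (replicate, host generation) with host fitness, within-host microbial
#' fitness, scaled Shannon alpha diversity, the environmental value used for
#' host selection, and the across-host pooled taxon richness.
#'
#' @param x A `holosim_sim` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.holosim_sim <- function(x, ...) {
  x$metrics
}

#' Summarize a simulation result
#'
#' One row per simulation: final-generation means (across replicates) of
#' host fitness, microbial fitness and alpha diversity, together with the
#' identifying parameters.
#'
#' @param x A `holosim_sim` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.holosim_sim <- function(x, ...) {
  fin <- dplyr::filter(x$metrics, .data$host_generation == x$config$T_H)
  tibble::tibble(
    scenario = x$config$scenario,
    X = x$config$X,
    T_M = x$config$T_M,
    replicates = dplyr::n_distinct(x$metrics$replicate),
    T_H = x$config$T_H,
    burn_in = x$config$burn_in,
    final_host_fitness = mean(fin$mean_host_fitness),
    final_microbe_fitness = mean(fin$mean_microbe_fitness),
    final_alpha = mean(fin$mean_alpha)
  )
}

#' Plot simulation trajectories
#'
#' Host fitness, within-host microbial fitness and alpha diversity over host
#' generations, one faint line per replicate plus the across-replicate mean;
#' the burn-in period is shaded.
#'
#' @param object A `holosim_sim` object.
#' @param metrics Which metrics to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.holosim_sim <- function(object,
                                 metrics = c("mean_host_fitness",
                                             "mean_microbe_fitness",
                                             "mean_alpha"),
                                 ...) {
  plot_trajectories(object$metrics, metrics = metrics,
                    burn_in = object$config$burn_in)
}

#' @export
plot.holosim_sim <- function(x, ...) print(autoplot(x, ...))

#' Trajectory plot for a tidy metrics table
#'
#' @param data A metrics tibble (e.g. from [run_replicate()], [tidy()] or
#'   [read_metrics()]).
#' @param metrics Metric columns to facet over.
#' @param burn_in Burn-in length to shade (0 for none).
#' @return A ggplot object.
#' @export
plot_trajectories <- function(data,
                              metrics = c("mean_host_fitness",
                                          "mean_microbe_fitness",
                                          "mean_alpha"),
                              burn_in = 0) {
  long <- data |>
    tidyr::pivot_longer(dplyr::all_of(metrics),
                        names_to = "metric", values_to = "value")
  mean_line <- long |>
    dplyr::group_by(.data$host_generation, .data$metric) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$host_generation, .data$value))
  if (burn_in > 0) {
    p <- p + ggplot2::annotate("rect", xmin = -Inf, xmax = burn_in,
                               ymin = -Inf, ymax = Inf, alpha = 0.08)
  }
  p +
    ggplot2::geom_line(ggplot2::aes(group = .data$replicate),
                       alpha = 0.3, linewidth = 0.3) +
    ggplot2::geom_line(data = mean_line, linewidth = 0.8, colour = "#2166ac") +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "host generation", y = NULL) +
    ggplot2::theme_minimal()
}

#' Final-state sweep plot
#'
#' Final-generation metric against vertical inheritance `X`, coloured by
#' `T_M`, for combined grid output.
#'
#' @param data Combined metrics tibble from [run_grid()].
#' @param metric Metric column to summarise.
#' @return A ggplot object.
#' @export
plot_final_sweep <- function(data, metric = "mean_host_fitness") {
  fin <- data |>
    dplyr::group_by(.data$scenario, .data$X, .data$T_M, .data$replicate) |>
    dplyr::filter(.data$host_generation == max(.data$host_generation)) |>
    dplyr::group_by(.data$scenario, .data$X, .data$T_M) |>
    dplyr::summarise(value = mean(.data[[metric]]), .groups = "drop")
  ggplot2::ggplot(fin, ggplot2::aes(.data$X, .data$value,
                                    colour = factor(.data$T_M))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::labs(x = "vertical inheritance (X)", y = metric,
                  colour = "T_M") +
    ggplot2::theme_minimal()
}
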