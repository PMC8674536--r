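#' Plot a specificity correlation spectrum or time course
#'
#' Observed split-half correlation per bin with FDR-significant bins marked.
#'
#' @param object A `correlation_result` from [correlation_spectrum()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.correlation_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin,
                                       y = .data$observed_r)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        color = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(color = .data$significant)) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "firebrick",
                                           `FALSE` = "grey40"),
                                name = "FDR significant") +
    ggplot2::labs(x = "bin", y = "split-half correlation r") +
    ggplot2::theme_minimal()
}

#' Plot trial-averaged power spectra per site
#'
#' @param object A `power_spectrum`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.power_spectrum <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::group_by(.data$site, .data$freq) |>
    dplyr::summarise(power = mean(.data$power), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq, y = .data$power,
                                   color = factor(.data$site))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)",
                  y = if (isTRUE(object$normalized))
                    "power (stimulation / baseline)" else "power (a.u.)",
                  color = "site") +
    ggplot2::theme_minimal()
}

#' Plot the permutation null against the observed specificity correlation
#'
#' @param object A `specificity_result` from [specificity_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.specificity_result <- function(object, ...) {
  null <- attr(object, "null")
  ggplot2::ggplot(tibble::tibble(null = null),
                  ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed_r,
                        color = "firebrick", linewidth = 1) +
    ggplot2::labs(x = "split-half correlation r",
                  y = "permutation count",
                  title = sprintf("observed r = %.3f, p = %.3g",
                                  object$observed_r, object$p)) +
    ggplot2::theme_minimal()
}

#' Plot repetition trajectories of a response feature
#'
#' Mean response per repetition with a +-2 bootstrap-SEM ribbon.
#'
#' @param data Tibble with `session_id`, `repetition`, `value` (and
#'   optionally `stimulus_id`, `animal_id`).
#' @param n_boot Bootstrap resamples for the SEM ribbon.
#' @param seed Integer seed for the bootstrap.
#' @return A ggplot object.
#' @export
plot_trajectory <- function(data, n_boot = 1000, seed = NULL) {
  if (!"animal_id" %in% names(data)) data$animal_id <- "animal1"
  if (!"stimulus_id" %in% names(data)) data$stimulus_id <- "stim"
  summ <- data |>
    dplyr::group_by(.data$repetition) |>
    dplyr::group_modify(function(d, key) {
      bs <- bootstrap_sem(dplyr::rename(d, value = "value"), n_boot = n_boot,
                          seed = seed)
      tibble::tibble(mean = bs$mean, sem = bs$sem)
    }) |>
    dplyr::ungroup()
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$repetition, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - 2 * .data$sem,
                                      ymax = .data$mean + 2 * .data$sem),
                         fill = "grey80") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "repetition", y = "response") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
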