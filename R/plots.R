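#' Plot an ensemble summary
#'
#' One panel per enzyme: the ensemble-mean activity trend with the 95%
#' envelope ribbon, optionally overlaying the individual member
#' trajectories in grey.
#'
#' @param object An [summarize_ensemble()] result.
#' @param members Optional selected `gma_ensemble` whose member
#'   trajectories are drawn in grey.
#' @param truth Optional [activity_schedule()] overlaid as a dashed line
#'   (synthetic ground truth).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ensemble_summary <- function(object, members = NULL, truth = NULL,
                                      ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time))
  if (!is.null(members)) {
    md <- dplyr::bind_rows(lapply(seq_along(members$candidates), function(i) {
      d <- tidy(members$candidates[[i]]$schedule)
      d$member <- i
      d
    }))
    p <- p + ggplot2::geom_line(
      data = md,
      ggplot2::aes(y = .data$fold, group = .data$member),
      colour = "grey70", linewidth = 0.2, alpha = 0.5)
  }
  p <- p +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), colour = "red")
  if (!is.null(truth)) {
    p <- p + ggplot2::geom_line(
      data = tidy(truth), ggplot2::aes(y = .data$fold),
      linetype = "dashed", colour = "black")
  }
  p +
    ggplot2::facet_wrap(~enzyme, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = "activity fold change")
}

#' Plot a simulated time course
#'
#' @param object A `gma_timecourse`.
#' @param species Optional subset of species.
#' @param fold Plot fold changes (default) or absolute values.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gma_timecourse <- function(object, species = NULL, fold = TRUE,
                                    ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(species)) df <- df[df$species %in% species, ]
  y <- if (fold) "fold" else "value"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data[[y]],
                                   colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)",
                  y = if (fold) "fold change" else "concentration")
}

#' Plot smoothed targets against the raw observations
#'
#' @param object A [smooth_targets()] result.
#' @param observations Optional observation set drawn as points.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.smoothed_targets <- function(object, observations = NULL, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$time, y = .data$fold)) +
    ggplot2::geom_line(colour = "steelblue")
  if (!is.null(observations)) {
    p <- p + ggplot2::geom_point(
      data = observations,
      ggplot2::aes(x = .data$time_min, y = .data$fold_change),
      shape = 1)
  }
  p + ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = "fold change")
}
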