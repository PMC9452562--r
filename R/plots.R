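#' Waterfall plot of per-model best responses
#'
#' Bars of the best (or day-35) percent volume change per model, sorted
#' decreasing, with dashed lines at the +20% and -30% band boundaries.
#'
#' @param calls Response calls from [model_response_calls()] or
#'   [response_calls()].
#' @param value Which column to plot (default `best_pct_change`).
#' @return A ggplot object.
#' @export
plot_waterfall <- function(calls, value = "best_pct_change") {
  stopifnot(value %in% names(calls))
  d <- calls %>%
    dplyr::filter(is.finite(.data[[value]])) %>%
    dplyr::arrange(dplyr::desc(.data[[value]])) %>%
    dplyr::mutate(.rank = factor(dplyr::row_number()))
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$.rank, y = .data[[value]],
    fill = .data$mrecist
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(20, -30), linetype = "dashed") +
    ggplot2::labs(
      x = "model (sorted)", y = "% tumor volume change",
      fill = "mRECIST"
    ) +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Spaghetti plot of relative tumor volume over time
#'
#' One line per tumor with the RTV band boundaries (0.7 and 1.2) as dashed
#' lines.
#'
#' @param rtv Output of [relative_tumor_volume()].
#' @return A ggplot object.
#' @export
plot_spaghetti <- function(rtv) {
  stopifnot(all(c("day", "rtv") %in% names(rtv)))
  ggplot2::ggplot(rtv, ggplot2::aes(
    x = .data$day, y = .data$rtv,
    group = interaction(.data$model_id, .data$animal_id, .data$arm),
    color = .data$model_id
  )) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = c(0.7, 1.2), linetype = "dashed") +
    ggplot2::labs(x = "day", y = "relative tumor volume") +
    ggplot2::theme_classic()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a ROC curve with its optimal cutoff
#'
#' @param object A [roc_optimal_cutoff()] result.
#' @param ... Unused.
#' @return A ggplot object showing the ROC curve, the chance diagonal and
#'   the Youden-optimal operating point.
#' @export
autoplot.roc_cutoff <- function(object, ...) {
  pts <- object$roc$points
  best <- tibble::tibble(
    fpr = 1 - object$specificity,
    tpr = object$sensitivity
  )
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = best, color = "red", size = 2) +
    ggplot2::labs(
      x = "1 - specificity", y = "sensitivity",
      title = sprintf(
        "AUC %.3f; cutoff %.3g", object$auc, object$threshold
      )
    ) +
    ggplot2::theme_classic()
}

#' Plot a 4PL dose-response fit
#'
#' @param object An [ic50_fit] object.
#' @param ... Unused.
#' @return A ggplot object with the observed growth percentages, the fitted
#'   curve and, when reached, the IC50 marked.
#' @export
autoplot.ic50_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble::tibble(
    log_dose = seq(min(d$log_dose), max(d$log_dose), length.out = 200)
  )
  grid$growth_pct <- stats::predict(object$fit, newdata = grid)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$log_dose, y = .data$growth_pct)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid) +
    ggplot2::geom_hline(yintercept = 50, linetype = "dashed") +
    ggplot2::labs(x = "log10 dose", y = "% of control growth") +
    ggplot2::theme_classic()
  if (!object$not_reached) {
    p <- p + ggplot2::geom_vline(
      xintercept = log10(object$ic50), linetype = "dotted", color = "red"
    )
  }
  p
}
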