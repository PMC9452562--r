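#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a logistic fit
#'
#' @param x A [logistic_fit] object.
#' @param exponentiate Return odds ratios instead of log-odds coefficients
#'   (confidence bounds are transformed alongside). Default `FALSE`.
#' @param ... Unused.
#' @return A tibble with one row per model term.
#' @export
tidy.logistic_fit <- function(x, exponentiate = FALSE, ...) {
  out <- x$terms
  if (exponentiate) {
    out <- out %>%
      dplyr::mutate(
        estimate = exp(.data$estimate),
        conf_low = exp(.data$conf_low),
        conf_high = exp(.data$conf_high)
      )
  }
  out
}

#' @rdname tidy.logistic_fit
#' @export
glance.logistic_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    converged = x$converged,
    separation = x$separation,
    deviance = x$deviance,
    null_deviance = x$null_deviance
  )
}

#' Tidy a cohort response summary
#'
#' @param x A [cohort_summary] object.
#' @param ... Unused.
#' @return `tidy()`: per-class counts with percentages. `glance()`: one row
#'   with pRR/pCB (exact and rounded), the mean best percent change and its
#'   bootstrap SE.
#' @export
tidy.cohort_summary <- function(x, ...) {
  x$counts %>%
    dplyr::mutate(pct = 100 * .data$n / x$n_evaluable)
}

#' @rdname tidy.cohort_summary
#' @export
glance.cohort_summary <- function(x, ...) {
  tibble::tibble(
    n_evaluable = x$n_evaluable,
    prr = x$prr,
    pcb = x$pcb,
    prr_rounded = x$prr_rounded,
    pcb_rounded = x$pcb_rounded,
    mean_change = x$mean_change,
    se_change = x$se_change
  )
}

#' Tidy a concordance report
#'
#' @param x A [concordance] report.
#' @param ... Unused.
#' @return `tidy()`: one row per metric with its value. `glance()`: one row
#'   with the 2x2 counts and all metrics.
#' @export
tidy.concordance_report <- function(x, ...) {
  tibble::tibble(
    metric = c("sensitivity", "specificity", "accuracy", "ppv", "npv"),
    value = c(x$sensitivity, x$specificity, x$accuracy, x$ppv, x$npv)
  )
}

#' @rdname tidy.concordance_report
#' @export
glance.concordance_report <- function(x, ...) {
  dplyr::bind_cols(
    x$table,
    tibble::tibble(
      n = x$n,
      sensitivity = x$sensitivity,
      specificity = x$specificity,
      accuracy = x$accuracy,
      ppv = x$ppv,
      npv = x$npv
    )
  )
}

#' Tidy an IC50 fit
#'
#' @param x An [ic50_fit] object.
#' @param ... Unused.
#' @return `glance()`: one row with the IC50, the not-reached flag and the
#'   fitted 4PL parameters.
#' @export
glance.ic50_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(ic50 = x$ic50, not_reached = x$not_reached),
    x$parameters
  )
}

#' Tidy the exposure-association model pair
#'
#' @param x An [association_models] object.
#' @param exponentiate Report odds ratios (default `FALSE`).
#' @param ... Unused.
#' @return A tibble stacking the terms of both fits with a `model` column
#'   (`"M1"` interaction model, `"M2"` double-hit indicator model).
#' @export
tidy.association_models <- function(x, exponentiate = FALSE, ...) {
  dplyr::bind_rows(
    tidy(x$m1, exponentiate = exponentiate) %>% dplyr::mutate(model = "M1"),
    tidy(x$m2, exponentiate = exponentiate) %>% dplyr::mutate(model = "M2")
  ) %>%
    dplyr::relocate("model")
}

#' @rdname tidy.association_models
#' @export
glance.association_models <- function(x, ...) {
  dplyr::bind_rows(
    glance(x$m1) %>% dplyr::mutate(model = "M1"),
    glance(x$m2) %>% dplyr::mutate(model = "M2")
  ) %>%
    dplyr::relocate("model")
}
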