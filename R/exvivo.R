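#' Relative spheroid area per treatment condition
#'
#' Normalizes mean spheroid area per model and condition to the untreated
#' (vehicle) control: the relative area is 100 x mean(treated) /
#' mean(vehicle), and the change is relative area minus 100. Replicate areas
#' are aggregated by the mean by default, with the median as an option.
#'
#' @param readouts Long tibble with columns `model_id`, `condition`, `area`
#'   (one row per replicate spheroid).
#' @param vehicle Condition label of the untreated control (default
#'   `"vehicle"`).
#' @param aggregate `"mean"` (default) or `"median"` replicate aggregation.
#' @return A tibble per model and condition: `relative_area_pct`,
#'   `change_pct` (vehicle rows included at 100 / 0).
#' @export
relative_spheroid_area <- function(readouts, vehicle = "vehicle",
                                   aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  stopifnot(all(c("model_id", "condition", "area") %in% names(readouts)))
  if (any(readouts$area <= 0, na.rm = TRUE)) {
    stop("spheroid areas must be positive", call. = FALSE)
  }
  agg <- if (aggregate == "mean") mean else stats::median
  summ <- readouts %>%
    dplyr::group_by(.data$model_id, .data$condition) %>%
    dplyr::summarise(mean_area = agg(.data$area), .groups = "drop")
  veh <- summ %>%
    dplyr::filter(.data$condition == vehicle) %>%
    dplyr::select("model_id", vehicle_area = "mean_area")
  if (!all(unique(summ$model_id) %in% veh$model_id)) {
    stop("every model needs a '", vehicle, "' condition for normalization",
      call. = FALSE
    )
  }
  summ %>%
    dplyr::left_join(veh, by = "model_id") %>%
    dplyr::mutate(
      relative_area_pct = 100 * .data$mean_area / .data$vehicle_area,
      change_pct = .data$relative_area_pct - 100
    ) %>%
    dplyr::select("model_id", "condition", "relative_area_pct", "change_pct")
}

#' EdU-positive fraction and vehicle-relative proliferation
#'
#' `edu_fraction()` converts EdU-positive and total nuclei counts into the
#' percentage of S-phase cells; `relative_edu()` expresses a treated
#' percentage relative to the vehicle mean (100 = no antiproliferative
#' effect).
#'
#' @param edu_positive,total_nuclei Non-negative counts with
#'   `edu_positive <= total_nuclei` and `total_nuclei > 0`.
#' @return Percentage(s) of EdU-positive cells.
#' @examples
#' edu_fraction(50, 200) # 25
#' @export
edu_fraction <- function(edu_positive, total_nuclei) {
  bad <- total_nuclei <= 0 | edu_positive < 0 | edu_positive > total_nuclei
  if (any(bad, na.rm = TRUE)) {
    stop("need 0 <= edu_positive <= total_nuclei and total_nuclei > 0",
      call. = FALSE
    )
  }
  100 * edu_positive / total_nuclei
}

#' @rdname edu_fraction
#' @param treated_pct EdU percentage(s) under treatment.
#' @param vehicle_pct EdU percentage(s) in matched vehicle wells.
#' @export
relative_edu <- function(treated_pct, vehicle_pct) {
  vm <- mean(vehicle_pct, na.rm = TRUE)
  if (!is.finite(vm) || vm <= 0) {
    stop("vehicle EdU mean must be positive", call. = FALSE)
  }
  100 * treated_pct / vm
}

#' Classify ex vivo response from the spheroid-area change
#'
#' A culture is called sensitive when its percent change in spheroid area is
#' at or below the cutoff (default -25%, i.e. at least a 25% reduction
#' relative to vehicle); the boundary is inclusive.
#'
#' @param change_pct Percent change in spheroid area vs vehicle.
#' @param cutoff Response cutoff (default -25).
#' @return Character vector `"sensitive"`/`"resistant"`.
#' @examples
#' classify_exvivo_response(c(-30, -25, 5))
#' @export
classify_exvivo_response <- function(change_pct, cutoff = -25) {
  if (any(!is.finite(change_pct) & !is.na(change_pct))) {
    stop("change_pct must be finite", call. = FALSE)
  }
  ifelse(change_pct <= cutoff, "sensitive", "resistant")
}

#' ROC analysis of the ex vivo area change with optimal cutoff
#'
#' Builds the full ROC curve of the spheroid-area change for discriminating
#' sensitive from resistant models, computes the trapezoidal AUC, and picks
#' the Youden-optimal cutoff in the low-is-positive direction (sensitive
#' models show the greater area reduction, i.e. the more negative change).
#'
#' @param changes Percent area changes, one per model.
#' @param labels Binary truth labels; positive class = `"sensitive"` unless
#'   overridden.
#' @param positive Positive class label (default `"sensitive"` for character
#'   labels).
#' @return An object of class `roc_cutoff`: `roc` (a [roc_points()] result
#'   computed on the negated changes so that higher = more positive), `auc`,
#'   `threshold` (on the original change scale), `sensitivity`,
#'   `specificity`, `j`.
#' @export
roc_optimal_cutoff <- function(changes, labels, positive = NULL) {
  if (is.null(positive) && !is.logical(labels) && !is.numeric(labels)) {
    lev <- unique(as.character(labels))
    positive <- if ("sensitive" %in% lev) "sensitive" else NULL
  }
  roc <- roc_points(-changes, labels, positive = positive)
  best <- youden_cutoff(changes, labels,
    direction = "low_is_positive", positive = positive
  )
  structure(
    list(
      roc = roc,
      auc = roc$auc,
      threshold = best$threshold,
      sensitivity = best$sensitivity,
      specificity = best$specificity,
      j = best$j
    ),
    class = "roc_cutoff"
  )
}

#' @export
print.roc_cutoff <- function(x, ...) {
  cat(sprintf(
    "ROC AUC %.3f; optimal cutoff %.3g (sensitivity %.3f, specificity %.3f)\n",
    x$auc, x$threshold, x$sensitivity, x$specificity
  ))
  invisible(x)
}

#' Normalize a proliferation dose plate
#'
#' Day-6 readouts are first normalized to their matched day-0 readouts
#' (growth over the assay window), then expressed as a percentage of the
#' vehicle (dose 0) growth — the normalization order used for crystal-violet
#' proliferation assays.
#'
#' @param plate Long tibble with columns `dose` (0 for vehicle), `day`
#'   (0 or the endpoint day), `replicate`, `value`.
#' @return A tibble per dose and replicate with `growth` (day-end/day-0) and
#'   `growth_pct` (percent of mean vehicle growth).
#' @export
normalize_plate <- function(plate) {
  stopifnot(all(c("dose", "day", "replicate", "value") %in% names(plate)))
  days <- sort(unique(plate$day))
  if (length(days) != 2L || days[1] != 0) {
    stop("plate must contain day 0 and one endpoint day", call. = FALSE)
  }
  wide <- plate %>%
    dplyr::mutate(day = ifelse(.data$day == 0, "d0", "dend")) %>%
    tidyr::pivot_wider(names_from = "day", values_from = "value") %>%
    dplyr::mutate(growth = .data$dend / .data$d0)
  veh <- wide %>% dplyr::filter(.data$dose == 0)
  if (nrow(veh) == 0L) stop("plate must contain vehicle (dose 0) wells", call. = FALSE)
  v0 <- mean(veh$growth)
  wide %>%
    dplyr::mutate(growth_pct = 100 * .data$growth / v0) %>%
    dplyr::select("dose", "replicate", "growth", "growth_pct")
}

#' Fit a four-parameter logistic dose-response curve and extract the IC50
#'
#' Fits \eqn{y = lower + (upper - lower) / (1 + (x / e)^{h})} by
#' Levenberg-Marquardt least squares on the percent-of-control scale, with
#' starting values taken from the data quantiles and the hill slope left
#' free in sign. The IC50 is the concentration at which the fitted curve
#' crosses 50% of control growth; when the fitted curve never reaches 50%
#' within the dose range the fit is returned with `ic50 = NA` and
#' `not_reached = TRUE` rather than an extrapolated value.
#'
#' @param plate Either a normalized tibble with columns `dose` and
#'   `growth_pct` (vehicle rows at dose 0 are used only through the
#'   normalization) or a raw plate accepted by [normalize_plate()].
#' @return An object of class `ic50_fit`: `ic50`, `not_reached`,
#'   `parameters` (lower, upper, inflection, hill), `data` and the `nls`
#'   fit object. [glance()] is provided, and [fold_change()] compares two
#'   IC50s.
#' @export
fit_ic50 <- function(plate) {
  if (all(c("day", "value") %in% names(plate))) plate <- normalize_plate(plate)
  stopifnot(all(c("dose", "growth_pct") %in% names(plate)))
  d <- plate %>% dplyr::filter(.data$dose > 0, is.finite(.data$growth_pct))
  if (dplyr::n_distinct(d$dose) < 4L) {
    stop("need at least 4 distinct positive doses for a 4PL fit", call. = FALSE)
  }
  d <- d %>% dplyr::mutate(log_dose = log10(.data$dose))
  # a start value that is numerically ~0 but not exactly 0 defeats the
  # relative-step numeric gradient, so snap tiny starts to zero
  zap <- function(x) if (abs(x) < 1e-8) 0 else x
  start <- list(
    lower = zap(stats::quantile(d$growth_pct, 0.05, names = FALSE)),
    upper = zap(stats::quantile(d$growth_pct, 0.95, names = FALSE)),
    log_e = zap(stats::median(d$log_dose)),
    hill = 1
  )
  try_fit <- function(st) {
    tryCatch(
      minpack.lm::nlsLM(
        growth_pct ~ lower + (upper - lower) / (1 + 10^((log_dose - log_e) * hill)),
        data = d,
        start = st,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
  }
  # deterministic cascade of start perturbations: the LM solver can land on
  # a rank-deficient point from some starts (e.g. exactly centered log_e on
  # noiseless data), and rising curves need the opposite hill sign
  starts <- list(
    start,
    utils::modifyList(start, list(log_e = start$log_e + 0.3)),
    utils::modifyList(start, list(log_e = start$log_e - 0.3, hill = 1.5)),
    utils::modifyList(start, list(hill = -1)),
    utils::modifyList(start, list(
      lower = min(d$growth_pct), upper = max(d$growth_pct),
      log_e = start$log_e + 0.1, hill = -1.5
    ))
  )
  fit <- NULL
  for (st in starts) {
    fit <- try_fit(st)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    # degenerate (e.g. flat) data: no usable sigmoid. If the observations
    # never span the 50% level this is an honest not-reached result.
    if (all(d$growth_pct > 50) || all(d$growth_pct < 50)) {
      return(structure(
        list(
          ic50 = NA_real_,
          not_reached = TRUE,
          parameters = tibble::tibble(
            lower = NA_real_, upper = NA_real_,
            inflection = NA_real_, hill = NA_real_
          ),
          data = d,
          fit = NULL
        ),
        class = "ic50_fit"
      ))
    }
    stop("4PL fit failed to converge for this plate", call. = FALSE)
  }
  cf <- as.list(stats::coef(fit))
  # dose at absolute 50% of control: solve lower + (upper-lower)/(1+r) = 50
  ic50 <- NA_real_
  not_reached <- TRUE
  lo <- min(cf$lower, cf$upper)
  hi <- max(cf$lower, cf$upper)
  if (lo < 50 && hi > 50) {
    r <- (cf$upper - 50) / (50 - cf$lower) # (x/e)^hill at the crossing
    if (is.finite(r) && r > 0) {
      log_x <- cf$log_e + log10(r) / cf$hill
      x <- 10^log_x
      if (x >= min(d$dose) && x <= max(d$dose)) {
        ic50 <- x
        not_reached <- FALSE
      }
    }
  }
  structure(
    list(
      ic50 = ic50,
      not_reached = not_reached,
      parameters = tibble::tibble(
        lower = cf$lower, upper = cf$upper,
        inflection = 10^cf$log_e, hill = cf$hill
      ),
      data = d,
      fit = fit
    ),
    class = "ic50_fit"
  )
}

#' @export
print.ic50_fit <- function(x, ...) {
  if (x$not_reached) {
    cat("4PL fit: 50% of control not reached within the dose range\n")
  } else {
    cat(sprintf("4PL fit: IC50 = %.4g\n", x$ic50))
  }
  invisible(x)
}

#' @rdname fit_ic50
#' @param ic50_test,ic50_reference IC50 values (numbers or `ic50_fit`
#'   objects) to compare.
#' @export
fold_change <- function(ic50_test, ic50_reference) {
  get_ic50 <- function(x) if (inherits(x, "ic50_fit")) x$ic50 else x
  a <- get_ic50(ic50_test)
  b <- get_ic50(ic50_reference)
  if (!is.finite(a) || !is.finite(b) || b <= 0) {
    stop("fold change needs two finite positive IC50 values", call. = FALSE)
  }
  a / b
}
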