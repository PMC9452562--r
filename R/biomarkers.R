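#' Allred score from percent positivity and staining intensity
#'
#' The Allred score (0-8) is the sum of a proportion score binned from the
#' percentage of positive cells (0%, <1%, 1-10%, 11-33%, 34-66%, >66% map to
#' 0-5) and the staining intensity (0-3).
#'
#' @param positive_pct Percentage of positive cells in \[0, 100\].
#' @param intensity Staining intensity, integer 0-3.
#' @return Integer Allred score 0-8, vectorized.
#' @examples
#' allred_score(20, 2) # proportion bin 3 + intensity 2 = 5
#' @export
allred_score <- function(positive_pct, intensity) {
  if (any(positive_pct < 0 | positive_pct > 100, na.rm = TRUE)) {
    stop("positive_pct must lie in [0, 100]", call. = FALSE)
  }
  if (any(!intensity %in% 0:3 & !is.na(intensity))) {
    stop("intensity must be an integer in 0-3", call. = FALSE)
  }
  prop <- ifelse(positive_pct == 0, 0L,
    ifelse(positive_pct < 1, 1L,
      ifelse(positive_pct <= 10, 2L,
        ifelse(positive_pct <= 33, 3L,
          ifelse(positive_pct <= 66, 4L, 5L)
        )
      )
    )
  )
  as.integer(prop + intensity)
}

#' Default composite-biomarker cutoffs
#'
#' The Youden-optimized cutoffs of the composite resistance rule: p16 high at
#' semiquantitative score >= 2, pRb low at <= 2, cyclin E1 high at Allred
#' > 4 and cyclin D1 high at Allred > 6.
#'
#' @return A named list with `p16_high_ge`, `prb_low_le`, `e1_high_gt`,
#'   `d1_high_gt`.
#' @export
default_cutoffs <- function() {
  list(p16_high_ge = 2, prb_low_le = 2, e1_high_gt = 4, d1_high_gt = 6)
}

#' Composite p16/pRb/cyclin resistance classifier
#'
#' Applies the decision flow that predicts CDK4/6-inhibitor resistance from
#' an IHC panel: a Basal-like intrinsic subtype is called resistant first;
#' otherwise high p16, then low pRb, then high cyclin E1 or cyclin D1 each
#' call resistance; a panel in which no rule fires is predicted sensitive.
#' The rule order only affects which rule is recorded as having fired, not
#' the binary call. A missing score simply cannot fire its rule; a panel
#' with all four scores missing is an error.
#'
#' @param panel A tibble with columns `sample_id`, `p16` (0-4), `prb` (0-4),
#'   `cyclin_e1` (Allred 0-8), `cyclin_d1` (Allred 0-8) and optionally
#'   `subtype` (PAM50 label; `"Basal"` triggers the subtype rule).
#' @param cutoffs A cutoff list as from [default_cutoffs()].
#' @return The panel with `predicted` (`"resistant"`/`"sensitive"`) and
#'   `fired_rule` (`basal_subtype`, `p16_high`, `prb_low`, `cyclin_high`, or
#'   `none`) columns appended.
#' @export
classify_composite <- function(panel, cutoffs = default_cutoffs()) {
  stopifnot(is.data.frame(panel))
  need <- c("p16", "prb", "cyclin_e1", "cyclin_d1")
  missing <- setdiff(need, names(panel))
  if (length(missing)) {
    stop("panel is missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  check_score_range(panel$p16, 0, 4, "p16")
  check_score_range(panel$prb, 0, 4, "prb")
  check_score_range(panel$cyclin_e1, 0, 8, "cyclin_e1")
  check_score_range(panel$cyclin_d1, 0, 8, "cyclin_d1")
  all_missing <- is.na(panel$p16) & is.na(panel$prb) &
    is.na(panel$cyclin_e1) & is.na(panel$cyclin_d1)
  if (any(all_missing)) {
    stop("unclassifiable panel(s): all four scores missing", call. = FALSE)
  }
  subtype <- if ("subtype" %in% names(panel)) as.character(panel$subtype) else
    rep(NA_character_, nrow(panel))
  basal <- !is.na(subtype) & subtype %in% c("Basal", "Basal-like")
  p16_hit <- !is.na(panel$p16) & panel$p16 >= cutoffs$p16_high_ge
  prb_hit <- !is.na(panel$prb) & panel$prb <= cutoffs$prb_low_le
  cyc_hit <- (!is.na(panel$cyclin_e1) & panel$cyclin_e1 > cutoffs$e1_high_gt) |
    (!is.na(panel$cyclin_d1) & panel$cyclin_d1 > cutoffs$d1_high_gt)
  fired <- dplyr::case_when(
    basal ~ "basal_subtype",
    p16_hit ~ "p16_high",
    prb_hit ~ "prb_low",
    cyc_hit ~ "cyclin_high",
    TRUE ~ "none"
  )
  panel %>%
    dplyr::mutate(
      predicted = ifelse(fired == "none", "sensitive", "resistant"),
      fired_rule = fired
    )
}

check_score_range <- function(x, lo, hi, name) {
  if (any(x < lo | x > hi, na.rm = TRUE)) {
    stop(name, " scores must lie in ", lo, "-", hi, call. = FALSE)
  }
}

#' Youden-index optimal cutoff
#'
#' Finds the threshold maximizing the Youden index
#' \eqn{J = \mathrm{sensitivity} + \mathrm{specificity} - 1} over all
#' achievable thresholds. With `direction = "high_is_positive"` a score at or
#' above the threshold is called positive; with `"low_is_positive"` a score
#' at or below it. Ties in J are broken in favor of the threshold with the
#' highest sensitivity, then the lowest threshold value (the screening-
#' oriented convention: prefer catching positives).
#'
#' @param scores Numeric or ordinal score values.
#' @param labels Binary labels (positive class `"resistant"` by default when
#'   labels are character; see [roc_points()]).
#' @param direction Whether high or low scores indicate the positive class.
#' @param positive Positive label value for character labels.
#' @return A one-row tibble: `threshold`, `j`, `sensitivity`, `specificity`.
#' @examples
#' youden_cutoff(c(1, 2, 3, 4), c("sensitive", "sensitive", "resistant", "resistant"))
#' @export
youden_cutoff <- function(scores, labels,
                          direction = c("high_is_positive", "low_is_positive"),
                          positive = NULL) {
  direction <- match.arg(direction)
  lab <- as_binary_labels(labels, positive)
  stopifnot(length(scores) == length(lab))
  keep <- is.finite(scores) & !is.na(lab)
  scores <- scores[keep]
  lab <- lab[keep]
  if (length(unique(lab)) < 2L) {
    stop("both classes must be present to optimize a cutoff", call. = FALSE)
  }
  s <- if (direction == "high_is_positive") scores else -scores
  np <- sum(lab == 1)
  nn <- sum(lab == 0)
  cand <- sort(unique(s))
  sens <- vapply(cand, function(t) sum(s >= t & lab == 1) / np, numeric(1))
  spec <- vapply(cand, function(t) sum(s < t & lab == 0) / nn, numeric(1))
  j <- sens + spec - 1
  # tie rule: max J, then max sensitivity, then lowest threshold (on the
  # original score scale)
  thr_orig <- if (direction == "high_is_positive") cand else -cand
  ord <- order(-j, -sens, thr_orig)
  i <- ord[1]
  tibble::tibble(
    threshold = thr_orig[i],
    j = j[i],
    sensitivity = sens[i],
    specificity = spec[i]
  )
}

#' Concordance of predicted vs observed binary calls
#'
#' Builds the 2x2 confusion table with `"resistant"` (or the supplied
#' positive label) as the positive class and derives sensitivity,
#' specificity, accuracy, positive and negative predictive values from it.
#'
#' @param predicted,observed Equal-length binary label vectors.
#' @param positive Positive class label (default `"resistant"` for character
#'   labels).
#' @return An object of class `concordance_report`: `table` (tp, fp, fn, tn)
#'   and the five metrics as proportions. [tidy()] returns the metrics.
#' @export
concordance <- function(predicted, observed, positive = NULL) {
  if (length(predicted) != length(observed)) {
    stop("predicted and observed must have the same length", call. = FALSE)
  }
  p <- as_binary_labels(predicted, positive)
  o <- as_binary_labels(observed, positive)
  keep <- !is.na(p) & !is.na(o)
  p <- p[keep]
  o <- o[keep]
  tp <- sum(p == 1 & o == 1)
  fp <- sum(p == 1 & o == 0)
  fn <- sum(p == 0 & o == 1)
  tn <- sum(p == 0 & o == 0)
  n <- tp + fp + fn + tn
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  structure(
    list(
      table = tibble::tibble(tp = tp, fp = fp, fn = fn, tn = tn),
      sensitivity = safe_div(tp, tp + fn),
      specificity = safe_div(tn, tn + fp),
      accuracy = safe_div(tp + tn, n),
      ppv = safe_div(tp, tp + fp),
      npv = safe_div(tn, tn + fn),
      n = n
    ),
    class = "concordance_report"
  )
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Concordance over", x$n, "pairs (positive = resistant)\n")
  cat(sprintf(
    "  sensitivity %.3f  specificity %.3f  accuracy %.3f  PPV %.3f  NPV %.3f\n",
    x$sensitivity, x$specificity, x$accuracy, x$ppv, x$npv
  ))
  invisible(x)
}

#' KI67-based Luminal A/B split
#'
#' Luminal tumors are split by baseline proliferation: Luminal A if
#' KI67 < 15%, Luminal B if KI67 >= 15%.
#'
#' @param ki67_pct KI67 percentage in \[0, 100\].
#' @return Character vector `"LumA"`/`"LumB"`.
#' @export
ki67_luminal_split <- function(ki67_pct) {
  if (any(ki67_pct < 0 | ki67_pct > 100, na.rm = TRUE)) {
    stop("ki67_pct must lie in [0, 100]", call. = FALSE)
  }
  ifelse(ki67_pct < 15, "LumA", "LumB")
}

#' Antiproliferative KI67 response rule
#'
#' A tumor is called sensitive when the natural logarithm of its on-treatment
#' (day 15) KI67 percentage is below 1, i.e. KI67 below about 2.72%; this is
#' the standard antiproliferative-response endpoint of short presurgical
#' CDK4/6-inhibitor treatment. The log is taken on the percentage as printed
#' (not a fraction). Non-positive inputs, where the log is undefined, are
#' clamped to the smallest positive representable percentage and flagged with
#' a warning (a KI67 of 0 is an unambiguous responder).
#'
#' @param ki67_pct_day15 On-treatment KI67 percentage.
#' @return Character vector `"sensitive"`/`"resistant"`.
#' @export
ki67_response <- function(ki67_pct_day15) {
  if (any(ki67_pct_day15 < 0, na.rm = TRUE)) {
    stop("ki67_pct_day15 must be non-negative", call. = FALSE)
  }
  if (any(ki67_pct_day15 == 0, na.rm = TRUE)) {
    warning("KI67 of 0% clamped before taking the log; called sensitive")
    ki67_pct_day15 <- pmax(ki67_pct_day15, .Machine$double.xmin)
  }
  ifelse(log(ki67_pct_day15) < 1, "sensitive", "resistant")
}

#' Odds ratio per standard deviation of a continuous biomarker
#'
#' Univariate logistic regression of a binary response on the z-scored
#' biomarker (e.g. a continuous 0-300 H-score); the reported odds ratio is
#' the multiplicative change in odds per one-SD increase.
#'
#' @param data A data frame.
#' @param biomarker Column name (string or bare) of the continuous biomarker.
#' @param response Column name of the binary response.
#' @return A one-row tibble: `odds_ratio`, `conf_low`, `conf_high`,
#'   `p_value`, `n`, `separation`.
#' @export
or_per_sd <- function(data, biomarker, response) {
  biomarker <- rlang::as_name(rlang::ensym(biomarker))
  response <- rlang::as_name(rlang::ensym(response))
  d <- data[stats::complete.cases(data[, c(biomarker, response)]), ]
  if (nrow(d) < 10L) stop("need at least 10 complete observations", call. = FALSE)
  z <- as.numeric(scale(d[[biomarker]]))
  dd <- data.frame(.y = as_binary_labels(d[[response]]), .z = z)
  fit <- logistic_fit(dd, .y ~ .z)
  co <- fit$terms[fit$terms$term == ".z", ]
  tibble::tibble(
    odds_ratio = exp(co$estimate),
    conf_low = exp(co$conf_low),
    conf_high = exp(co$conf_high),
    p_value = co$p_value,
    n = fit$n,
    separation = fit$separation
  )
}
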