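#' Fit a logistic regression with Wald inference
#'
#' Maximum-likelihood logistic regression via iteratively reweighted least
#' squares (tolerance 1e-8, at most 100 iterations), with Wald standard
#' errors, z statistics, two-sided p-values and 95% confidence intervals per
#' term. Complete or quasi-complete separation is detected after fitting
#' (exploding coefficient magnitude or standard errors) and flagged; when
#' separation is detected the estimates are reported as `NA` rather than a
#' silently diverged value.
#'
#' @param data A data frame holding the outcome and predictors.
#' @param formula A model formula whose left-hand side is a binary outcome
#'   (logical, 0/1 numeric, or a two-level factor).
#' @return An object of class `logistic_fit`: a list with a `terms` tibble
#'   (`term`, `estimate`, `std_error`, `statistic`, `p_value`, `conf_low`,
#'   `conf_high`), `converged` and `separation` flags, `n`, and the model
#'   formula. [tidy()] and [glance()] methods are provided.
#' @examples
#' d <- data.frame(y = rep(c(0, 1), each = 20), x = rnorm(40))
#' fit <- logistic_fit(d, y ~ x)
#' tidy(fit)
#' @export
logistic_fit <- function(data, formula) {
  stopifnot(is.data.frame(data))
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1))) {
    stop("outcome must be binary (0/1, logical or two-level factor)", call. = FALSE)
  }
  if (length(unique(y)) < 2L) {
    stop("outcome is degenerate: both classes must be present", call. = FALSE)
  }
  x <- stats::model.matrix(attr(mf, "terms"), mf)
  if (nrow(x) <= ncol(x)) {
    stop("more model terms than observations", call. = FALSE)
  }

  fit <- suppressWarnings(stats::glm.fit(
    x, y,
    family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-8, maxit = 100)
  ))

  est <- fit$coefficients
  # Wald covariance from the final IRLS weights
  w <- fit$weights
  xtx <- crossprod(x * sqrt(w))
  covmat <- tryCatch(solve(xtx), error = function(e) NULL)
  cov_ok <- !is.null(covmat) && all(is.finite(covmat)) && all(diag(covmat) > 0)
  se <- if (cov_ok) sqrt(diag(covmat)) else rep(NA_real_, length(est))

  # separation: diverging coefficients or exploding SEs
  separation <- !fit$converged && fit$boundary ||
    any(abs(est[-1]) > 15, na.rm = TRUE) ||
    any(se > 100, na.rm = TRUE) ||
    !cov_ok
  if (length(est) == 1L) {
    separation <- isTRUE(any(abs(est) > 15)) || isTRUE(any(se > 100)) || !cov_ok
  }

  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  terms_tbl <- tibble::tibble(
    term = colnames(x),
    estimate = if (separation) NA_real_ else unname(est),
    std_error = if (separation) NA_real_ else unname(se),
    statistic = if (separation) NA_real_ else unname(z),
    p_value = if (separation) NA_real_ else unname(p),
    conf_low = if (separation) NA_real_ else unname(est - 1.96 * se),
    conf_high = if (separation) NA_real_ else unname(est + 1.96 * se)
  )

  structure(
    list(
      terms = terms_tbl,
      converged = fit$converged,
      separation = separation,
      n = nrow(x),
      deviance = fit$deviance,
      null_deviance = fit$null.deviance,
      formula = formula
    ),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic fit (Wald inference), n =", x$n, "\n")
  if (x$separation) cat("!! separation detected: estimates withheld\n")
  print(x$terms)
  invisible(x)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value from the conditional hypergeometric distribution (sum of
#' the probabilities of all tables, with the observed margins, no more likely
#' than the observed one) together with the sample cross-product odds ratio.
#' With a zero cell the odds ratio is undefined; `continuity = TRUE` adds 0.5
#' to every cell for the odds-ratio estimate only (the p-value is always
#' exact).
#'
#' @param table A 2x2 matrix of non-negative integer counts, rows = groups,
#'   columns = outcomes.
#' @param continuity Add 0.5 to each cell for the odds ratio when any cell is
#'   zero. Default `TRUE`.
#' @return A tibble with `odds_ratio` and `p_value`.
#' @examples
#' fisher_exact(matrix(c(5, 0, 0, 5), nrow = 2))
#' @export
fisher_exact <- function(table, continuity = TRUE) {
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)))
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  p <- stats::fisher.test(table)$p.value
  t2 <- table
  if (continuity && any(table == 0)) t2 <- table + 0.5
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  tibble::tibble(odds_ratio = or, p_value = min(p, 1))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values controlling the FDR; `NA`s are preserved.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' ROC curve points and area under the curve
#'
#' Computes the full ROC curve over every achievable threshold of a
#' continuous (or ordinal) score against binary labels, plus the trapezoidal
#' AUC. Ties in the score are handled by placing thresholds only at distinct
#' score values, so the AUC equals the Mann-Whitney rank statistic
#' \eqn{P(X_{pos} > X_{neg}) + 0.5 P(X_{pos} = X_{neg})}.
#'
#' @param scores Numeric scores; higher score means more "positive" by
#'   convention (flip the sign for the opposite direction).
#' @param labels Binary labels (logical, 0/1, or a vector matched against
#'   `positive`).
#' @param positive The label value counted as positive when `labels` is not
#'   already logical/0-1.
#' @return A list of class `roc_result` with `points` (a tibble with
#'   `threshold`, `fpr`, `tpr`) and `auc`.
#' @examples
#' roc_points(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc
#' @export
roc_points <- function(scores, labels, positive = NULL) {
  lab <- as_binary_labels(labels, positive)
  stopifnot(length(scores) == length(lab))
  keep <- is.finite(scores) & !is.na(lab)
  scores <- scores[keep]
  lab <- lab[keep]
  if (length(unique(lab)) < 2L) {
    stop("both classes must be present to compute a ROC curve", call. = FALSE)
  }
  np <- sum(lab == 1)
  nn <- sum(lab == 0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & lab == 1) / np, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & lab == 0) / nn, numeric(1))
  pts <- tibble::tibble(
    threshold = c(Inf, thr),
    fpr = c(0, fpr),
    tpr = c(0, tpr)
  )
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("ROC with", nrow(x$points), "points; AUC =", format(x$auc, digits = 4), "\n")
  invisible(x)
}

# Coerce assorted label encodings to 0/1 integers.
as_binary_labels <- function(labels, positive = NULL) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels) && all(labels %in% c(0, 1), na.rm = TRUE)) {
    return(as.integer(labels))
  }
  labels <- as.character(labels)
  lev <- sort(unique(stats::na.omit(labels)))
  if (is.null(positive)) {
    if (length(lev) > 2L) stop("labels must be binary", call. = FALSE)
    positive <- if ("resistant" %in% lev) "resistant" else lev[length(lev)]
  }
  as.integer(labels == positive)
}

# Half-away-from-zero rounding to integer (report parity with printed
# percentages; R's round() would round to even).
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}
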