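#' Ellipsoid tumor volume from caliper measurements
#'
#' Computes the standard ellipsoid approximation
#' \eqn{V = (L \times W^2) \times \pi / 6} used for subcutaneous implants,
#' where the smaller of the two caliper dimensions is squared. Arguments are
#' normalized so that passing the dimensions in either order gives the same
#' volume.
#'
#' @param length,width Caliper dimensions in mm; both must be positive.
#' @return Volume in mm^3, vectorized over the inputs.
#' @examples
#' ellipsoid_volume(10, 6) # 60 * pi
#' @export
ellipsoid_volume <- function(length, width) {
  if (any(!is.finite(length)) || any(!is.finite(width)) ||
      any(length <= 0) || any(width <= 0)) {
    stop("caliper dimensions must be finite and positive", call. = FALSE)
  }
  l <- pmax(length, width)
  w <- pmin(length, width)
  (l * w^2) * pi / 6
}

#' PDX engraftment success rate
#'
#' @param n_engrafted Number of specimens that established a growing model.
#' @param n_implanted Number of specimens implanted.
#' @return A tibble with the exact percentage and the integer-rounded value.
#' @examples
#' engraftment_rate(58, 473)
#' @export
engraftment_rate <- function(n_engrafted, n_implanted) {
  stopifnot(n_implanted > 0, n_engrafted >= 0, n_engrafted <= n_implanted)
  pct <- 100 * n_engrafted / n_implanted
  tibble::tibble(
    n_engrafted = n_engrafted,
    n_implanted = n_implanted,
    rate_pct = pct,
    rate_pct_rounded = round_half_away(pct)
  )
}

# Add an mm^3 volume column; swap length/width so width <= length.
add_volumes <- function(measurements) {
  measurements %>%
    dplyr::mutate(
      .l = pmax(.data$length_mm, .data$width_mm),
      .w = pmin(.data$length_mm, .data$width_mm),
      length_mm = .data$.l,
      width_mm = .data$.w,
      volume_mm3 = ellipsoid_volume(.data$length_mm, .data$width_mm)
    ) %>%
    dplyr::select(-".l", -".w")
}

#' Percent tumor-volume change per tumor
#'
#' For every tumor (one `model_id`/`animal_id`/`arm` series) computes
#' \eqn{100 (V_{day} - V_{baseline}) / V_{baseline}} at the requested day.
#' A measurement at exactly the requested day is preferred; otherwise the
#' nearest measurement within `window` days is used; series with no
#' measurement in the window, or no day-0 baseline, are returned with `NA`
#' and `evaluable = FALSE`.
#'
#' @param measurements A caliper table with columns `model_id`, `animal_id`,
#'   `arm`, `day`, `length_mm`, `width_mm`.
#' @param day Target day since treatment start (default 35, the standard
#'   efficacy endpoint).
#' @param window Maximum distance in days for the nearest-day fallback
#'   (default 3).
#' @return A tibble with one row per tumor: `model_id`, `animal_id`, `arm`,
#'   `day_used`, `pct_change`, `evaluable`.
#' @export
pct_volume_change <- function(measurements, day = 35, window = 3) {
  check_caliper(measurements)
  stopifnot(is.finite(day), day >= 0)
  add_volumes(measurements) %>%
    dplyr::group_by(.data$model_id, .data$animal_id, .data$arm) %>%
    dplyr::group_modify(function(d, key) {
      base <- d$volume_mm3[d$day == 0]
      if (length(base) == 0L) {
        return(tibble::tibble(day_used = NA_real_, pct_change = NA_real_, evaluable = FALSE))
      }
      base <- base[[1]]
      dist <- abs(d$day - day)
      i <- which.min(dist)
      if (d$day[i] == 0 && day > 0) {
        # only the baseline is in range
        cand <- which(d$day > 0 & dist <= window)
        i <- if (length(cand)) cand[which.min(dist[cand])] else NA_integer_
      } else if (dist[i] > window) {
        i <- NA_integer_
      }
      if (is.na(i)) {
        return(tibble::tibble(day_used = NA_real_, pct_change = NA_real_, evaluable = FALSE))
      }
      tibble::tibble(
        day_used = d$day[i],
        pct_change = 100 * (d$volume_mm3[i] - base) / base,
        evaluable = TRUE
      )
    }) %>%
    dplyr::ungroup()
}

#' Classify percent change into mRECIST-like response bands
#'
#' Band boundaries follow the preclinical mRECIST convention, closed on the
#' sensitive side: CR for best response \eqn{\le -95}%, PR for
#' \eqn{(-95, -30]}, SD for \eqn{(-30, +20]} and PD above +20%.
#'
#' @param best_pct_change Numeric vector of best percent volume changes.
#' @return A factor with levels `CR`, `PR`, `SD`, `PD`.
#' @examples
#' classify_mrecist(c(-100, -95, -30, 20, 20.01))
#' @export
classify_mrecist <- function(best_pct_change) {
  if (any(!is.finite(best_pct_change) & !is.na(best_pct_change))) {
    stop("best_pct_change must be finite", call. = FALSE)
  }
  cut(best_pct_change,
    breaks = c(-Inf, -95, -30, 20, Inf),
    labels = c("CR", "PR", "SD", "PD"),
    right = TRUE
  )
}

#' Per-tumor response calls from a caliper table
#'
#' Computes, for each tumor, the best (most negative) percent volume change
#' over the whole treatment window, the percent change at the reporting day
#' (day 35 by default), and the mRECIST class determined by the best
#' response. Tumors without a baseline or with fewer than two measurements
#' are marked not evaluable.
#'
#' @inheritParams pct_volume_change
#' @param arms Optional character vector restricting to treatment arms
#'   (e.g. exclude the vehicle arm before summarizing responses).
#' @param min_day Earliest day contributing to the best response (default
#'   10). The best response is the most negative percent change over
#'   measurements taken at `min_day` or later; the short exclusion window
#'   avoids calling a spurious "best" from the first days after treatment
#'   start, when even a progressing tumor has barely moved from baseline —
#'   the convention of preclinical mRECIST analyses.
#' @return A tibble with one row per tumor: identity columns,
#'   `best_pct_change`, `day_pct_change`, `day_used`, `mrecist`, `evaluable`.
#' @export
response_calls <- function(measurements, day = 35, window = 3, arms = NULL,
                           min_day = 10) {
  check_caliper(measurements)
  if (!is.null(arms)) measurements <- dplyr::filter(measurements, .data$arm %in% arms)
  best <- add_volumes(measurements) %>%
    dplyr::group_by(.data$model_id, .data$animal_id, .data$arm) %>%
    dplyr::group_modify(function(d, key) {
      base <- d$volume_mm3[d$day == 0]
      eligible <- d$day >= max(min_day, .Machine$double.eps)
      if (length(base) == 0L || !any(eligible)) {
        return(tibble::tibble(best_pct_change = NA_real_, evaluable = FALSE))
      }
      base <- base[[1]]
      pc <- 100 * (d$volume_mm3[eligible] - base) / base
      tibble::tibble(best_pct_change = min(pc), evaluable = TRUE)
    }) %>%
    dplyr::ungroup()
  at_day <- pct_volume_change(measurements, day = day, window = window) %>%
    dplyr::select("model_id", "animal_id", "arm",
      day_pct_change = "pct_change", "day_used"
    )
  best %>%
    dplyr::left_join(at_day, by = c("model_id", "animal_id", "arm")) %>%
    dplyr::mutate(
      mrecist = classify_mrecist(.data$best_pct_change)
    )
}

#' Model-level response calls
#'
#' Averages the per-day percent volume change across the tumors of each
#' model and arm (the way cohort waterfall and spaghetti plots aggregate
#' replicate tumors), then derives the best response and mRECIST class of
#' the model from that mean trajectory.
#'
#' @inheritParams response_calls
#' @return One row per model and arm: `best_pct_change`, `day_pct_change`,
#'   `mrecist`, `evaluable`, `n_tumors`.
#' @export
model_response_calls <- function(measurements, day = 35, window = 3,
                                 arms = NULL, min_day = 10) {
  check_caliper(measurements)
  if (!is.null(arms)) measurements <- dplyr::filter(measurements, .data$arm %in% arms)
  traj <- add_volumes(measurements) %>%
    dplyr::group_by(.data$model_id, .data$animal_id, .data$arm) %>%
    dplyr::group_modify(function(d, key) {
      base <- d$volume_mm3[d$day == 0]
      if (length(base) == 0L) {
        return(tibble::tibble(day = numeric(), pct_change = numeric()))
      }
      tibble::tibble(
        day = d$day,
        pct_change = 100 * (d$volume_mm3 - base[[1]]) / base[[1]]
      )
    }) %>%
    dplyr::ungroup()
  traj %>%
    dplyr::group_by(.data$model_id, .data$arm, .data$day) %>%
    dplyr::summarise(
      pct_change = mean(.data$pct_change),
      n_tumors = dplyr::n(),
      .groups = "drop"
    ) %>%
    dplyr::group_by(.data$model_id, .data$arm) %>%
    dplyr::group_modify(function(d, key) {
      eligible <- d$day >= min_day
      best <- if (any(eligible)) min(d$pct_change[eligible]) else NA_real_
      near <- which(abs(d$day - day) <= window & d$day > 0)
      at_day <- if (length(near)) {
        d$pct_change[near[which.min(abs(d$day[near] - day))]]
      } else {
        NA_real_
      }
      tibble::tibble(
        best_pct_change = best,
        day_pct_change = at_day,
        evaluable = !is.na(best),
        n_tumors = max(d$n_tumors)
      )
    }) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(mrecist = classify_mrecist(.data$best_pct_change))
}

#' Relative tumor volume with growth bands
#'
#' Computes RTV\eqn{_t = V_t / V_{baseline}} for every measurement of every
#' tumor, with the growth-band label used in longitudinal (spaghetti) plots:
#' PD above 1.2, SD in \[0.7, 1.2\], PR/CR below 0.7.
#'
#' @inheritParams pct_volume_change
#' @return A tibble with identity columns plus `day`, `rtv`, `band`.
#' @export
relative_tumor_volume <- function(measurements) {
  check_caliper(measurements)
  add_volumes(measurements) %>%
    dplyr::group_by(.data$model_id, .data$animal_id, .data$arm) %>%
    dplyr::group_modify(function(d, key) {
      base <- d$volume_mm3[d$day == 0]
      if (length(base) == 0L) {
        stop("series without a day-0 baseline: ", key$model_id, "/", key$animal_id,
          call. = FALSE
        )
      }
      d$rtv <- d$volume_mm3 / base[[1]]
      d[, c("day", "rtv")]
    }) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(band = rtv_band(.data$rtv))
}

#' @rdname relative_tumor_volume
#' @param rtv Numeric vector of relative tumor volumes (must be positive).
#' @export
rtv_band <- function(rtv) {
  if (any(rtv < 0, na.rm = TRUE)) stop("RTV cannot be negative", call. = FALSE)
  cut(rtv,
    breaks = c(-Inf, 0.7, 1.2, Inf),
    labels = c("PR/CR", "SD", "PD"),
    right = FALSE
  ) -> out
  # make the 1.2 boundary inclusive for SD: [0.7, 1.2]
  out[!is.na(rtv) & rtv == 1.2] <- "SD"
  out
}

#' Cohort-level response summary (pRR and pCB)
#'
#' Aggregates per-tumor (or per-model) response calls into class counts, the
#' preclinical response rate pRR = 100 (CR + PR) / n and the preclinical
#' benefit rate pCB = 100 (CR + PR + SD) / n over evaluable calls, with both
#' exact and integer-rounded percentages, the mean best percent change and
#' its bootstrap standard error.
#'
#' @param calls A tibble with a `mrecist` column (and optionally
#'   `best_pct_change` and `evaluable`), as produced by [response_calls()].
#' @param n_boot Bootstrap resamples for the SE of the mean percent change
#'   (default 2000).
#' @param seed Seed for the bootstrap (default 1).
#' @return An object of class `cohort_summary` with `counts`, `n_evaluable`,
#'   `prr`, `pcb` (exact), `prr_rounded`, `pcb_rounded`, `mean_change` and
#'   `se_change`. [tidy()] and [glance()] methods are provided.
#' @export
cohort_summary <- function(calls, n_boot = 2000, seed = 1) {
  stopifnot(is.data.frame(calls), "mrecist" %in% names(calls))
  if ("evaluable" %in% names(calls)) calls <- dplyr::filter(calls, .data$evaluable)
  calls <- dplyr::filter(calls, !is.na(.data$mrecist))
  n <- nrow(calls)
  if (n == 0L) stop("no evaluable response calls in cohort", call. = FALSE)
  cls <- factor(calls$mrecist, levels = c("CR", "PR", "SD", "PD"))
  counts <- table(cls)
  prr <- 100 * (counts[["CR"]] + counts[["PR"]]) / n
  pcb <- 100 * (counts[["CR"]] + counts[["PR"]] + counts[["SD"]]) / n
  mean_change <- se_change <- NA_real_
  if ("best_pct_change" %in% names(calls) &&
      sum(is.finite(calls$best_pct_change)) >= 2) {
    v <- calls$best_pct_change[is.finite(calls$best_pct_change)]
    mean_change <- mean(v)
    se_change <- bootstrap_se(v, n_boot = n_boot, seed = seed)
  }
  structure(
    list(
      counts = tibble::tibble(
        mrecist = names(counts),
        n = as.integer(counts)
      ),
      n_evaluable = n,
      prr = prr,
      pcb = pcb,
      prr_rounded = round_half_away(prr),
      pcb_rounded = round_half_away(pcb),
      mean_change = mean_change,
      se_change = se_change
    ),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort of", x$n_evaluable, "evaluable responses\n")
  cat(sprintf(
    "  pRR %.1f%% (%d%%), pCB %.1f%% (%d%%)\n",
    x$prr, x$prr_rounded, x$pcb, x$pcb_rounded
  ))
  print(tidyr::pivot_wider(x$counts, names_from = "mrecist", values_from = "n"))
  invisible(x)
}

#' Bootstrap standard error of a mean
#'
#' Standard deviation of `n_boot` resampled means; the convention used for
#' the SE of the mean percent tumor-volume change. Deterministic for a given
#' seed.
#'
#' @param values Numeric vector (at least 2 values).
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param seed Integer seed.
#' @return The bootstrap standard error (a single number).
#' @export
bootstrap_se <- function(values, n_boot = 2000, seed = 1) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("need at least 2 values for a bootstrap SE", call. = FALSE)
  withr::with_seed(seed, {
    means <- vapply(
      seq_len(n_boot),
      function(i) mean(sample(values, replace = TRUE)),
      numeric(1)
    )
  })
  stats::sd(means)
}

check_caliper <- function(measurements) {
  need <- c("model_id", "animal_id", "arm", "day", "length_mm", "width_mm")
  missing <- setdiff(need, names(measurements))
  if (length(missing)) {
    stop("caliper table is missing columns: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(measurements$day < 0)) stop("day must be >= 0", call. = FALSE)
  invisible(measurements)
}
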