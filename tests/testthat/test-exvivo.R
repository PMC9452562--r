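make_areas <- function(treated_mean, vehicle_mean = 100, n = 4, model = "M1") {
  tibble::tibble(
    model_id = model,
    condition = rep(c("vehicle", "treated"), each = n),
    replicate = rep(seq_len(n), 2),
    area = c(rep(vehicle_mean, n), rep(treated_mean, n))
  )
}

test_that("relative spheroid area normalizes to the vehicle mean", {
  out <- relative_spheroid_area(make_areas(100))
  expect_equal(out$relative_area_pct[out$condition == "treated"], 100)
  expect_equal(out$change_pct[out$condition == "treated"], 0)
  half <- relative_spheroid_area(make_areas(50))
  expect_equal(half$change_pct[half$condition == "treated"], -50)
  at_cut <- relative_spheroid_area(make_areas(75))
  expect_equal(at_cut$change_pct[at_cut$condition == "treated"], -25)
  no_veh <- dplyr::filter(make_areas(50), condition != "vehicle")
  expect_error(relative_spheroid_area(no_veh), "vehicle")
})

test_that("relative readouts are scale invariant", {
  a <- make_areas(63)
  scaled <- dplyr::mutate(a, area = area * 17.3)
  expect_equal(
    relative_spheroid_area(a)$relative_area_pct,
    relative_spheroid_area(scaled)$relative_area_pct
  )
})

test_that("EdU fractions and vehicle-relative values follow count arithmetic", {
  expect_equal(edu_fraction(0, 200), 0)
  expect_equal(edu_fraction(50, 200), 25)
  expect_equal(relative_edu(10, 40), 25)
  expect_error(edu_fraction(201, 200), "edu_positive")
  expect_error(edu_fraction(5, 0), "edu_positive")
})

test_that("ex vivo response boundary is inclusive at the -25% cutoff", {
  expect_equal(
    classify_exvivo_response(c(-30, -25, 5)),
    c("sensitive", "sensitive", "resistant")
  )
})

test_that("ROC AUC equals the Mann-Whitney pair-counting identity", {
  withr::with_seed(7, {
    for (i in 1:20) {
      n <- sample(6:30, 1)
      scores <- sample(seq(-60, 20, by = 5), n, replace = TRUE)
      labels <- rbinom(n, 1, 0.5)
      if (length(unique(labels)) < 2) next
      r <- roc_points(scores, labels)
      expect_equal(r$auc, oracle_auc(scores, labels))
    }
  })
})

test_that("ROC AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(13, {
    scores <- rnorm(60)
    labels <- rbinom(60, 1, 0.5)
  })
  ours <- roc_points(scores, labels)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(labels, scores,
    direction = "<", quiet = TRUE
  )))
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("optimal ex vivo cutoff lands between separated class means", {
  withr::with_seed(21, {
    n <- 37
    lab <- sample(c("sensitive", "resistant"), n, TRUE, prob = c(0.4, 0.6))
    chg <- ifelse(lab == "sensitive", rnorm(n, -50, 10), rnorm(n, 0, 10))
  })
  rc <- roc_optimal_cutoff(chg, lab)
  expect_gt(rc$threshold, -50)
  expect_lt(rc$threshold, 0)
  expect_gt(rc$auc, 0.95)
  # perfectly separated case
  perfect <- roc_optimal_cutoff(
    c(-60, -55, -50, 5, 10, 15),
    rep(c("sensitive", "resistant"), each = 3)
  )
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  # shuffled labels give chance-level AUC
  withr::with_seed(3, {
    big_chg <- rnorm(2000)
    big_lab <- rbinom(2000, 1, 0.5)
  })
  expect_lt(abs(roc_points(big_chg, big_lab)$auc - 0.5), 0.05)
})

test_that("plate normalization applies day-0 then vehicle ordering", {
  plate <- tidyr::expand_grid(
    dose = c(0, 1, 10), replicate = 1:2, day = c(0, 6)
  ) %>%
    dplyr::mutate(value = ifelse(day == 0, 100,
      ifelse(dose == 0, 400, ifelse(dose == 1, 300, 200))
    ))
  out <- normalize_plate(plate)
  expect_equal(out$growth_pct[out$dose == 0], c(100, 100))
  expect_equal(out$growth_pct[out$dose == 1], c(75, 75))
  expect_equal(out$growth_pct[out$dose == 10], c(50, 50))
})

test_that("4PL fit recovers a noiseless IC50 and flags curves never reaching 50%", {
  doses <- 10^seq(-2, 2, length.out = 8)
  y <- 100 / (1 + doses / 1) # true IC50 = 1, lower 0, upper 100
  plate <- tibble::tibble(dose = doses, growth_pct = y)
  fit <- fit_ic50(plate)
  expect_false(fit$not_reached)
  expect_equal(fit$ic50, 1, tolerance = 0.01)
  # monotone-increasing response: no inhibition, 50% never reached
  up <- tibble::tibble(dose = doses, growth_pct = 100 + 10 * log10(doses) + 25)
  fit_up <- fit_ic50(up)
  expect_true(fit_up$not_reached)
  expect_true(is.na(fit_up$ic50))
  expect_error(fit_ic50(tibble::tibble(dose = c(1, 2), growth_pct = c(60, 40))), "4 distinct")
})

test_that("fold change is the plain IC50 ratio", {
  expect_equal(fold_change(20, 1), 20)
  expect_error(fold_change(NA, 1), "finite")
})
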