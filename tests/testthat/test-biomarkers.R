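test_that("Allred scoring follows the proportion bins plus intensity", {
  expect_equal(allred_score(0, 0), 0L)
  expect_equal(allred_score(80, 3), 8L)
  expect_equal(allred_score(20, 2), 5L)
  # bin-table oracle over the full grid
  bins <- function(p) {
    if (p == 0) 0 else if (p < 1) 1 else if (p <= 10) 2 else if (p <= 33) 3 else if (p <= 66) 4 else 5
  }
  for (p in c(0, 0.5, 1, 5, 10, 10.5, 33, 34, 66, 67, 100)) {
    for (i in 0:3) expect_equal(allred_score(p, i), bins(p) + i)
  }
  expect_error(allred_score(101, 1), "0, 100")
  expect_error(allred_score(50, 4), "0-3")
})

test_that("composite classifier fires rules in the documented order", {
  panel <- tibble::tibble(
    sample_id = paste0("s", 1:5),
    p16 = c(4, 0, 1, 0, 3),
    prb = c(3, 4, 3, 1, 1),
    cyclin_e1 = c(2, 0, 6, 0, 8),
    cyclin_d1 = c(2, 0, 2, 0, 8),
    subtype = c("LumB", "LumB", "LumB", "LumB", "Basal")
  )
  out <- classify_composite(panel)
  expect_equal(out$predicted, c("resistant", "sensitive", "resistant", "resistant", "resistant"))
  expect_equal(out$fired_rule, c("p16_high", "none", "cyclin_high", "prb_low", "basal_subtype"))
})

test_that("composite call is invariant to swapping cyclin roles with matched cutoffs", {
  withr::with_seed(5, {
    panel <- tibble::tibble(
      sample_id = paste0("s", 1:50),
      p16 = sample(0:4, 50, TRUE), prb = sample(0:4, 50, TRUE),
      cyclin_e1 = sample(0:8, 50, TRUE), cyclin_d1 = sample(0:8, 50, TRUE),
      subtype = sample(c("LumA", "LumB", "Basal"), 50, TRUE)
    )
  })
  a <- classify_composite(panel)
  swapped <- dplyr::rename(panel, cyclin_e1 = cyclin_d1, cyclin_d1 = cyclin_e1)
  cut2 <- default_cutoffs()
  cut2$e1_high_gt <- 6
  cut2$d1_high_gt <- 4
  b <- classify_composite(swapped, cut2)
  expect_equal(a$predicted, b$predicted)
})

test_that("missing scores cannot fire rules; all-missing panel errors", {
  p <- tibble::tibble(
    sample_id = "x", p16 = NA, prb = NA, cyclin_e1 = NA, cyclin_d1 = 2,
    subtype = "LumA"
  )
  expect_equal(classify_composite(p)$predicted, "sensitive")
  p_all <- dplyr::mutate(p, cyclin_d1 = NA)
  expect_error(classify_composite(p_all), "unclassifiable")
})

test_that("Youden cutoff equals exhaustive enumeration on random instances", {
  # worked micro-example
  out <- youden_cutoff(1:4, c("sensitive", "sensitive", "resistant", "resistant"))
  expect_equal(out$threshold, 3)
  expect_equal(out$j, 1)
  withr::with_seed(99, {
    for (i in 1:40) {
      n <- sample(5:50, 1)
      scores <- sample(0:10, n, replace = TRUE)
      labels <- rbinom(n, 1, 0.5)
      if (length(unique(labels)) < 2) next
      dir_high <- runif(1) < 0.5
      got <- youden_cutoff(scores, labels,
        direction = if (dir_high) "high_is_positive" else "low_is_positive"
      )
      want <- oracle_youden(scores, labels, high_is_positive = dir_high)
      expect_equal(got$threshold, want$threshold)
      expect_equal(got$j, want$j)
      expect_equal(got$sensitivity, want$sens)
      expect_equal(got$specificity, want$spec)
    }
  })
})

test_that("Youden J is near zero when labels are independent of scores", {
  withr::with_seed(17, {
    scores <- rnorm(4000)
    labels <- rbinom(4000, 1, 0.5)
  })
  expect_lt(youden_cutoff(scores, labels)$j, 0.1)
  expect_error(youden_cutoff(1:5, rep(1, 5)), "both classes")
})

test_that("concordance metrics reproduce 2x2 arithmetic exactly", {
  pred <- rep(c("resistant", "sensitive"), c(14, 9))
  obs <- c(
    rep("resistant", 13), "sensitive", # 13 TP, 1 FP
    rep("resistant", 2), rep("sensitive", 7) # 2 FN, 7 TN
  )
  cc <- concordance(pred, obs)
  expect_equal(cc$table$tp, 13)
  expect_equal(cc$sensitivity, 13 / 15)
  expect_equal(cc$accuracy, 20 / 23)
  expect_equal(cc$ppv, 13 / 14)
  expect_equal(cc$npv, 7 / 9)
  # identical vectors: all ones
  same <- concordance(obs, obs)
  expect_equal(tidy(same)$value, rep(1, 5))
  # degenerate: everything called resistant
  allr <- concordance(rep("resistant", 10), rep(c("resistant", "sensitive"), 5))
  expect_equal(allr$sensitivity, 1)
  expect_equal(allr$specificity, 0)
  expect_error(concordance(1:3, 1:4), "same length")
})

test_that("KI67 rules use the printed boundaries", {
  expect_equal(ki67_luminal_split(c(14.9, 15, 0)), c("LumA", "LumB", "LumA"))
  expect_error(ki67_luminal_split(101), "0, 100")
  expect_equal(ki67_response(2), "sensitive") # ln 2 = 0.69 < 1
  expect_equal(ki67_response(exp(1)), "resistant") # ln = 1 exactly
  expect_equal(ki67_response(20), "resistant")
  expect_warning(out <- ki67_response(0), "clamped")
  expect_equal(out, "sensitive")
})

test_that("OR per SD recovers the null and flags separation", {
  withr::with_seed(31, {
    d <- data.frame(h = rnorm(600, 150, 40), y = rbinom(600, 1, 0.4))
  })
  out <- or_per_sd(d, h, y)
  expect_gt(out$odds_ratio, 0.8)
  expect_lt(out$odds_ratio, 1.25)
  expect_true(out$conf_low < 1 && out$conf_high > 1)
  sep <- data.frame(h = c(1:10, 101:110), y = rep(c(0, 1), each = 10))
  expect_true(or_per_sd(sep, h, y)$separation)
})
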