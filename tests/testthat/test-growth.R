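test_that("ellipsoid volume matches the closed formula and is symmetric", {
  expect_equal(ellipsoid_volume(10, 6), 60 * pi)
  expect_equal(ellipsoid_volume(1, 1), pi / 6)
  expect_equal(ellipsoid_volume(6, 10), ellipsoid_volume(10, 6))
  expect_error(ellipsoid_volume(0, 5), "positive")
  expect_error(ellipsoid_volume(5, -1), "positive")
})

test_that("percent volume change reproduces hand arithmetic", {
  s <- make_series(c(0, 35), c(200, 200))
  expect_equal(pct_volume_change(s)$pct_change, 0)
  s <- make_series(c(0, 35), c(200, 100))
  expect_equal(pct_volume_change(s)$pct_change, -50)
  s <- make_series(c(0, 35), c(100, 240))
  expect_equal(pct_volume_change(s)$pct_change, 140)
})

test_that("day matching prefers exact day, then nearest within the window", {
  s <- make_series(c(0, 14, 33, 36), c(100, 90, 80, 70))
  out <- pct_volume_change(s, day = 35, window = 3)
  expect_equal(out$day_used, 36) # nearest to 35
  out14 <- pct_volume_change(s, day = 14)
  expect_equal(out14$day_used, 14)
  far <- pct_volume_change(s, day = 25, window = 3)
  expect_false(far$evaluable)
  no_base <- make_series(c(7, 35), c(100, 50))
  expect_false(pct_volume_change(no_base)$evaluable)
})

test_that("mRECIST banding matches the band definitions and an if-chain oracle", {
  expect_equal(as.character(classify_mrecist(c(-95, -30, 20, 20.01, -100))),
    c("CR", "PR", "SD", "PD", "CR"))
  grid <- c(seq(-120, 50, by = 0.5), -95, -95.0001, -94.9999,
    -30.0001, -29.9999, 19.9999, 20.0001)
  expect_equal(as.character(classify_mrecist(grid)), oracle_mrecist(grid))
  expect_error(classify_mrecist(Inf), "finite")
  # exhaustive and mutually exclusive: every value gets exactly one class
  expect_false(anyNA(classify_mrecist(grid)))
})

test_that("relative tumor volume bands follow the 0.7/1.2 boundaries", {
  s <- make_series(c(0, 7, 14), c(100, 100, 100))
  rtv <- relative_tumor_volume(s)
  expect_equal(rtv$rtv, c(1, 1, 1))
  expect_equal(as.character(rtv$band), rep("SD", 3))
  s2 <- make_series(c(0, 7), c(100, 200))
  expect_equal(as.character(relative_tumor_volume(s2)$band)[2], "PD")
  grid <- c(seq(0, 3, by = 0.01), 0.7, 1.2, 0.69, 1.21)
  expect_equal(as.character(rtv_band(grid)), oracle_rtv_band(grid))
})

test_that("cohort summary reproduces the printed screen rates and conserves counts", {
  calls <- tibble::tibble(mrecist = rep(c("CR", "PR", "SD", "PD"), c(1, 2, 2, 16)))
  cs <- cohort_summary(calls)
  expect_equal(cs$n_evaluable, 21)
  expect_equal(cs$prr, 100 * 3 / 21)
  expect_equal(cs$pcb, 100 * 5 / 21)
  expect_equal(cs$prr_rounded, 14)
  expect_equal(cs$pcb_rounded, 24)
  expect_equal(sum(cs$counts$n), cs$n_evaluable)
  all_pd <- cohort_summary(tibble::tibble(mrecist = rep("PD", 5)))
  expect_equal(c(all_pd$prr, all_pd$pcb), c(0, 0))
  all_cr <- cohort_summary(tibble::tibble(mrecist = rep("CR", 4)))
  expect_equal(c(all_cr$prr, all_cr$pcb), c(100, 100))
  expect_error(cohort_summary(tibble::tibble(mrecist = character())), "evaluable")
})

test_that("pRR <= pCB <= 100 over random cohorts", {
  withr::with_seed(42, {
    for (i in 1:25) {
      calls <- tibble::tibble(
        mrecist = sample(c("CR", "PR", "SD", "PD"), sample(3:40, 1), replace = TRUE)
      )
      cs <- cohort_summary(calls)
      expect_lte(cs$prr, cs$pcb)
      expect_lte(cs$pcb, 100)
    }
  })
})

test_that("bootstrap SE is 0 for constants, deterministic, and near sigma/sqrt(n)", {
  expect_equal(bootstrap_se(rep(5, 10), seed = 7), 0)
  v <- withr::with_seed(11, rnorm(100))
  expect_identical(bootstrap_se(v, seed = 3), bootstrap_se(v, seed = 3))
  expect_error(bootstrap_se(1), "at least 2")
})

test_that("best response uses the day >= 10 window and day-35 value is reported", {
  # tumor that dips transiently early, then progresses
  s <- make_series(c(0, 3, 14, 35), c(100, 95, 130, 180))
  rc <- response_calls(s)
  expect_equal(rc$best_pct_change, 30) # day-3 dip ignored
  expect_equal(rc$day_pct_change, 80)
  expect_equal(as.character(rc$mrecist), "PD")
  # responder keeps its minimum inside the window
  s2 <- make_series(c(0, 14, 35), c(100, 60, 40))
  expect_equal(response_calls(s2)$best_pct_change, -60)
})

test_that("model-level calls average tumor trajectories before banding", {
  two <- dplyr::bind_rows(
    make_series(c(0, 14, 35), c(100, 60, 40), animal = "a1"),
    make_series(c(0, 14, 35), c(200, 160, 160), animal = "a2")
  )
  mc <- model_response_calls(two)
  # per-tumor changes at day 35: -60 and -20 -> mean -40 -> PR
  expect_equal(mc$best_pct_change, -40)
  expect_equal(as.character(mc$mrecist), "PR")
  expect_equal(mc$n_tumors, 2)
})

test_that("engraftment rate reproduces the 58-of-473 worked example", {
  er <- engraftment_rate(58, 473)
  expect_equal(er$rate_pct_rounded, 12)
  expect_equal(er$rate_pct, 100 * 58 / 473)
})
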