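test_that("protein-change parsing covers the reported variant styles", {
  expect_equal(
    parse_protein_change(c(
      "p.M695Nfs*26", "p.K810*", "p.X180_splice", "p.H1047R", "", NA, "gibberish"
    )),
    c(
      "frameshift_variant", "stop_gained", "splice_variant",
      "missense_variant", "unknown", "unknown", "unknown"
    )
  )
  expect_equal(parse_protein_change("p.Q217Efs*5"), "frameshift_variant")
  expect_equal(parse_protein_change("p.L199P"), "missense_variant")
  expect_equal(parse_protein_change("p.M1?"), "start_lost")
})

test_that("consequence rule sets: truncating is a strict subset of coding", {
  expect_true(all(deleterious_truncating_terms() %in% hmf_coding_terms()))
  v <- tibble::tibble(
    sample_id = "s", gene = "RB1",
    consequence = c("missense variant", "frameshift variant", "inframe deletions")
  )
  coding <- classify_consequence(v, "hmf_coding")
  trunc <- classify_consequence(v, "deleterious_truncating")
  expect_equal(coding$qualifies, c(TRUE, TRUE, TRUE))
  expect_equal(trunc$qualifies, c(FALSE, TRUE, FALSE))
  # hmf_coding superset property on arbitrary parsed inputs
  w <- tibble::tibble(
    sample_id = "s", gene = "g",
    protein_change = c("p.M695Nfs*26", "p.K810*", "p.X180_splice", "p.A5T", "junk")
  )
  expect_true(all(
    classify_consequence(w, "deleterious_truncating")$qualifies <=
      classify_consequence(w, "hmf_coding")$qualifies
  ))
})

test_that("CN log-ratio bands match the printed boundaries and an oracle grid", {
  expect_equal(
    as.character(classify_cn_logratio(c(-0.9, -1.5, 0))),
    c("shallow_del", "deep_del", "unaltered")
  )
  grid <- c(seq(-5, 2, by = 0.01), -1, -0.4, -1.0001, -0.3999)
  expect_equal(as.character(classify_cn_logratio(grid)), oracle_cn_band(grid))
  expect_false(anyNA(classify_cn_logratio(grid)))
})

test_that("allele-CN deletion calls follow the 0.01 threshold", {
  expect_equal(
    as.character(classify_allele_cn(c(0, 0, 1), c(0, 1, 1))),
    c("hom_del", "het_del", "unaltered")
  )
  expect_equal(as.character(classify_allele_cn(0.009, 0.009)), "hom_del")
  expect_equal(as.character(classify_allele_cn(0.009, 0.01)), "het_del")
  expect_error(classify_allele_cn(-0.1, 1), "non-negative")
  expect_error(classify_allele_cn(2, 1), "minor_cn")
})

test_that("double-hit calling composes mutation and deletion evidence", {
  v <- tibble::tibble(
    sample_id = c("A", "C"), gene = "RB1",
    protein_change = c("p.K810*", "p.R320*")
  )
  cn <- tibble::tibble(
    sample_id = c("A", "B", "C", "D"), gene = "RB1",
    minor_cn = c(0, 0, 1, 0), major_cn = c(1, 1, 1, 0.005)
  )
  out <- call_double_hit(v, cn, gene = "RB1")
  expect_equal(out$category[out$sample_id == "A"], "double_hit")
  expect_equal(out$category[out$sample_id == "B"], "deletion_only")
  expect_equal(out$category[out$sample_id == "C"], "mutation_only")
  expect_equal(out$category[out$sample_id == "D"], "homozygous_deletion")
})

test_that("allele CN takes precedence over log-ratio; caller is order independent and idempotent", {
  v <- tibble::tibble(sample_id = "A", gene = "RB1", protein_change = "p.K810*")
  cn <- tibble::tibble(
    sample_id = "A", gene = "RB1",
    log_ratio = -2, minor_cn = 0.001, major_cn = 1.2
  )
  # log-ratio says deep del, allele CN says het del -> het del wins
  out <- call_double_hit(v, cn)
  expect_equal(out$category, "double_hit")
  expect_false(out$hom_del_flag)
  # shuffling input rows changes nothing
  v2 <- tibble::tibble(
    sample_id = c("A", "B", "A"), gene = "RB1",
    protein_change = c("p.A5T", "p.K810*", "p.M695Nfs*26")
  )
  cn2 <- tibble::tibble(
    sample_id = c("B", "A"), gene = "RB1",
    minor_cn = c(0, 0.004), major_cn = c(1, 1)
  )
  a <- call_double_hit(v2, cn2)
  b <- call_double_hit(v2[c(3, 1, 2), ], cn2[c(2, 1), ])
  expect_identical(a, b)
})

test_that("packaged derivative tumors yield 3 of 8 deleterious RB1 mutations", {
  variants <- readr::read_tsv(
    system.file("extdata", "pdx244_variants.tsv", package = "cdkresist"),
    show_col_types = FALSE
  )
  cn <- readr::read_tsv(
    system.file("extdata", "pdx244_copynumber.tsv", package = "cdkresist"),
    show_col_types = FALSE
  )
  hits <- call_double_hit(variants, cn, gene = "RB1", rule_set = "deleterious_truncating")
  resistant <- setdiff(unique(cn$sample_id), "2R")
  expect_length(resistant, 8)
  expect_equal(sum(hits$mutation_flag[hits$sample_id %in% resistant]), 3)
  # the three mutated derivatives sit on the shallow-deleted background
  expect_equal(
    sort(hits$sample_id[hits$category == "double_hit"]),
    c("16L", "16R", "18R")
  )
})

test_that("association models recover the interaction and error on degenerate cohorts", {
  cfg <- synthetic_config(seed = 4, cohort_n = 2000, double_hit_log_or = 1.5)
  cohort <- sim_genomic_cohort(cfg)$cohort
  am <- association_models(cohort)
  t1 <- tidy(am)
  inter <- t1[t1$model == "M1" & t1$term == "mutation:deletion", ]
  expect_gt(inter$estimate, 0.5)
  # M1 and M2 agree in sign of the double-hit effect
  dh <- t1[t1$model == "M2" & t1$term == "double_hit", ]
  expect_equal(sign(inter$estimate), sign(dh$estimate))
  all_unexposed <- dplyr::mutate(cohort, exposed = 0)
  expect_error(association_models(all_unexposed), "degenerate")
})
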