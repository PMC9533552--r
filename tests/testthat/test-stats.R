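test_that("rank-sum test reproduces exact reference values", {
  expect_equal(ranksum_test(c(1, 2, 3), c(4, 5, 6))$p.value, 0.1)
  # symmetric identical groups carry no evidence
  same <- ranksum_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p.value, 1)
  expect_equal(unname(same$statistic), 3 * 7 / 2)  # null center
})

test_that("exact rank-sum matches wilcox.test when there are no ties", {
  set.seed(61)
  for (i in 1:20) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    v <- sample(seq(0, 1, by = 1e-4), nx + ny)  # distinct values
    x <- v[1:nx]; y <- v[-(1:nx)]
    expect_equal(ranksum_test(x, y)$p.value,
                 wilcox.test(x, y, exact = TRUE)$p.value)
  }
})

test_that("signed-rank test reproduces exact reference values", {
  expect_equal(signrank_test(c(5, 4, 6, 5, 7))$p.value, 2 / 32)
  allzero <- signrank_test(c(0, 0, 0))
  expect_equal(allzero$p.value, 1)
  expect_true(allzero$all_zero)
  set.seed(62)
  for (i in 1:20) {
    d <- sample(seq(0.01, 1, by = 1e-4), sample(4:9, 1)) *
      sample(c(-1, 1), 1, replace = TRUE)
    expect_equal(signrank_test(d)$p.value,
                 wilcox.test(d, exact = TRUE)$p.value)
  }
})

test_that("large-sample fallback approximates the exact p-value", {
  set.seed(63)
  x <- rnorm(25); y <- rnorm(25, 0.5)
  p_norm <- ranksum_test(x, y)$p.value
  expect_equal(p_norm, wilcox.test(x, y, exact = FALSE)$p.value,
               tolerance = 1e-8)
})

test_that("modified z-score flags the documented outlier cases", {
  keep <- detect_outliers(c(1, 2, 3, 100))
  expect_equal(keep, c(TRUE, TRUE, TRUE, FALSE), ignore_attr = TRUE)
  # score of the outlier: 0.6745 * 97.5 / 1.0
  expect_equal(attr(keep, "scores")[4], 0.6745 * 97.5, tolerance = 1e-9)
  expect_true(all(detect_outliers(c(5, 5, 5, 5))))
  expect_true(all(detect_outliers(c(1, 2))))  # below minimum n: no exclusion
})

test_that("outlier screening is converged (idempotent on the kept set)", {
  set.seed(64)
  for (i in 1:50) {
    v <- c(rnorm(sample(3:10, 1)), sample(c(numeric(0), 50, -30), 1))
    keep <- detect_outliers(v)
    kept <- v[keep]
    again <- detect_outliers(kept)
    expect_true(all(again), info = paste("values:", paste(v, collapse = ",")))
  }
})

test_that("data points average a donor's contributing images", {
  rows <- tibble::tibble(
    donor = "D1", group = "AD", region = "central", layer = "GCL",
    percent = c(10, 20, 30, 40))
  pts <- aggregate_points(rows, percent)
  expect_equal(pts$value, 25)
  expect_equal(pts$n_images, 4)
  # one image's layer excluded -> mean over the remaining 3
  pts3 <- aggregate_points(rows[-1, ], percent)
  expect_equal(pts3$value, 30)
  expect_equal(pts3$n_images, 3)
  # undefined values never contribute
  rows$percent[2] <- NA
  expect_equal(aggregate_points(rows, percent)$n_images, 3)
})

test_that("group comparison reports both groups and flags empties", {
  pts <- tidyr::expand_grid(donor = sprintf("D%d", 1:8),
                            region = retinal_regions(),
                            layer = retinal_layers()) |>
    dplyr::mutate(group = ifelse(donor %in% sprintf("D%d", 1:4), "AD", "control"),
                  value = ifelse(group == "AD", 2, 1) + as.numeric(factor(donor)) / 100)
  cmp <- compare_groups(pts)
  expect_equal(nrow(cmp), 12)
  expect_true(all(cmp$computable))
  expect_true(all(cmp$mean_ad > cmp$mean_control))
  # perfectly separated groups at n = 4 + 4: exact p = 2 / choose(8, 4)
  expect_equal(unique(cmp$p_value), 2 / choose(8, 4))
  # a missing group is not computable
  cmp2 <- compare_groups(dplyr::filter(pts, group == "AD"))
  expect_true(all(!cmp2$computable))
  expect_true(all(is.na(cmp2$p_value)))
})

test_that("paired colocalization test flags enrichment direction", {
  coloc <- tidyr::expand_grid(donor = sprintf("D%d", 1:6),
                              region = "central", layer = "GCL") |>
    dplyr::mutate(group = "control",
                  p_pos = 10 + (seq_along(donor) %% 3),
                  p_neg = 5)
  out <- paired_coloc_test(coloc)
  expect_equal(out$n_donors, 6)
  expect_equal(out$p_value, 2 / 64)  # all differences positive, n = 6
  expect_true(out$colocalized)
  # reversed direction is never called colocalization
  rev <- paired_coloc_test(dplyr::mutate(coloc, p_pos = 2))
  expect_false(rev$colocalized)
  # too few pairs: flagged not computable
  few <- paired_coloc_test(dplyr::filter(coloc, donor %in% c("D1", "D2")))
  expect_false(few$computable)
})

test_that("significance summaries count tiers and annotate stars", {
  res <- tibble::tibble(group = rep(c("AD", "control"), each = 12),
                        p_value = c(rep(0.004, 2), rep(0.03, 2), rep(0.2, 8),
                                    rep(0.0005, 1), rep(0.2, 11)))
  s <- significance_summary(res)
  expect_equal(s$n_keys, c(12, 12))
  expect_equal(s$n_p05[s$group == "AD"], 4)
  expect_equal(s$n_p01[s$group == "AD"], 2)
  expect_equal(s$n_p001[s$group == "control"], 1)
  expect_equal(signif_stars(c(0.004, 0.03, 0.2, 0.0005)),
               c("**", "*", "", "***"))
})

test_that("tidy and glance expose test results as tibbles", {
  t <- ranksum_test(1:3, 4:6)
  expect_s3_class(tidy(t), "tbl_df")
  expect_equal(tidy(t)$p.value, 0.1)
  expect_equal(glance(t)$alternative, "two.sided")
})

test_that("the donor age-matching check reproduces the cohort facts", {
  chk <- age_matching_check()
  expect_equal(chk$mean_control, 74.8)
  expect_equal(chk$n_ad, 9)
  expect_equal(chk$n_control, 10)
  expect_gt(chk$test$p.value, 0.05)
})
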