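test_that("otsu separates a two-level image", {
  x <- matrix(c(rep(10L, 50), rep(200L, 50)), 10)
  t <- otsu_threshold(x)
  expect_gt(t, 10)
  expect_lte(t, 200)
  m <- threshold_channel(x, t)
  expect_equal(sum(m), 50)
})

test_that("constant images admit no threshold", {
  expect_error(otsu_threshold(matrix(7L, 5, 5)), "no threshold")
})

test_that("otsu classification accuracy on separated Gaussians >= 99%", {
  set.seed(404)
  n <- 1e4
  truth <- rep(c(FALSE, TRUE), each = n / 2)
  x <- matrix(round(stats::rnorm(n, ifelse(truth, 180, 30), 10)), 100)
  t <- otsu_threshold(x)
  acc <- mean((x >= t) == matrix(truth, 100))
  expect_gte(acc, 0.99)
})

test_that("otsu agrees with an independent reference on a full frame", {
  skip_if_not_installed("EBImage")
  set.seed(77)
  x <- matrix(round(stats::rnorm(4e3, rep(c(40, 200), each = 2e3), 15)), 50)
  x[x < 0] <- 0L; x[x > 255] <- 255L
  t <- otsu_threshold(x)
  t_ref <- EBImage::otsu(EBImage::Image(x / 255), range = c(0, 1), levels = 256) * 255
  # same inter-mode gap: identical classification of every pixel
  expect_equal(x >= t, x > t_ref)
})

test_that("masked otsu ignores background pixels", {
  m <- tiling_mask()
  x <- matrix(100L, 60, 10)
  x[m == 0] <- 0L          # nothing outside tissue
  x[m >= 1 & m <= 3] <- 500L
  expect_gt(otsu_threshold(x, m), 100)
  expect_error(otsu_threshold(matrix(100L, 60, 10), m), "no threshold")
})

test_that("thresholding is inclusive, idempotent and boundary-correct", {
  x <- matrix(c(0L, 5L, 10L, 65535L), 2)
  expect_true(all(threshold_channel(x, 0)))
  expect_false(any(threshold_channel(x, 65536)))
  expect_equal(as.vector(threshold_channel(x, 10)), c(FALSE, FALSE, TRUE, TRUE))
  m1 <- threshold_channel(x, 10)
  m2 <- threshold_channel(x, attr(m1, "threshold"))
  expect_identical(m1, m2)
})

test_that("raising the threshold never adds positive pixels", {
  set.seed(12)
  x <- matrix(sample.int(1000, 400, replace = TRUE), 20)
  ts <- sort(sample.int(1000, 10))
  masks <- lapply(ts, function(t) threshold_channel(x, t))
  for (i in seq_len(length(ts) - 1)) {
    expect_true(all(masks[[i]] | !masks[[i + 1]]))  # mask_{t+1} subset of mask_t
  }
})

test_that("fixed policy with the otsu value reproduces the otsu mask", {
  set.seed(5)
  x <- matrix(round(stats::rnorm(2e3, rep(c(30, 180), each = 1e3), 10)), 40)
  t <- otsu_threshold(x)
  auto <- threshold_channel(x, threshold_policy("otsu"), role = "amyloid")
  fixed <- threshold_channel(x, threshold_policy("fixed", c(amyloid = t)),
                             role = "amyloid")
  expect_equal(unclass(auto), unclass(fixed))
  expect_equal(attr(auto, "threshold"), attr(fixed, "threshold"))
})

test_that("per-cohort overrides take precedence and gaps are fatal", {
  pol <- threshold_policy("fixed", values = c(amyloid = 100, marker = 50),
                          overrides = list("IBA-1" = c(marker = 80)))
  expect_equal(resolve_threshold(pol, "marker", "IBA-1"), 80)
  expect_equal(resolve_threshold(pol, "marker", "TUBB3"), 50)
  expect_error(resolve_threshold(pol, "gs", "GS"), "no threshold")
  expect_error(threshold_policy("fixed"), "named")
})

test_that("rater panels write one overlay per candidate, consistently", {
  set.seed(8)
  x <- matrix(sample.int(65535, 600), 30)
  dir <- withr::local_tempdir()
  out <- rater_panel(x, c(10000, 30000, 60000), dir)
  expect_equal(nrow(out), 3)
  expect_true(all(file.exists(out$file)))
  expect_equal(out$n_positive,
               sapply(c(10000, 30000, 60000), function(t) sum(threshold_channel(x, t))))
  expect_error(rater_panel(x, numeric(0), dir), "at least one")
})
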