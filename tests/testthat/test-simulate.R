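test_that("identical seed and scenario give bit-identical images", {
  geo <- small_geometry()
  a <- simulate_image(geo, flat_slice(0.2, 0.3, 2), seed = 11)
  b <- simulate_image(geo, flat_slice(0.2, 0.3, 2), seed = 11)
  expect_identical(a, b)
  c <- simulate_image(geo, flat_slice(0.2, 0.3, 2), seed = 12)
  expect_false(identical(a$truth_red, c$truth_red))
})

test_that("a zero positive fraction yields an empty ground-truth layer", {
  geo <- tiling_mask()
  sl <- flat_slice(0.3, 0.4, 1)
  sl$p_red[sl$layer == "IPL"] <- 0
  img <- simulate_image(geo, sl, seed = 3)
  expect_false(any(img$truth_red[geo == 3L]))
  expect_true(any(img$truth_red[geo == 2L]))
})

test_that("empirical marker fraction concentrates at its marginal", {
  # one 10^4-pixel layer per band; binomial 3-sigma tolerance
  geo <- make_layer_geometry(600, 100, rep(100, 6))
  img <- simulate_image(geo, flat_slice(0.2, 0.3, 1), seed = 42)
  for (lab in 1:6) {
    frac <- mean(img$truth_green[geo == lab])
    expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 1e4))
  }
})

test_that("marginal red fraction is preserved regardless of enrichment", {
  geo <- make_layer_geometry(600, 170, rep(100, 6))  # ~1e5 tissue px
  for (rho in c(1, 3)) {
    img <- simulate_image(geo, flat_slice(0.2, 0.3, rho), seed = 5)
    tissue <- geo >= 1 & geo <= 6
    expect_lt(abs(mean(img$truth_red[tissue]) - 0.2),
              3 * sqrt(0.2 * 0.8 / sum(tissue)))
  }
})

test_that("empirical conditional ratio converges to rho", {
  geo <- make_layer_geometry(600, 170, rep(100, 6))
  tissue <- geo >= 1 & geo <= 6
  for (rho in c(1, 3)) {
    img <- simulate_image(geo, flat_slice(0.2, 0.3, rho), seed = 6)
    g <- img$truth_green[tissue]; r <- img$truth_red[tissue]
    ratio <- mean(r[g]) / mean(r[!g])
    expect_lt(abs(ratio - rho) / rho, 0.1)
  }
})

test_that("foreground and background intensities are separable", {
  geo <- tiling_mask()
  img <- simulate_image(geo, flat_slice(0.5, 0.5, 1), seed = 9)
  fg <- img$red[img$truth_red]
  bg <- img$red[!img$truth_red]
  expect_gt(min(fg), max(bg))  # modes 27 sd apart; no overlap at this n
})

test_that("written dataset has one manifest row per image and round-trips", {
  sc <- default_scenario("IBA-1", n_ad = 2, n_control = 2, n_sections = 2,
                         n_images = 2, geometry = small_geometry(), seed = 21)
  dir <- withr::local_tempdir()
  manifest <- write_dataset(sc, dir)
  expect_equal(nrow(manifest), 4 * 2 * 2 * 2)  # donors x sections x regions x images
  sim <- simulate_cohort(sc)
  rec0 <- sim$records[[1]]
  rec1 <- read_record(manifest[1, ], dir)
  expect_identical(rec1$mask, rec0$mask)
  expect_identical(rec1$channels$amyloid, rec0$channels$amyloid)
  expect_identical(rec1$channels$marker, rec0$channels$marker)
  # collision guard
  expect_error(write_dataset(sc, dir), "manifest already exists")
  # truth sidecar round-trips
  truth <- readr::read_csv(file.path(dir, "truth.csv"), show_col_types = FALSE)
  expect_equal(nrow(truth), 4 * 2 * 6)
})

test_that("study-design layout yields 5*8 + 7*8 manifest rows", {
  sc <- default_scenario("TUBB3", geometry = small_geometry(), seed = 2)
  sim <- simulate_cohort(sc)
  expect_equal(nrow(sim$manifest), 5 * 8 + 7 * 8)
  expect_equal(length(sim$records), 96)
})

test_that("an empty scenario writes an empty manifest and no images", {
  sc <- default_scenario("GS", n_ad = 0, n_control = 0,
                         geometry = small_geometry(), seed = 3)
  dir <- withr::local_tempdir()
  manifest <- write_dataset(sc, dir)
  expect_equal(nrow(manifest), 0)
  expect_length(list.files(dir, pattern = "\\.tif$"), 0)
})

test_that("label masks round-trip through TIFF and NIfTI", {
  m <- small_geometry()
  m[15, 3] <- 7L  # artifact pixel
  dir <- withr::local_tempdir()
  t1 <- file.path(dir, "m.tif"); t2 <- file.path(dir, "m.nii.gz")
  write_mask(m, t1); write_mask(m, t2)
  expect_identical(read_mask(t1), m)
  expect_identical(read_mask(t2), m)
})

test_that("cohort simulation is reproducible end to end", {
  sc <- tiny_scenario(seed = 77)
  a <- simulate_cohort(sc)
  b <- simulate_cohort(sc)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$records[[5]]$channels, b$records[[5]]$channels)
})
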