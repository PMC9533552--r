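one_layer <- function(n = 200, label = 2L) matrix(label, 20, n / 20)

lgl <- function(mask, k) {
  # first k tissue pixels positive
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  out[which(mask >= 1 & mask <= 6)[seq_len(k)]] <- TRUE
  out
}

test_that("layer percentages are positive counts over layer pixels", {
  m <- tiling_mask()
  pos <- matrix(FALSE, 60, 10)
  pos[m == 2L][1:25] <- TRUE
  out <- layer_positive_fraction(pos, m)
  expect_equal(out$percent[out$layer == "GCL"], 25)
  expect_equal(out$percent[out$layer != "GCL"], rep(0, 5))
  empty <- layer_positive_fraction(matrix(FALSE, 60, 10), m)
  expect_equal(empty$percent, rep(0, 6))
})

test_that("artifact pixels leave numerator and denominator", {
  m <- tiling_mask()
  gcl_idx <- which(m == 2L)
  pos <- matrix(FALSE, 60, 10)
  pos[gcl_idx[1:20]] <- TRUE
  m[gcl_idx[1:10]] <- 7L   # artifact over half the positive px
  out <- layer_positive_fraction(pos, m)
  expect_equal(out$positive_px[out$layer == "GCL"], 10L)
  expect_equal(out$layer_px[out$layer == "GCL"], 90L)
})

test_that("conditional colocalization matches the worked contingency", {
  m <- one_layer(200)
  marker <- lgl(m, 50)
  amyloid <- matrix(FALSE, 20, 10)
  amyloid[which(marker)[1:10]] <- TRUE          # 10 of 50 inside
  amyloid[which(!marker)[1:15]] <- TRUE         # 15 of 150 outside
  out <- conditional_coloc(amyloid, marker, m)
  expect_equal(out$p_pos, 20)
  expect_equal(out$p_neg, 10)
  expect_equal(out$n_marker_pos, 50L)
  expect_equal(out$n_marker_neg, 150L)
})

test_that("undefined conditional percentages are NA, never 0", {
  m <- one_layer(100)
  all_marker <- matrix(TRUE, 20, 5)
  out <- conditional_coloc(matrix(FALSE, 20, 5), all_marker, m)
  expect_true(is.na(out$p_neg))
  expect_false(is.na(out$p_pos))
})

test_that("amyloid decomposes exactly over the marker partition", {
  set.seed(90)
  for (i in 1:25) {
    m <- matrix(sample(0:7, 300, replace = TRUE), 15)
    a <- matrix(stats::runif(300) < 0.3, 15)
    mk <- matrix(stats::runif(300) < 0.4, 15)
    cc <- conditional_coloc(a, mk, m)
    fr <- suppressWarnings(layer_positive_fraction(a, m))
    joined <- dplyr::inner_join(cc, fr, by = "layer")
    recon <- joined$p_pos * joined$n_marker_pos / 100
    recon[is.na(recon)] <- 0
    recon_n <- joined$p_neg * joined$n_marker_neg / 100
    recon_n[is.na(recon_n)] <- 0
    expect_equal(recon + recon_n, joined$positive_px)
  }
})

test_that("macroglia partition does exact set algebra", {
  m <- matrix(c(rep(1L, 10), rep(0L, 10)), 4)  # 10-px inner group
  gs <- gfap <- matrix(FALSE, 4, 5)
  gs[c(1, 2, 3)] <- TRUE    # {a,b,c}
  gfap[c(2, 3, 4)] <- TRUE  # {b,c,d}
  out <- macroglia_partition(gs, gfap, m)
  expect_equal(out$layer_group, "inner")
  expect_equal(out$pct_both, 20)
  expect_equal(out$pct_gs_only, 10)
  expect_equal(out$pct_gfap_only, 10)
})

test_that("identical and disjoint stains are degenerate partitions", {
  m <- one_layer(100, label = 4L)  # INL -> outer group
  x <- lgl(m, 30)
  same <- macroglia_partition(x, x, m)
  expect_equal(same$pct_gs_only, 0)
  expect_equal(same$pct_gfap_only, 0)
  expect_equal(same$pct_both, 30)
  y <- matrix(FALSE, 20, 5); y[which(!x)[1:20]] <- TRUE
  disj <- macroglia_partition(x, y, m)
  expect_equal(disj$pct_both, 0)
  expect_equal(disj$pct_gs_only + disj$pct_gfap_only, 30 + 20)
})

test_that("partition conservation holds on arbitrary inputs", {
  set.seed(17)
  for (i in 1:25) {
    m <- matrix(sample(0:7, 400, replace = TRUE), 20)
    gs <- matrix(stats::runif(400) < 0.4, 20)
    gf <- matrix(stats::runif(400) < 0.5, 20)
    out <- macroglia_partition(gs, gf, m)
    lab <- m >= 1 & m <= 6
    for (j in seq_len(nrow(out))) {
      grp_labels <- if (out$layer_group[j] == "inner") 1:3 else 4:6
      inl <- m %in% grp_labels
      expect_equal(out$pct_both[j] + out$pct_gs_only[j],
                   100 * sum(gs & inl) / sum(inl))
      expect_equal(out$pct_both[j] + out$pct_gfap_only[j],
                   100 * sum(gf & inl) / sum(inl))
    }
  }
})

test_that("coverage fraction handles containment, disjointness, arithmetic", {
  m <- one_layer(200)
  amyloid <- lgl(m, 40)
  everywhere <- matrix(TRUE, 20, 10)
  expect_equal(coverage_fraction(amyloid, everywhere, m)$percent, 100)
  nowhere <- matrix(FALSE, 20, 10)
  expect_equal(coverage_fraction(amyloid, nowhere, m)$percent, 0)
  ten <- matrix(FALSE, 20, 10); ten[which(amyloid)[1:10]] <- TRUE
  expect_equal(coverage_fraction(amyloid, ten, m)$percent, 25)
  expect_true(is.na(coverage_fraction(nowhere, everywhere, m)$percent))
})

test_that("quantify_record wires cohorts to their statistics", {
  q <- quantify_record(toy_record("IBA-1"))
  expect_setequal(unique(q$fractions$role), c("amyloid", "marker"))
  expect_false(is.null(q$coloc))
  expect_false(is.null(q$coverage))
  expect_null(q$macroglia)
  qgs <- quantify_record(toy_record("GS"))
  expect_null(qgs$coloc)
  expect_equal(sort(unique(qgs$macroglia$layer_group)), c("inner", "outer"))
  expect_setequal(unique(qgs$fractions$role), c("gs", "gfap"))
})
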