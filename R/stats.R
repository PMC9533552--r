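new_htest <- function(statistic, p.value, method, n, extra = list()) {
  structure(c(list(statistic = statistic, p.value = p.value,
                   method = method, n = n,
                   alternative = "two.sided"), extra),
            class = "ret_htest")
}

#' @export
print.ret_htest <- function(x, ...) {
  cat(sprintf("%s\n  statistic = %.6g, two-sided p = %.6g (n = %s)\n",
              x$method, x$statistic, x$p.value, paste(x$n, collapse = " + ")))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.ret_htest <- function(x, ...) {
  tibble::tibble(statistic = unname(x$statistic), p.value = x$p.value,
                 method = x$method, alternative = x$alternative)
}

#' @export
glance.ret_htest <- function(x, ...) tidy(x)

#' Wilcoxon rank-sum test with exact tie-aware enumeration
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test of two independent
#' samples. When the number of group assignments `choose(n, nx)` is
#' small enough the null distribution of the rank-sum statistic (using
#' midranks, so ties are handled exactly) is enumerated in full and the
#' p-value is the exact permutation probability
#' `P(|W - E W| >= |w - E W|)`. Beyond the enumeration cap a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y numeric samples (NAs dropped).
#' @param exact_limit enumerate exactly while `choose(n, nx)` is at most
#'   this.
#' @return a `ret_htest`: statistic `W` (rank-sum of `x`), two-sided
#'   `p.value`, `method`, group sizes `n`.
#' @examples
#' ranksum_test(c(1, 2, 3), c(4, 5, 6))$p.value  # exact 0.1
#' @export
ranksum_test <- function(x, y, exact_limit = 2e5) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y); n <- nx + ny
  if (nx < 1 || ny < 1) stop("both groups need at least one value", call. = FALSE)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  if (choose(n, nx) <= exact_limit) {
    cmb <- utils::combn(n, nx)
    W_all <- colSums(matrix(r[cmb], nrow = nx))
    p <- mean(abs(W_all - mu) >= abs(w - mu) - 1e-9)
    method <- "Wilcoxon rank-sum (exact tie-aware permutation)"
  } else {
    ties <- table(r)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "Wilcoxon rank-sum (normal approximation, tie-corrected)"
  }
  new_htest(c(W = w), p, method, c(nx, ny))
}

#' Wilcoxon signed-rank test with exact tie-aware null
#'
#' Two-sided one-sample Wilcoxon signed-rank test on paired differences.
#' Zero differences are dropped (the classical convention); ties among
#' absolute differences use midranks. The exact null distribution of the
#' positive-rank sum over all `2^n` sign patterns is computed by dynamic
#' programming (a convolution over doubled midranks, so it is exact with
#' ties) up to `exact_n`; beyond that a tie-corrected normal
#' approximation is used. If every difference is zero the test carries
#' no evidence: p = 1, flagged `all_zero`.
#'
#' @param d numeric differences (NAs dropped).
#' @param exact_n exact enumeration while the number of nonzero
#'   differences is at most this.
#' @return a `ret_htest`: statistic `V` (positive-rank sum), two-sided
#'   `p.value`, `n` (nonzero differences), flag `all_zero`.
#' @examples
#' signrank_test(c(5, 4, 6, 5, 7))$p.value  # exact 2/32
#' @export
signrank_test <- function(d, exact_n = 50) {
  d <- d[!is.na(d)]
  nz <- d[d != 0]
  n <- length(nz)
  if (length(d) == 0) stop("no differences supplied", call. = FALSE)
  if (n == 0) {
    return(new_htest(c(V = 0), 1, "Wilcoxon signed-rank (all differences zero)",
                     0, list(all_zero = TRUE)))
  }
  r <- rank(abs(nz))
  v <- sum(r[nz > 0])
  mu <- n * (n + 1) / 4
  if (n <= exact_n) {
    # distribution of V over sign patterns: convolve doubled midranks
    r2 <- as.integer(round(2 * r))
    dist <- numeric(sum(r2) + 1L)    # index i -> P(2V = i - 1)
    dist[1] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), dist[seq_len(length(dist) - ri)])
      dist <- (dist + shifted) / 2
    }
    v2 <- round(2 * v); mu2 <- 2 * mu
    support <- seq_along(dist) - 1
    p <- sum(dist[abs(support - mu2) >= abs(v2 - mu2) - 1e-9])
    method <- "Wilcoxon signed-rank (exact tie-aware)"
  } else {
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "Wilcoxon signed-rank (normal approximation, tie-corrected)"
  }
  new_htest(c(V = v), min(p, 1), method, n, list(all_zero = FALSE))
}

#' Modified z-score outlier detection
#'
#' Flags outliers with the modified z-score
#' `0.6745 |x - median| / MAD > threshold` (MAD unscaled). When the MAD
#' is zero the scaled mean absolute deviation replaces it; if that is
#' also zero nothing is excluded. The rule is applied iteratively until
#' convergence (removing an extreme value shrinks the MAD, so a single
#' pass is not idempotent; the converged rule is). No exclusion is
#' performed below `min_n` values.
#'
#' @param values numeric vector.
#' @param threshold modified z-score cutoff (default 3.5).
#' @param min_n minimum sample size for any exclusion (default 3).
#' @param iterate repeat until no further exclusion (default TRUE).
#' @return a logical keep-vector aligned with `values`, with the final
#'   scores in `attr(, "scores")`.
#' @examples
#' detect_outliers(c(1, 2, 3, 100))
#' @export
detect_outliers <- function(values, threshold = 3.5, min_n = 3, iterate = TRUE) {
  stopifnot(is.numeric(values))
  keep <- !is.na(values)
  scores <- rep(NA_real_, length(values))
  repeat {
    idx <- which(keep)
    if (length(idx) < min_n) break
    v <- values[idx]
    med <- stats::median(v)
    madv <- stats::median(abs(v - med))
    s <- if (madv > 0) {
      0.6745 * abs(v - med) / madv
    } else {
      meanad <- mean(abs(v - med))
      if (meanad > 0) abs(v - med) / (1.253314 * meanad) else rep(0, length(v))
    }
    scores[idx] <- s
    out <- s > threshold
    if (!any(out) || !iterate) {
      keep[idx[out]] <- FALSE
      break
    }
    keep[idx[out]] <- FALSE
  }
  attr(keep, "scores") <- scores
  keep
}

key_cols <- function(rows) {
  intersect(c("region", "layer", "layer_group"), names(rows))
}

#' Aggregate image-level rows into donor data points
#'
#' The unit of statistical analysis is the data point: one value per
#' donor, region and layer (or inner/outer layer group), defined as the
#' arithmetic mean over that donor's contributing images (up to
#' 2 sections x 2 images = 4 values; fewer when layers or whole images
#' were excluded). `NA` values (undefined ratios) do not contribute.
#'
#' @param rows image-level tibble carrying `donor`, `group`, `region`
#'   and `layer` (or `layer_group`) columns.
#' @param value the value column (tidy-eval).
#' @param mode `"layer"` or `"layer-group"`; in layer-group mode
#'   layer-level rows are first mapped through [layer_group()]. Rows
#'   already carrying `layer_group` are used as-is.
#' @return a tibble of data points: `donor`, `group`, key columns,
#'   `value`, `n_images`.
#' @export
aggregate_points <- function(rows, value, mode = c("layer", "layer-group")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(rows))
  if (mode == "layer-group" && !"layer_group" %in% names(rows)) {
    rows <- dplyr::mutate(rows, layer_group = layer_group(.data$layer))
  }
  key <- if (mode == "layer") "layer" else "layer_group"
  rows |>
    dplyr::filter(!is.na({{ value }})) |>
    dplyr::group_by(.data$donor, .data$group, .data$region,
                    .data[[key]]) |>
    dplyr::summarise(value = mean({{ value }}), n_images = dplyr::n(),
                     .groups = "drop")
}

#' Layer-wise group comparison with outlier screening
#'
#' For every geo-layer key present in the data points, screens each
#' group's values with [detect_outliers()] and compares the surviving
#' AD and control values with the two-sided exact tie-aware
#' [ranksum_test()]. Group means and standard errors (for plotting) are
#' computed on the post-screening values. Keys where either group is
#' empty after screening are returned flagged not-computable.
#'
#' @param points data-point tibble from [aggregate_points()].
#' @param value the value column (tidy-eval, default `value`).
#' @param outlier_threshold,outlier_min_n passed to [detect_outliers()];
#'   set `outlier_threshold = Inf` to disable screening.
#' @param p_adjust `"none"` (default; per-geo-layer p-values are
#'   reported unadjusted) or `"BH"` to add Benjamini-Hochberg adjusted
#'   p-values across keys.
#' @return a tibble, one row per geo-layer: key columns, per-group n
#'   (after exclusion), means and standard errors, excluded values
#'   (list-columns), `statistic`, `p_value`, `stars`, `computable`.
#' @export
compare_groups <- function(points, value = value, outlier_threshold = 3.5,
                           outlier_min_n = 3, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  keys <- key_cols(points)
  stopifnot(length(keys) >= 1, "group" %in% names(points))
  pts <- dplyr::mutate(points, .value = {{ value }})
  out <- pts |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(d, k) {
      one_comparison(d$.value[d$group == "AD"],
                     d$.value[d$group == "control"],
                     outlier_threshold, outlier_min_n)
    }) |>
    dplyr::ungroup()
  if (p_adjust == "BH") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  }
  out$stars <- signif_stars(out$p_value)
  out
}

one_comparison <- function(ad, control, outlier_threshold, outlier_min_n) {
  keep_ad <- detect_outliers(ad, outlier_threshold, outlier_min_n)
  keep_ct <- detect_outliers(control, outlier_threshold, outlier_min_n)
  a <- ad[keep_ad]; b <- control[keep_ct]
  se <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  res <- tibble::tibble(
    n_ad = length(a), n_control = length(b),
    mean_ad = if (length(a)) mean(a) else NA_real_,
    se_ad = se(a),
    mean_control = if (length(b)) mean(b) else NA_real_,
    se_control = se(b),
    excluded_ad = list(ad[!keep_ad]),
    excluded_control = list(control[!keep_ct]))
  if (length(a) >= 1 && length(b) >= 1) {
    t <- ranksum_test(a, b)
    res$statistic <- unname(t$statistic)
    res$p_value <- t$p.value
    res$computable <- TRUE
  } else {
    res$statistic <- NA_real_
    res$p_value <- NA_real_
    res$computable <- FALSE
  }
  res
}

#' Paired colocalization test per geo-layer and group
#'
#' Tests, within one group, whether amyloid positivity is enriched
#' inside the marker footprint: donor-level paired data points
#' (`p_pos`, `p_neg`) are formed per geo-layer (means over images where
#' both percentages are defined), and the paired differences
#' `p_pos - p_neg` are tested with the two-sided exact [signrank_test()].
#' Significant colocalization is declared at `p < alpha` together with a
#' positive median difference. Keys with fewer than `min_pairs` donors
#' are flagged not-computable.
#'
#' @param coloc image-level colocalization tibble (from
#'   [quantify_record()]: columns `donor`, `group`, `region`, `layer`,
#'   `p_pos`, `p_neg`).
#' @param alpha significance level for the colocalization call.
#' @param min_pairs minimum donors per key (default 3).
#' @return a tibble per (group, region, layer): `n_donors`,
#'   `mean_p_pos`, `mean_p_neg`, `median_diff`, `statistic`, `p_value`,
#'   `stars`, `colocalized`, `computable`.
#' @export
paired_coloc_test <- function(coloc, alpha = 0.05, min_pairs = 3) {
  stopifnot(all(c("donor", "group", "region", "layer", "p_pos", "p_neg")
                %in% names(coloc)))
  pts <- coloc |>
    dplyr::filter(!is.na(.data$p_pos), !is.na(.data$p_neg)) |>
    dplyr::group_by(.data$donor, .data$group, .data$region, .data$layer) |>
    dplyr::summarise(p_pos = mean(.data$p_pos), p_neg = mean(.data$p_neg),
                     .groups = "drop")
  out <- pts |>
    dplyr::group_by(.data$group, .data$region, .data$layer) |>
    dplyr::group_modify(function(d, k) {
      diff <- d$p_pos - d$p_neg
      res <- tibble::tibble(n_donors = nrow(d),
                            mean_p_pos = mean(d$p_pos),
                            mean_p_neg = mean(d$p_neg),
                            median_diff = stats::median(diff))
      if (nrow(d) >= min_pairs) {
        t <- signrank_test(diff)
        res$statistic <- unname(t$statistic)
        res$p_value <- t$p.value
        res$computable <- TRUE
      } else {
        res$statistic <- NA_real_
        res$p_value <- NA_real_
        res$computable <- FALSE
      }
      res
    }) |>
    dplyr::ungroup()
  out$stars <- signif_stars(out$p_value)
  out$colocalized <- out$computable & !is.na(out$p_value) &
    out$p_value < alpha & out$median_diff > 0
  out
}

#' Significance stars
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, empty
#' otherwise.
#'
#' @param p numeric p-values.
#' @return character vector of star annotations.
#' @export
signif_stars <- function(p) {
  dplyr::case_when(is.na(p) ~ "",
                   p < 0.001 ~ "***",
                   p < 0.01 ~ "**",
                   p < 0.05 ~ "*",
                   TRUE ~ "")
}

#' Count significant geo-layers
#'
#' Summarises a result table (from [compare_groups()] or
#' [paired_coloc_test()]): the number of geo-layer keys tested and how
#' many reach p < 0.05 / 0.01 / 0.001, split by group when a `group`
#' column is present (as in the per-group colocalization analyses, where
#' calls are reported as "k out of 12 geo-layers").
#'
#' @param results tibble with a `p_value` column.
#' @return a tibble of counts (`n_keys`, `n_p05`, `n_p01`, `n_p001`),
#'   one row per group or a single row.
#' @export
significance_summary <- function(results) {
  stopifnot("p_value" %in% names(results))
  grp <- intersect("group", names(results))
  results |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(n_keys = dplyr::n(),
                     n_p05 = sum(.data$p_value < 0.05, na.rm = TRUE),
                     n_p01 = sum(.data$p_value < 0.01, na.rm = TRUE),
                     n_p001 = sum(.data$p_value < 0.001, na.rm = TRUE),
                     .groups = "drop")
}
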