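# Per-pixel layer assignment honouring artifact pixels and whole-layer
# exclusion flags: returns integer labels with excluded pixels set to NA.
included_labels <- function(mask, exclude = character()) {
  lab <- as.vector(mask)
  lab[lab == BACKGROUND_LABEL | lab == ARTIFACT_LABEL] <- NA_integer_
  if (length(exclude) > 0) {
    drop <- layer_labels()[exclude]
    lab[lab %in% drop] <- NA_integer_
  }
  lab
}

check_aligned <- function(mask, ...) {
  grids <- list(...)
  for (g in grids) {
    stopifnot(is.matrix(g))
    if (!identical(dim(g), dim(mask))) {
      stop("grids must share the layer mask's shape exactly", call. = FALSE)
    }
  }
  validate_layer_mask(mask)
}

per_layer_counts <- function(lab, positive) {
  labs <- layer_labels()[retinal_layers()]
  tibble::tibble(
    layer = retinal_layers(),
    positive_px = unname(vapply(labs, function(l)
      sum(positive[!is.na(lab) & lab == l]), integer(1))),
    layer_px = unname(vapply(labs, function(l)
      sum(lab == l, na.rm = TRUE), integer(1))))
}

#' Layer-wise positive-pixel percentage
#'
#' For each included retinal layer, the percentage of its pixels that are
#' positive in the thresholded channel, normalised by the layer's pixel
#' count (artifact pixels and excluded layers contribute to neither the
#' numerator nor the denominator). Percentages are on the 0--100 scale.
#'
#' @param positive logical positivity matrix (see [threshold_channel()]).
#' @param mask integer layer label matrix.
#' @param exclude character vector of excluded layer names.
#' @return a tibble with columns `layer`, `positive_px`, `layer_px`,
#'   `percent`; excluded layers and layers with zero pixels are absent
#'   (the latter with a warning).
#' @examples
#' m <- make_layer_geometry(60, 10, rep(10, 6))
#' layer_positive_fraction(m == 2, m)   # GCL band fully positive
#' @export
layer_positive_fraction <- function(positive, mask, exclude = character()) {
  check_aligned(mask, positive)
  lab <- included_labels(mask, exclude)
  out <- per_layer_counts(lab, as.vector(positive)) |>
    dplyr::filter(!.data$layer %in% exclude)
  empty <- out$layer[out$layer_px == 0]
  if (length(empty) > 0) {
    warning("layer(s) with zero pixels omitted: ", paste(empty, collapse = ", "),
            call. = FALSE)
  }
  out |>
    dplyr::filter(.data$layer_px > 0) |>
    dplyr::mutate(percent = 100 * .data$positive_px / .data$layer_px)
}

#' Marker-conditional amyloid colocalization per layer
#'
#' For each included layer L, computes the percentage of amyloid-positive
#' pixels inside the marker footprint, `p_pos = 100 |A & M & L| / |M & L|`,
#' and outside it, `p_neg = 100 |A & !M & L| / |!M & L|`. Under the
#' "randomly distributed" null the two percentages coincide; an excess of
#' `p_pos` over `p_neg` is the colocalization signal. A percentage whose
#' denominator is empty is returned as `NA` (undefined, never 0), with
#' both denominators reported.
#'
#' @param amyloid,marker logical positivity matrices.
#' @inheritParams layer_positive_fraction
#' @return a tibble per included layer: `layer`, `n_marker_pos`,
#'   `n_marker_neg`, `p_pos`, `p_neg`.
#' @export
conditional_coloc <- function(amyloid, marker, mask, exclude = character()) {
  check_aligned(mask, amyloid, marker)
  lab <- included_labels(mask, exclude)
  a <- as.vector(amyloid); m <- as.vector(marker)
  labs <- layer_labels()[retinal_layers()]
  out <- purrr::map_dfr(retinal_layers(), function(ly) {
    inl <- !is.na(lab) & lab == labs[[ly]]
    if (!any(inl) && ly %in% exclude) return(NULL)
    n_pos <- sum(inl & m)
    n_neg <- sum(inl & !m)
    tibble::tibble(
      layer = ly, n_marker_pos = n_pos, n_marker_neg = n_neg,
      p_pos = if (n_pos > 0) 100 * sum(a[inl & m]) / n_pos else NA_real_,
      p_neg = if (n_neg > 0) 100 * sum(a[inl & !m]) / n_neg else NA_real_)
  })
  out[!out$layer %in% exclude & (out$n_marker_pos + out$n_marker_neg) > 0, ]
}

#' Three-way macroglia pixel partition (GS / GFAP)
#'
#' Partitions macroglia staining into three disjoint classes -- pixels
#' positive for both GS and GFAP (activated Mueller cells), GS-only
#' (resting Mueller cells), and GFAP-only (astrocytes) -- each expressed
#' as a percentage of the layer-group pixel count. Counts are computed
#' per layer and pooled into the inner (RNFL, GCL, IPL) and outer (INL,
#' OPL, ONL) groups by summing counts, not by averaging percentages, so
#' the partition is the exact pixel-level statistic. By construction
#' `%both + %GS-only` equals the total GS percentage and
#' `%both + %GFAP-only` the total GFAP percentage.
#'
#' @param gs,gfap logical positivity matrices.
#' @inheritParams layer_positive_fraction
#' @return a tibble per non-empty layer group: `layer_group`, `group_px`,
#'   `both_px`, `gs_only_px`, `gfap_only_px`, `pct_both`, `pct_gs_only`,
#'   `pct_gfap_only`.
#' @export
macroglia_partition <- function(gs, gfap, mask, exclude = character()) {
  check_aligned(mask, gs, gfap)
  lab <- included_labels(mask, exclude)
  g <- as.vector(gs); f <- as.vector(gfap)
  groups <- layer_group(retinal_layers())
  labs <- layer_labels()[retinal_layers()]
  purrr::map_dfr(c("inner", "outer"), function(lg) {
    inl <- !is.na(lab) & lab %in% labs[groups == lg]
    n <- sum(inl)
    if (n == 0) return(NULL)
    both <- sum(g[inl] & f[inl])
    gs_only <- sum(g[inl] & !f[inl])
    gfap_only <- sum(!g[inl] & f[inl])
    tibble::tibble(layer_group = lg, group_px = n, both_px = both,
                   gs_only_px = gs_only, gfap_only_px = gfap_only,
                   pct_both = 100 * both / n,
                   pct_gs_only = 100 * gs_only / n,
                   pct_gfap_only = 100 * gfap_only / n)
  })
}

#' Amyloid coverage by microglia per layer
#'
#' The percentage of amyloid-positive pixels that are also
#' microglia-positive (`100 |A & M & L| / |A & L|`), a pixel-level proxy
#' for microglial engagement with deposits. Undefined (`NA`) in layers
#' with no amyloid-positive pixels -- a layer with no amyloid is not a
#' layer with 0% coverage.
#'
#' @param amyloid,microglia logical positivity matrices.
#' @inheritParams layer_positive_fraction
#' @return a tibble per included layer: `layer`, `amyloid_px`,
#'   `covered_px`, `percent`.
#' @export
coverage_fraction <- function(amyloid, microglia, mask, exclude = character()) {
  check_aligned(mask, amyloid, microglia)
  lab <- included_labels(mask, exclude)
  a <- as.vector(amyloid); m <- as.vector(microglia)
  labs <- layer_labels()[retinal_layers()]
  out <- purrr::map_dfr(retinal_layers(), function(ly) {
    inl <- !is.na(lab) & lab == labs[[ly]]
    n_a <- sum(inl & a)
    tibble::tibble(layer = ly, amyloid_px = n_a, covered_px = sum(inl & a & m),
                   percent = if (n_a > 0) 100 * sum(m[inl & a]) / n_a else NA_real_,
                   layer_px = sum(inl))
  })
  out[!out$layer %in% exclude & out$layer_px > 0,
      c("layer", "amyloid_px", "covered_px", "percent")]
}

record_meta <- function(record) {
  tibble::tibble(donor = record$donor, group = record$group,
                 region = record$region, cohort = record$cohort,
                 section = record$section, image = record$image)
}

#' Quantify one image record
#'
#' Applies the threshold policy to the record's analysis channels (the
#' nuclei channel is never thresholded or used in any denominator) and
#' computes every per-image quantity relevant to the record's cohort:
#' layer-wise positive percentages for both channels, the
#' marker-conditional amyloid colocalization contrast (TUBB3 / GFAP /
#' IBA-1 cohorts), amyloid coverage by microglia (IBA-1 cohort), and the
#' GS/GFAP macroglia partition (GS cohort). Unusable records yield empty
#' tables.
#'
#' @param record an [image_record()].
#' @param policy a [threshold_policy()].
#' @return a list of tibbles (`thresholds`, `fractions`, `coloc`,
#'   `coverage`, `macroglia`), each carrying the record's metadata
#'   columns; inapplicable components are `NULL`.
#' @export
quantify_record <- function(record, policy = threshold_policy()) {
  stopifnot(inherits(record, "image_record"))
  meta <- record_meta(record)
  if (!record$usable) {
    return(list(thresholds = dplyr::bind_cols(meta[0, ],
                                              tibble::tibble(role = character(),
                                                             threshold = double())),
                fractions = NULL, coloc = NULL, coverage = NULL,
                macroglia = NULL))
  }
  roles <- setdiff(names(record$channels), "nuclei")
  masks <- purrr::map(stats::setNames(roles, roles), function(role) {
    threshold_channel(record$channels[[role]], policy, role = role,
                      cohort = record$cohort, mask = record$mask)
  })
  excl <- names(record$excluded)
  thresholds <- dplyr::bind_cols(
    meta[rep(1, length(roles)), ],
    tibble::tibble(role = roles,
                   threshold = purrr::map_dbl(masks, attr, "threshold")))
  fractions <- purrr::map_dfr(roles, function(role) {
    dplyr::bind_cols(role = role,
                     suppressWarnings(
                       layer_positive_fraction(masks[[role]], record$mask, excl)))
  })
  fractions <- dplyr::bind_cols(meta[rep(1, nrow(fractions)), ], fractions)

  coloc <- coverage <- macroglia <- NULL
  if (record$cohort == "GS") {
    macroglia <- macroglia_partition(masks[["gs"]], masks[["gfap"]],
                                     record$mask, excl)
    macroglia <- dplyr::bind_cols(meta[rep(1, nrow(macroglia)), ], macroglia)
  } else {
    coloc <- conditional_coloc(masks[["amyloid"]], masks[["marker"]],
                               record$mask, excl)
    coloc <- dplyr::bind_cols(meta[rep(1, nrow(coloc)), ], coloc)
    if (record$cohort == "IBA-1") {
      coverage <- coverage_fraction(masks[["amyloid"]], masks[["marker"]],
                                    record$mask, excl)
      coverage <- dplyr::bind_cols(meta[rep(1, nrow(coverage)), ], coverage)
    }
  }
  list(thresholds = thresholds, fractions = fractions, coloc = coloc,
       coverage = coverage, macroglia = macroglia)
}
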