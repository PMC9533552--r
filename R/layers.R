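#' Retinal layer and label conventions
#'
#' The pipeline analyses six retinal layers of a cross-section, ordered
#' inner to outer along the axial (row) direction: retinal nerve fiber
#' layer (RNFL), ganglion cell layer (GCL), inner plexiform layer (IPL),
#' inner nuclear layer (INL), outer plexiform layer (OPL) and outer
#' nuclear layer (ONL). Label masks use the fixed integer coding
#' `0` background, `1`--`6` RNFL..ONL, `7` artifact (pixels excluded from
#' every denominator).
#'
#' @return `retinal_layers()` returns the six layer names inner to outer;
#'   `layer_labels()` returns the full named label dictionary.
#' @examples
#' retinal_layers()
#' layer_labels()
#' @export
retinal_layers <- function() {
  c("RNFL", "GCL", "IPL", "INL", "OPL", "ONL")
}

#' @rdname retinal_layers
#' @export
layer_labels <- function() {
  c(background = 0L,
    RNFL = 1L, GCL = 2L, IPL = 3L, INL = 4L, OPL = 5L, ONL = 6L,
    artifact = 7L)
}

BACKGROUND_LABEL <- 0L
ARTIFACT_LABEL <- 7L

#' Inner/outer grouping of retinal layers
#'
#' Layers are conventionally pooled into inner (RNFL, GCL, IPL) and outer
#' (INL, OPL, ONL) groups for the macroglia (GS/GFAP) analysis.
#'
#' @param layer character vector of layer names.
#' @return character vector (`"inner"` or `"outer"`) of the same length.
#' @examples
#' layer_group(c("RNFL", "ONL"))
#' @export
layer_group <- function(layer) {
  stopifnot(all(layer %in% retinal_layers()))
  ifelse(layer %in% c("RNFL", "GCL", "IPL"), "inner", "outer")
}

#' Enumerate geo-layers
#'
#' A geo-layer is one cell of the analysis grid: a retinal region
#' (central, ~5 mm from the optic nerve head, or mid-peripheral, ~10 mm)
#' crossed with a retinal layer. In layer mode there are 12 geo-layers
#' (2 regions x 6 layers); in layer-group mode, used for the GS cohort,
#' there are 4 (2 regions x inner/outer).
#'
#' @param mode `"layer"` (default) or `"layer-group"`.
#' @return a tibble with columns `region` and `layer` (or `layer_group`),
#'   one row per geo-layer.
#' @examples
#' geo_layer_keys()
#' geo_layer_keys("layer-group")
#' @export
geo_layer_keys <- function(mode = c("layer", "layer-group")) {
  mode <- match.arg(mode)
  if (mode == "layer") {
    tidyr::expand_grid(region = retinal_regions(), layer = retinal_layers())
  } else {
    tidyr::expand_grid(region = retinal_regions(),
                       layer_group = c("inner", "outer"))
  }
}

#' @rdname geo_layer_keys
#' @export
retinal_regions <- function() {
  c("central", "mid-peripheral")
}

#' Build a banded retinal layer mask
#'
#' Constructs an idealised cross-section geometry: six contiguous,
#' non-overlapping horizontal bands ordered RNFL (top) to ONL (bottom),
#' with any remaining rows labelled background (split between above the
#' RNFL and below the ONL).
#'
#' @param height,width image size in pixels.
#' @param thicknesses numeric vector of six per-layer thicknesses in
#'   pixels (named or in RNFL..ONL order); all must be positive and sum
#'   to at most `height`.
#' @return an integer matrix (`height` x `width`) using [layer_labels()]
#'   coding.
#' @examples
#' m <- make_layer_geometry(60, 10, rep(10, 6))
#' table(m)
#' @export
make_layer_geometry <- function(height, width, thicknesses) {
  stopifnot(length(height) == 1, length(width) == 1, height >= 1, width >= 1)
  if (length(thicknesses) != 6) {
    stop("`thicknesses` must have one entry per retinal layer (6)", call. = FALSE)
  }
  if (!is.null(names(thicknesses))) {
    if (!setequal(names(thicknesses), retinal_layers())) {
      stop("named `thicknesses` must use the layer names RNFL..ONL", call. = FALSE)
    }
    thicknesses <- thicknesses[retinal_layers()]
  }
  thicknesses <- as.integer(thicknesses)
  if (any(thicknesses <= 0)) {
    stop("all layer thicknesses must be > 0 pixels", call. = FALSE)
  }
  total <- sum(thicknesses)
  if (total > height) {
    stop(sprintf("layer thicknesses sum to %d pixels but the image is only %d tall",
                 total, height), call. = FALSE)
  }
  top_bg <- (height - total) %/% 2L
  rows <- c(rep(BACKGROUND_LABEL, top_bg),
            rep.int(1:6, thicknesses),
            rep(BACKGROUND_LABEL, height - total - top_bg))
  matrix(as.integer(rows), nrow = height, ncol = width)
}

validate_layer_mask <- function(mask, what = "layer mask") {
  if (!is.matrix(mask) || !is.numeric(mask)) {
    stop(sprintf("%s must be an integer matrix", what), call. = FALSE)
  }
  bad <- setdiff(unique(as.vector(mask)), layer_labels())
  if (length(bad) > 0) {
    stop(sprintf("unknown label value(s) in %s: %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(mask)
}

layer_name_from_label <- function(label) {
  names(layer_labels())[match(label, layer_labels())]
}
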