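#' Validated multi-channel image record
#'
#' An image record bundles one cross-section image: its layer label mask,
#' the intensity channels (named by role: `amyloid`/`marker`/`nuclei`,
#' or `gs`/`gfap`/`nuclei` in the GS cohort), the sample metadata, and
#' per-layer exclusion flags. All grids must share the mask's shape
#' exactly; masks may only contain the [layer_labels()] values. A record
#' whose mask holds no tissue label (1--6) is flagged unusable.
#'
#' @param donor donor identifier.
#' @param group `"AD"` or `"control"`.
#' @param region `"central"` or `"mid-peripheral"`.
#' @param cohort `"TUBB3"`, `"GFAP"`, `"IBA-1"` or `"GS"`.
#' @param section,image indices within the donor.
#' @param mask integer layer label matrix.
#' @param channels named list of integer intensity matrices.
#' @param excluded named character vector: excluded layer name -> reason.
#' @return an object of class `image_record`.
#' @export
image_record <- function(donor, group, region, cohort, section, image,
                         mask, channels, excluded = character()) {
  group <- match.arg(group, c("AD", "control"))
  region <- match.arg(region, retinal_regions())
  cohort <- match.arg(cohort, c("TUBB3", "GFAP", "IBA-1", "GS"))
  validate_layer_mask(mask)
  required <- if (cohort == "GS") c("gs", "gfap") else c("amyloid", "marker")
  missing_roles <- setdiff(required, names(channels))
  if (length(missing_roles) > 0) {
    stop(sprintf("%s cohort record needs channel role(s): %s",
                 cohort, paste(missing_roles, collapse = ", ")), call. = FALSE)
  }
  for (role in names(channels)) {
    ch <- channels[[role]]
    if (!is.matrix(ch) || !identical(dim(ch), dim(mask))) {
      stop(sprintf("channel '%s' shape does not match the layer mask", role),
           call. = FALSE)
    }
    if (any(ch < 0) || any(ch > 65535)) {
      stop(sprintf("channel '%s' intensities outside the 16-bit range", role),
           call. = FALSE)
    }
  }
  if (length(excluded) > 0 &&
      !all(names(excluded) %in% retinal_layers())) {
    stop("excluded layer names must be retinal layers", call. = FALSE)
  }
  structure(
    list(donor = donor, group = group, region = region, cohort = cohort,
         section = as.integer(section), image = as.integer(image),
         mask = mask, channels = channels, excluded = excluded,
         usable = any(mask >= 1L & mask <= 6L)),
    class = "image_record")
}

#' @export
print.image_record <- function(x, ...) {
  cat(sprintf("<image_record> %s %s %s section %d image %d (%s cohort): %d x %d px",
              x$donor, x$group, x$region, x$section, x$image, x$cohort,
              nrow(x$mask), ncol(x$mask)))
  if (!x$usable) cat(" [UNUSABLE: no tissue labels]")
  if (length(x$excluded) > 0) {
    cat(sprintf("\n  excluded layers: %s", paste(names(x$excluded), collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' Read one image record from a manifest row
#'
#' Loads the channel TIFFs and the label mask referenced by a manifest
#' row (paths relative to `dir`), validates shapes and label values, and
#' applies any persisted layer exclusions matching this image. Shape or
#' label violations are fatal for the record.
#'
#' @param row one manifest row (as written by [write_dataset()]).
#' @param dir dataset directory.
#' @param exclusions optional exclusion audit table (see
#'   [read_exclusions()]); matching rows are re-applied.
#' @return an [image_record()].
#' @export
read_record <- function(row, dir, exclusions = NULL) {
  stopifnot(is.data.frame(row), nrow(row) == 1)
  mask <- read_mask(file.path(dir, row$file_mask))
  roles <- channel_roles(row$cohort)
  channels <- stats::setNames(
    list(read_channel_tiff(file.path(dir, row$file_red)),
         read_channel_tiff(file.path(dir, row$file_green)),
         read_channel_tiff(file.path(dir, row$file_nuclei))),
    c(roles[["red"]], roles[["green"]], "nuclei"))
  excluded <- character()
  if (!is.null(exclusions) && nrow(exclusions) > 0) {
    hit <- exclusions |>
      dplyr::filter(.data$donor == row$donor_id,
                    .data$region == row$region,
                    .data$section == row$section,
                    .data$image == row$image)
    excluded <- stats::setNames(hit$reason, hit$layer)
  }
  image_record(donor = row$donor_id, group = row$group, region = row$region,
               cohort = row$cohort, section = row$section, image = row$image,
               mask = mask, channels = channels, excluded = excluded)
}

#' Exclude a layer from one image
#'
#' Marks a layer so its pixels contribute to no downstream quantity for
#' this image; all other layers are untouched. Painting a whole layer's
#' pixels with the artifact label is equivalent; the flag form preserves
#' the mask. Excluding all six layers removes the image from the
#' analysis entirely.
#'
#' @param record an [image_record()].
#' @param layer layer name (`"RNFL"`..`"ONL"`).
#' @param reason free-text reason, kept for the audit trail.
#' @return the updated record.
#' @export
exclude_layer <- function(record, layer, reason = "artifact") {
  stopifnot(inherits(record, "image_record"))
  layer <- match.arg(layer, retinal_layers())
  record$excluded[layer] <- reason
  record
}

#' Exclusion audit table
#'
#' Layer exclusions are persisted as a plain CSV (donor, region, section,
#' image, layer, reason) so a re-read of the dataset reproduces them.
#'
#' @param records list of [image_record()]s.
#' @param path CSV path.
#' @return `exclusion_audit()` returns the tibble; `write_exclusions()`
#'   writes it and returns the path invisibly; `read_exclusions()` reads
#'   it back.
#' @export
exclusion_audit <- function(records) {
  purrr::map_dfr(records, function(r) {
    if (length(r$excluded) == 0) return(NULL)
    tibble::tibble(donor = r$donor, region = r$region, section = r$section,
                   image = r$image, layer = names(r$excluded),
                   reason = unname(r$excluded))
  })
}

#' @rdname exclusion_audit
#' @export
write_exclusions <- function(records, path) {
  audit <- exclusion_audit(records)
  if (nrow(audit) == 0) {
    audit <- tibble::tibble(donor = character(), region = character(),
                            section = integer(), image = integer(),
                            layer = character(), reason = character())
  }
  readr::write_csv(audit, path)
  invisible(path)
}

#' @rdname exclusion_audit
#' @export
read_exclusions <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(donor = "c", region = "c",
                                          section = "i", image = "i",
                                          layer = "c", reason = "c"))
}

#' Per-label pixel accounting for a layer mask
#'
#' Counts pixels per label. Tissue counts exclude background and
#' artifact pixels by construction (each pixel carries exactly one
#' label), and the per-label counts always sum to the grid size.
#'
#' @param mask integer layer label matrix.
#' @return a tibble with columns `label`, `layer` (label name) and `n`,
#'   covering all eight labels (zero counts included).
#' @examples
#' layer_pixel_counts(make_layer_geometry(60, 10, rep(10, 6)))
#' @export
layer_pixel_counts <- function(mask) {
  validate_layer_mask(mask)
  labs <- layer_labels()
  n <- vapply(labs, function(l) sum(mask == l), integer(1))
  tibble::tibble(label = unname(labs), layer = names(labs), n = unname(n))
}
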