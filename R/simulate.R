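# Run code under a temporary RNG state so simulation helpers are
# reproducible without clobbering the caller's random stream.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

clip16 <- function(x) {
  matrix(as.integer(pmin(pmax(round(x), 0), 65535)), nrow = nrow(x))
}

#' Simulate one multi-channel cross-section image
#'
#' Draws pixel positivity independently per pixel under the joint law of
#' [coloc_conditionals()]: within each layer the green channel is
#' Bernoulli(`p_green`), and the red channel is Bernoulli(`q_pos`) on
#' green-positive pixels and Bernoulli(`q_neg`) on green-negative pixels,
#' so the red marginal equals `p_red` and the conditional ratio equals
#' `rho`. Background and artifact pixels are always negative. Intensities
#' are then drawn from the foreground/background Gaussians of the
#' [intensity_model()], clipped to 16 bits. A DAPI-like nuclei channel is
#' generated for visualisation only.
#'
#' @param geometry integer layer mask (see [make_layer_geometry()]).
#' @param slice tibble with columns `layer`, `p_red`, `p_green`, `rho` --
#'   one row per retinal layer (a scenario restricted to one
#'   (group, region)).
#' @param intensity named list of [intensity_model()]s (`red`, `green`,
#'   `nuclei`).
#' @param seed optional integer; when given the draw is fully
#'   reproducible and the caller's RNG state is untouched.
#' @return a list with integer intensity matrices `red`, `green`,
#'   `nuclei` and logical ground-truth positivity matrices `truth_red`,
#'   `truth_green`.
#' @examples
#' geo <- make_layer_geometry(60, 20, rep(10, 6))
#' sl <- tibble::tibble(layer = retinal_layers(),
#'                      p_red = 0.2, p_green = 0.5, rho = 1)
#' img <- simulate_image(geo, sl, seed = 1)
#' mean(img$truth_green[geo > 0 & geo < 7])
#' @export
simulate_image <- function(geometry, slice,
                           intensity = list(red = intensity_model(),
                                            green = intensity_model(),
                                            nuclei = intensity_model()),
                           seed = NULL) {
  validate_layer_mask(geometry)
  stopifnot(is.data.frame(slice),
            all(c("layer", "p_red", "p_green", "rho") %in% names(slice)))
  if (!setequal(slice$layer, retinal_layers()) || nrow(slice) != 6) {
    stop("`slice` needs exactly one row per retinal layer", call. = FALSE)
  }
  # per-layer conditionals, validated up front naming the offending layer
  cond <- purrr::map(seq_len(nrow(slice)), function(i) {
    tryCatch(coloc_conditionals(slice$p_red[i], slice$p_green[i], slice$rho[i]),
             error = function(e) stop(sprintf("layer %s: %s", slice$layer[i],
                                              conditionMessage(e)), call. = FALSE))
  })
  ord <- match(retinal_layers(), slice$layer)
  p_green_l <- slice$p_green[ord]
  q_pos_l <- purrr::map_dbl(cond, "q_pos")[ord]
  q_neg_l <- purrr::map_dbl(cond, "q_neg")[ord]

  with_local_seed(seed, {
    lab <- as.vector(geometry)
    tissue <- lab >= 1L & lab <= 6L
    n <- length(lab)
    p_green_px <- numeric(n)
    p_green_px[tissue] <- p_green_l[lab[tissue]]
    green <- stats::runif(n) < p_green_px
    q_px <- numeric(n)
    q_px[tissue] <- ifelse(green[tissue], q_pos_l[lab[tissue]], q_neg_l[lab[tissue]])
    red <- stats::runif(n) < q_px
    p_nuc_px <- numeric(n)
    p_nuc_px[tissue] <- NUCLEI_FRACTIONS[lab[tissue]]
    nuc <- stats::runif(n) < p_nuc_px

    draw <- function(pos, m) {
      mu <- ifelse(pos, m$fg_mean, m$bg_mean)
      sd <- ifelse(pos, m$fg_sd, m$bg_sd)
      clip16(matrix(stats::rnorm(n, mu, sd), nrow = nrow(geometry)))
    }
    list(red = draw(red, intensity$red),
         green = draw(green, intensity$green),
         nuclei = draw(nuc, intensity$nuclei),
         truth_red = matrix(red, nrow = nrow(geometry)),
         truth_green = matrix(green, nrow = nrow(geometry)))
  })
}

channel_roles <- function(cohort) {
  if (cohort == "GS") c(red = "gs", green = "gfap") else c(red = "amyloid", green = "marker")
}

# Deterministic per-image sub-seed below 2^31.
derive_seed <- function(seed, idx) {
  as.integer((as.double(seed) + 999983 * as.double(idx)) %% 2147483629)
}

#' Simulate a full cohort in memory
#'
#' Expands a [sim_scenario()] into its image grid (donor x section x
#' region x image), applies donor-level logit random effects to the
#' marginal fractions, and simulates every image. The effects are drawn
#' independently per (donor, region, layer, channel), matching the unit
#' of the downstream statistics (one data point per donor and geo-layer)
#' and modelling donor- and site-level variability in staining and
#' biology. Identical scenario + seed give bit-identical output.
#'
#' @param scenario a `sim_scenario`.
#' @return a list with `records` (a list of [image_record()]s, each with
#'   a `truth` element holding the ground-truth positivity masks and the
#'   realised per-layer parameters), `manifest` (a tibble, one row per
#'   image) and `truth` (long tibble of the realised per-layer marginals
#'   per donor and region).
#' @export
simulate_cohort <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  donors <- scenario$donors
  if (nrow(donors) == 0) {
    return(list(records = list(),
                manifest = empty_manifest(scenario$cohort),
                truth = NULL))
  }
  shift_logit <- function(p, e) stats::plogis(stats::qlogis(p) + e)
  effects <- with_local_seed(scenario$seed, {
    e <- tidyr::expand_grid(donor_id = donors$donor_id,
                            region = retinal_regions(),
                            layer = retinal_layers())
    e$effect_red <- stats::rnorm(nrow(e), 0, scenario$donor_sd)
    e$effect_green <- stats::rnorm(nrow(e), 0, scenario$donor_sd)
    e
  })
  truth <- donors |>
    dplyr::left_join(effects, by = "donor_id") |>
    dplyr::left_join(scenario$params,
                     by = c("group", "region", "layer")) |>
    dplyr::mutate(p_red = shift_logit(.data$p_red, .data$effect_red),
                  p_green = shift_logit(.data$p_green, .data$effect_green)) |>
    dplyr::select("donor_id", "group", "region", "layer",
                  "p_red", "p_green", "rho")

  grid <- tidyr::expand_grid(donor_id = donors$donor_id,
                             section = seq_len(scenario$n_sections),
                             region = retinal_regions(),
                             image = seq_len(scenario$n_images)) |>
    dplyr::left_join(donors, by = "donor_id") |>
    dplyr::mutate(cohort = scenario$cohort,
                  seed = derive_seed(scenario$seed, dplyr::row_number()))

  records <- purrr::map(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    slice <- truth |>
      dplyr::filter(.data$donor_id == g$donor_id, .data$region == g$region) |>
      dplyr::select("layer", "p_red", "p_green", "rho")
    img <- simulate_image(scenario$geometry, slice, scenario$intensity,
                          seed = g$seed)
    roles <- channel_roles(scenario$cohort)
    rec <- image_record(
      donor = g$donor_id, group = g$group, region = g$region,
      cohort = scenario$cohort, section = g$section, image = g$image,
      mask = scenario$geometry,
      channels = stats::setNames(list(img$red, img$green, img$nuclei),
                                 c(roles[["red"]], roles[["green"]], "nuclei")))
    rec$truth <- list(red = img$truth_red, green = img$truth_green,
                      params = slice)
    rec
  })
  list(records = records, manifest = grid, truth = truth)
}

empty_manifest <- function(cohort = character()) {
  tibble::tibble(donor_id = character(), section = integer(),
                 region = character(), image = integer(),
                 group = character(), cohort = character(),
                 seed = integer())
}

#' Write a simulated dataset to disk
#'
#' Simulates the cohort (see [simulate_cohort()]) and writes, per image:
#' one 16-bit grayscale TIFF per channel, one 8-bit label-mask TIFF (and
#' optionally a NIfTI copy for ITK-SNAP interoperability), following the
#' filename pattern `{donor}_{region}_{section}_{image}_{channel}.tif`.
#' A `manifest.csv` (one row per image, with file paths, group, cohort
#' and per-image seed), a `truth.csv` (the realised ground-truth
#' per-layer marginals per donor and region) and a `scenario.yaml`
#' provenance dump are written alongside.
#'
#' @param scenario a `sim_scenario`.
#' @param dir output directory (created if missing).
#' @param nifti_masks also write each label mask as `.nii.gz`.
#' @param overwrite allow replacing an existing `manifest.csv`.
#' @return the manifest tibble, invisibly.
#' @export
write_dataset <- function(scenario, dir, nifti_masks = FALSE, overwrite = FALSE) {
  stopifnot(inherits(scenario, "sim_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(dir, "manifest.csv")
  if (file.exists(manifest_path) && !overwrite) {
    stop("manifest already exists at ", manifest_path,
         " (use overwrite = TRUE)", call. = FALSE)
  }
  sim <- simulate_cohort(scenario)
  manifest <- sim$manifest
  if (nrow(manifest) > 0) {
    stub <- sprintf("%s_%s_%d_%d", manifest$donor_id,
                    gsub("-", "", manifest$region),
                    manifest$section, manifest$image)
    roles <- channel_roles(scenario$cohort)
    manifest$file_red <- paste0(stub, "_", roles[["red"]], ".tif")
    manifest$file_green <- paste0(stub, "_", roles[["green"]], ".tif")
    manifest$file_nuclei <- paste0(stub, "_nuclei.tif")
    manifest$file_mask <- paste0(stub, "_mask.tif")
    for (i in seq_along(sim$records)) {
      rec <- sim$records[[i]]
      write_channel_tiff(rec$channels[[roles[["red"]]]],
                         file.path(dir, manifest$file_red[i]))
      write_channel_tiff(rec$channels[[roles[["green"]]]],
                         file.path(dir, manifest$file_green[i]))
      write_channel_tiff(rec$channels[["nuclei"]],
                         file.path(dir, manifest$file_nuclei[i]))
      write_mask(rec$mask, file.path(dir, manifest$file_mask[i]))
      if (nifti_masks) {
        write_mask(rec$mask, file.path(dir, paste0(stub[i], "_mask.nii.gz")))
      }
    }
  }
  readr::write_csv(manifest, manifest_path)
  if (!is.null(sim$truth)) {
    readr::write_csv(sim$truth, file.path(dir, "truth.csv"))
  }
  yaml::write_yaml(scenario_to_list(scenario), file.path(dir, "scenario.yaml"))
  invisible(manifest)
}

scenario_to_list <- function(scenario) {
  list(cohort = scenario$cohort,
       n_sections = scenario$n_sections,
       n_images = scenario$n_images,
       donor_sd = scenario$donor_sd,
       seed = scenario$seed,
       geometry = list(height = nrow(scenario$geometry),
                       width = ncol(scenario$geometry)),
       intensity = scenario$intensity,
       donors = as.list(scenario$donors),
       params = as.list(scenario$params))
}

#' Image and label-mask file I/O
#'
#' Intensity channels are stored as single-channel 16-bit grayscale TIFF;
#' label masks as 8-bit TIFF using the [layer_labels()] coding, or as
#' NIfTI (`.nii` / `.nii.gz`) for ITK-SNAP interoperability. Read and
#' write round-trip pixel-for-pixel.
#'
#' @param x integer matrix (intensities in `[0, 65535]`, or labels).
#' @param path file path; mask format is chosen by extension.
#' @return readers return an integer matrix; writers return `path`
#'   invisibly.
#' @name image_io
NULL

#' @rdname image_io
#' @export
write_channel_tiff <- function(x, path) {
  stopifnot(is.matrix(x))
  tiff::writeTIFF(x / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname image_io
#' @export
read_channel_tiff <- function(path) {
  if (!file.exists(path)) stop("missing image file: ", path, call. = FALSE)
  x <- tiff::readTIFF(path)
  if (length(dim(x)) != 2) stop("expected single-channel grayscale TIFF: ", path,
                                call. = FALSE)
  matrix(as.integer(round(x * 65535)), nrow = nrow(x))
}

#' @rdname image_io
#' @export
write_mask <- function(x, path) {
  stopifnot(is.matrix(x))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    RNifti::writeNifti(RNifti::asNifti(matrix(as.integer(x), nrow = nrow(x))), path)
  } else {
    tiff::writeTIFF(x / 255, path, bits.per.sample = 8L)
  }
  invisible(path)
}

#' @rdname image_io
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("missing mask file: ", path, call. = FALSE)
  m <- if (grepl("\\.nii(\\.gz)?$", path)) {
    x <- RNifti::readNifti(path)
    matrix(as.integer(x), nrow = dim(x)[1])
  } else {
    x <- tiff::readTIFF(path)
    if (length(dim(x)) != 2) stop("expected single-channel label TIFF: ", path,
                                  call. = FALSE)
    matrix(as.integer(round(x * 255)), nrow = nrow(x))
  }
  validate_layer_mask(m, paste0("mask ", path))
}
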