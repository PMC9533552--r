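#' Conditional positivity probabilities implied by an enrichment ratio
#'
#' The synthetic generator specifies the joint law of the two thresholded
#' channels at one pixel through the red-channel marginal `p_red`, the
#' green-channel marginal `p_green`, and an enrichment ratio `rho`,
#' defined as the ratio of conditional probabilities
#' \deqn{\rho = \frac{P(red+ \mid green+)}{P(red+ \mid green-)}}
#' with the marginal constraint
#' \eqn{p_{red} = p_{green} q_+ + (1 - p_{green}) q_-}. Solving gives
#' \eqn{q_- = p_{red} / (p_{green}\rho + 1 - p_{green})} and
#' \eqn{q_+ = \rho q_-}. `rho = 1` encodes independence of the two
#' channels; `rho > 1` enriches red positivity inside the green-positive
#' footprint while preserving the red marginal.
#'
#' @param p_red,p_green marginal positive fractions in `[0, 1]`.
#' @param rho enrichment ratio, `>= 0`.
#' @return a list with elements `q_pos` = P(red+ | green+) and
#'   `q_neg` = P(red+ | green-), both in `[0, 1]`.
#' @examples
#' coloc_conditionals(0.2, 0.3, 3)
#' @export
coloc_conditionals <- function(p_red, p_green, rho) {
  stopifnot(length(p_red) == 1, length(p_green) == 1, length(rho) == 1)
  if (is.na(p_red) || p_red < 0 || p_red > 1 ||
      is.na(p_green) || p_green < 0 || p_green > 1 ||
      is.na(rho) || rho < 0) {
    stop("need p_red, p_green in [0, 1] and rho >= 0", call. = FALSE)
  }
  if (p_green == 1 && rho != 1) {
    # conditional on green- is vacuous; any rho is formally consistent
    return(list(q_pos = p_red, q_neg = p_red))
  }
  q_neg <- p_red / (p_green * rho + 1 - p_green)
  q_pos <- rho * q_neg
  if (q_pos > 1 + 1e-12 || q_neg > 1 + 1e-12) {
    stop(sprintf(
      "infeasible (p_red = %.4g, p_green = %.4g, rho = %.4g): implied conditionals (%.4g, %.4g) leave [0, 1]",
      p_red, p_green, rho, q_pos, q_neg), call. = FALSE)
  }
  list(q_pos = min(q_pos, 1), q_neg = min(q_neg, 1))
}

#' Default per-channel intensity model
#'
#' Foreground (positive) and background pixels each draw intensities from
#' a Gaussian, clipped to the 16-bit range `[0, 65535]`. Defaults place
#' the two modes far apart (background 3000 +/- 1000, foreground
#' 30000 +/- 3000 grey levels) so a single global threshold separates
#' them, matching the thresholding approach of the analysis.
#'
#' @param fg_mean,fg_sd,bg_mean,bg_sd Gaussian parameters in grey levels.
#' @return a list with the four parameters and the bit depth.
#' @export
intensity_model <- function(fg_mean = 30000, fg_sd = 3000,
                            bg_mean = 3000, bg_sd = 1000) {
  stopifnot(fg_mean > bg_mean, fg_sd > 0, bg_sd > 0)
  list(fg_mean = fg_mean, fg_sd = fg_sd,
       bg_mean = bg_mean, bg_sd = bg_sd, bit_depth = 16L)
}

# DAPI nuclear density per layer: nuclear layers are dense, plexiform and
# fiber layers sparse. Cosmetic only -- nuclei never enter any denominator.
NUCLEI_FRACTIONS <- c(RNFL = 0.05, GCL = 0.35, IPL = 0.05,
                      INL = 0.50, OPL = 0.05, ONL = 0.60)

#' Construct and validate a simulation scenario
#'
#' A scenario fully determines a synthetic cohort: the donor roster, the
#' cross-section/image layout, the banded layer geometry, and for every
#' (group, region, layer) cell the marginal positive fraction of the red
#' channel (`p_red`: amyloid, or GS in the GS cohort), of the green
#' channel (`p_green`: TUBB3/GFAP/IBA-1, or GFAP in the GS cohort), and
#' the red-in-green enrichment ratio `rho` (see [coloc_conditionals()]).
#'
#' A per-donor, per-channel random effect on the logit scale (sd
#' `donor_sd`) models inter-donor variability in staining and biology;
#' set `donor_sd = 0` for exactly parameter-faithful images.
#'
#' @param cohort one of `"TUBB3"`, `"GFAP"`, `"IBA-1"`, `"GS"`.
#' @param params tibble with columns `group` (`"AD"`/`"control"`),
#'   `region`, `layer`, `p_red`, `p_green`, `rho`; one row per
#'   (group, region, layer).
#' @param n_ad,n_control donors per group.
#' @param n_sections cross-sections per donor.
#' @param n_images images per region per cross-section.
#' @param geometry layer mask from [make_layer_geometry()] used for every
#'   image.
#' @param intensity named list of [intensity_model()]s for `red`, `green`
#'   and `nuclei`.
#' @param donor_sd sd of the per-donor logit random effect.
#' @param seed integer seed controlling the whole cohort.
#' @return an object of class `sim_scenario`.
#' @seealso [default_scenario()] for the study-condition defaults.
#' @export
sim_scenario <- function(cohort, params, n_ad = 5, n_control = 7,
                         n_sections = 2, n_images = 2,
                         geometry = make_layer_geometry(180, 200, default_thicknesses()),
                         intensity = list(red = intensity_model(),
                                          green = intensity_model(),
                                          nuclei = intensity_model()),
                         donor_sd = 0.15, seed = 20221005) {
  cohort <- match.arg(cohort, c("TUBB3", "GFAP", "IBA-1", "GS"))
  stopifnot(is.data.frame(params))
  needed <- c("group", "region", "layer", "p_red", "p_green", "rho")
  missing_cols <- setdiff(needed, names(params))
  if (length(missing_cols) > 0) {
    stop("scenario params missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  full <- tidyr::expand_grid(group = c("AD", "control"),
                             region = retinal_regions(),
                             layer = retinal_layers())
  if (nrow(dplyr::anti_join(full, params, by = c("group", "region", "layer"))) > 0) {
    stop("scenario params must cover every (group, region, layer) cell",
         call. = FALSE)
  }
  # feasibility of every cell, naming the offender
  for (i in seq_len(nrow(params))) {
    tryCatch(
      coloc_conditionals(params$p_red[i], params$p_green[i], params$rho[i]),
      error = function(e) {
        stop(sprintf("infeasible scenario cell %s / %s / %s: %s",
                     params$group[i], params$region[i], params$layer[i],
                     conditionMessage(e)), call. = FALSE)
      })
  }
  validate_layer_mask(geometry, "scenario geometry")
  stopifnot(n_ad >= 0, n_control >= 0, n_sections >= 1, n_images >= 1,
            donor_sd >= 0)
  stopifnot(setequal(names(intensity), c("red", "green", "nuclei")))
  donors <- tibble::tibble(
    donor_id = c(sprintf("A%d", seq_len(n_ad)), sprintf("C%d", seq_len(n_control))),
    group = rep(c("AD", "control"), c(n_ad, n_control)))
  structure(
    list(cohort = cohort,
         params = tibble::as_tibble(params[needed]),
         donors = donors,
         n_sections = as.integer(n_sections),
         n_images = as.integer(n_images),
         geometry = geometry,
         intensity = intensity,
         donor_sd = donor_sd,
         seed = as.integer(seed)),
    class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("<sim_scenario> %s cohort: %d AD + %d control donors, %d section(s) x %d image(s) per region\n",
              x$cohort, sum(x$donors$group == "AD"),
              sum(x$donors$group == "control"), x$n_sections, x$n_images))
  cat(sprintf("  geometry %d x %d px, donor_sd = %g, seed = %d\n",
              nrow(x$geometry), ncol(x$geometry), x$donor_sd, x$seed))
  invisible(x)
}

#' @rdname sim_scenario
#' @export
default_thicknesses <- function() {
  c(RNFL = 20, GCL = 20, IPL = 30, INL = 25, OPL = 15, ONL = 35)
}

#' Study-condition default scenarios
#'
#' Returns the scenario the package uses to emulate the cross-section
#' study design: 5 AD and 7 control donors, two cross-sections each, and
#' two images per region (central / mid-peripheral) per cross-section.
#' Per-cohort positive fractions encode the qualitative layer profiles of
#' the analysis: amyloid elevated (2x) in AD mid-peripheral GCL/IPL/INL/
#' OPL with no central group difference; GFAP reduced and IBA-1 elevated
#' in AD mid-peripheral layers; the GS cohort with reduced activated-
#' Mueller (GS & GFAP) overlap in AD mid-peripheral retina. Enrichment
#' ratios encode strong amyloid-neuron colocalization (TUBB3), weak
#' amyloid-astroglia colocalization (GFAP), and amyloid-microglia
#' colocalization that is strong in controls but blunted in AD (IBA-1).
#'
#' @inheritParams sim_scenario
#' @param ... passed on to [sim_scenario()].
#' @return a `sim_scenario`.
#' @examples
#' default_scenario("IBA-1")
#' @export
default_scenario <- function(cohort = c("TUBB3", "GFAP", "IBA-1", "GS"),
                             n_ad = 5, n_control = 7, seed = 20221005, ...) {
  cohort <- match.arg(cohort)
  layers <- retinal_layers()
  # control amyloid positive fractions (percent / 100), per region
  ab_central <- c(RNFL = 0.015, GCL = 0.020, IPL = 0.015,
                  INL = 0.012, OPL = 0.015, ONL = 0.008)
  ab_midper <- c(RNFL = 0.020, GCL = 0.025, IPL = 0.020,
                 INL = 0.016, OPL = 0.020, ONL = 0.010)
  ab_elevated <- c("GCL", "IPL", "INL", "OPL")
  amyloid <- function(group, region) {
    p <- if (region == "central") ab_central else ab_midper
    if (group == "AD" && region == "mid-peripheral") {
      p[ab_elevated] <- 2 * p[ab_elevated]
    }
    p
  }
  gfap_ctrl <- c(RNFL = 0.40, GCL = 0.25, IPL = 0.15,
                 INL = 0.08, OPL = 0.10, ONL = 0.04)
  iba_ctrl <- c(RNFL = 0.030, GCL = 0.040, IPL = 0.050,
                INL = 0.030, OPL = 0.040, ONL = 0.020)
  tubb_both <- c(RNFL = 0.50, GCL = 0.40, IPL = 0.35,
                 INL = 0.25, OPL = 0.20, ONL = 0.15)
  gs_both <- c(RNFL = 0.20, GCL = 0.25, IPL = 0.25,
               INL = 0.30, OPL = 0.25, ONL = 0.20)

  cell <- function(group, region) {
    if (cohort == "GS") {
      p_red <- gs_both
      p_green <- gfap_ctrl
      if (group == "AD" && region == "mid-peripheral") p_green <- 0.6 * p_green
      rho <- if (group == "AD" && region == "mid-peripheral") 2.0 else 2.5
    } else {
      p_red <- amyloid(group, region)
      p_green <- switch(cohort,
        "TUBB3" = tubb_both,
        "GFAP" = if (group == "AD" && region == "mid-peripheral")
                   0.6 * gfap_ctrl else gfap_ctrl,
        "IBA-1" = if (group == "AD" && region == "mid-peripheral")
                    1.8 * iba_ctrl else iba_ctrl)
      rho <- switch(cohort,
        "TUBB3" = 3.0,
        "GFAP" = 1.2,
        "IBA-1" = if (group == "AD") 1.5 else 3.0)
    }
    tibble::tibble(group = group, region = region, layer = layers,
                   p_red = unname(p_red[layers]),
                   p_green = unname(p_green[layers]),
                   rho = rho)
  }
  params <- dplyr::bind_rows(purrr::map(c("AD", "control"), function(g) {
    dplyr::bind_rows(purrr::map(retinal_regions(), function(r) cell(g, r)))
  }))
  sim_scenario(cohort, params, n_ad = n_ad, n_control = n_control,
               seed = seed, ...)
}
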