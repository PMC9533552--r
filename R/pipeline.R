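KNOWN_CONFIG_KEYS <- c("data_dir", "output_dir", "threshold", "outlier",
                       "alpha", "seed", "scenario", "nifti_masks")

#' Pipeline configuration
#'
#' Builds and validates the single configuration object driving
#' [run_simulate()] and [run_analyze()]. Unknown keys are rejected; the
#' validated configuration is archived into the output directory for
#' provenance on every run.
#'
#' @param x a named list, or the path of a YAML file holding one.
#'   Recognised keys: `data_dir` (dataset directory holding
#'   `manifest.csv` and images), `output_dir`, `threshold` (list:
#'   `mode` = `"otsu"`/`"fixed"`, `values`, `overrides`), `outlier`
#'   (list: `threshold`, `min_n`), `alpha`, `seed`, `nifti_masks`, and
#'   `scenario` (list passed to [default_scenario()]: `cohort`, `n_ad`,
#'   `n_control`, `n_sections`, `n_images`, `donor_sd`, `seed`).
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(x) {
  if (is.character(x) && length(x) == 1) x <- yaml::read_yaml(x)
  stopifnot(is.list(x))
  unknown <- setdiff(names(x), KNOWN_CONFIG_KEYS)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(x$data_dir)) stop("config needs `data_dir`", call. = FALSE)
  x$output_dir <- x$output_dir %||% file.path(x$data_dir, "results")
  x$alpha <- x$alpha %||% 0.05
  x$seed <- as.integer(x$seed %||% 20221005)
  x$outlier <- utils::modifyList(list(threshold = 3.5, min_n = 3),
                                 x$outlier %||% list())
  th <- x$threshold %||% list(mode = "otsu")
  x$threshold_policy <- threshold_policy(
    mode = th$mode %||% "otsu",
    values = if (!is.null(th$values)) unlist(th$values),
    overrides = purrr::map(th$overrides %||% list(), unlist))
  x$nifti_masks <- isTRUE(x$nifti_masks)
  structure(x, class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a dataset from a configuration
#'
#' Builds the scenario described by `config$scenario` (study-condition
#' defaults from [default_scenario()], overridable per key) and writes
#' the dataset with [write_dataset()] into `config$data_dir`.
#'
#' @param config a [pipeline_config()] (or something coercible to one).
#' @return the manifest tibble, invisibly.
#' @export
run_simulate <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  sc <- config$scenario %||% list()
  scenario <- do.call(default_scenario,
                      utils::modifyList(list(seed = config$seed), sc))
  manifest <- write_dataset(scenario, config$data_dir,
                            nifti_masks = config$nifti_masks, overwrite = TRUE)
  log_jsonl(file.path(config$data_dir, "simulate_log.jsonl"), list(
    event = "simulate", cohort = scenario$cohort,
    n_images = nrow(manifest), seed = scenario$seed))
  invisible(manifest)
}

#' Analyze a set of image records in memory
#'
#' The core of the analysis stage, shared by [run_analyze()] and usable
#' directly on the output of [simulate_cohort()]: thresholds every
#' record, computes all per-image quantities ([quantify_record()]),
#' aggregates them into donor data points, screens outliers, and runs
#' the geo-layer group comparisons and the paired colocalization tests.
#'
#' @param records list of [image_record()]s (one cohort).
#' @param policy a [threshold_policy()].
#' @param outlier_threshold,outlier_min_n outlier screening parameters
#'   (see [detect_outliers()]).
#' @param alpha significance level for calls and summaries.
#' @return a named list of tibbles: `thresholds`, `fractions`,
#'   `fraction_points`, `fraction_comparisons`, and (per cohort type)
#'   `coloc`, `coloc_tests`, `coloc_summary`, `coverage`,
#'   `coverage_comparisons`, `macroglia`, `macroglia_comparisons`.
#' @export
analyze_records <- function(records, policy = threshold_policy(),
                            outlier_threshold = 3.5, outlier_min_n = 3,
                            alpha = 0.05) {
  stopifnot(length(records) > 0)
  quant <- purrr::map(records, quantify_record, policy = policy)
  pull <- function(name) {
    tabs <- purrr::compact(purrr::map(quant, name))
    if (length(tabs) == 0) NULL else dplyr::bind_rows(tabs)
  }
  thresholds <- pull("thresholds")
  fractions <- pull("fractions")
  out <- list(thresholds = thresholds, fractions = fractions)

  if (!is.null(fractions) && nrow(fractions) > 0) {
    out$fraction_points <- fractions |>
      dplyr::group_by(.data$role) |>
      dplyr::group_modify(function(d, k) {
        aggregate_points(d, .data$percent, mode = "layer")
      }) |>
      dplyr::ungroup()
    out$fraction_comparisons <- out$fraction_points |>
      dplyr::group_by(.data$role) |>
      dplyr::group_modify(function(d, k) {
        compare_groups(d, outlier_threshold = outlier_threshold,
                       outlier_min_n = outlier_min_n)
      }) |>
      dplyr::ungroup()
  }
  coloc <- pull("coloc")
  if (!is.null(coloc) && nrow(coloc) > 0) {
    out$coloc <- coloc
    out$coloc_tests <- paired_coloc_test(coloc, alpha = alpha)
    out$coloc_summary <- significance_summary(out$coloc_tests)
  }
  coverage <- pull("coverage")
  if (!is.null(coverage) && nrow(coverage) > 0) {
    out$coverage <- coverage
    pts <- aggregate_points(coverage, .data$percent, mode = "layer")
    out$coverage_comparisons <- compare_groups(
      pts, outlier_threshold = outlier_threshold, outlier_min_n = outlier_min_n)
  }
  macroglia <- pull("macroglia")
  if (!is.null(macroglia) && nrow(macroglia) > 0) {
    out$macroglia <- macroglia
    long <- macroglia |>
      tidyr::pivot_longer(c("pct_both", "pct_gs_only", "pct_gfap_only"),
                          names_to = "measure", values_to = "percent")
    out$macroglia_comparisons <- long |>
      dplyr::group_by(.data$measure) |>
      dplyr::group_modify(function(d, k) {
        pts <- aggregate_points(d, .data$percent, mode = "layer-group")
        compare_groups(pts, outlier_threshold = outlier_threshold,
                       outlier_min_n = outlier_min_n)
      }) |>
      dplyr::ungroup()
  }
  out
}

#' Analyze a dataset from a configuration
#'
#' Reads the manifest and every referenced image/mask under
#' `config$data_dir` (applying any persisted exclusions in
#' `exclusions.csv`), runs [analyze_records()], and writes all result
#' tables, a combined p-value dump, a structured JSON-lines run log and
#' the archived configuration into `config$output_dir`. Reading or
#' validation failures abort the run naming the offending file.
#'
#' @param config a [pipeline_config()] (or path / list coercible to
#'   one).
#' @return the [analyze_records()] result list, invisibly.
#' @export
run_analyze <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  manifest_path <- file.path(config$data_dir, "manifest.csv")
  if (!file.exists(manifest_path)) {
    stop("no manifest at ", manifest_path, call. = FALSE)
  }
  manifest <- readr::read_csv(manifest_path, show_col_types = FALSE)
  excl_path <- file.path(config$data_dir, "exclusions.csv")
  exclusions <- if (file.exists(excl_path)) read_exclusions(excl_path) else NULL
  records <- purrr::map(seq_len(nrow(manifest)), function(i) {
    read_record(manifest[i, ], config$data_dir, exclusions)
  })
  res <- analyze_records(records, policy = config$threshold_policy,
                         outlier_threshold = config$outlier$threshold,
                         outlier_min_n = config$outlier$min_n,
                         alpha = config$alpha)
  write_results(res, records, config)
  invisible(res)
}

write_results <- function(res, records, config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  flatten_lists <- function(d) {
    dplyr::mutate(d, dplyr::across(
      dplyr::where(is.list),
      ~ purrr::map_chr(.x, function(v) paste(signif(v, 6), collapse = ";"))))
  }
  for (name in names(res)) {
    if (is.data.frame(res[[name]])) {
      readr::write_csv(flatten_lists(res[[name]]),
                       file.path(config$output_dir, paste0(name, ".csv")))
    }
  }
  pvals <- purrr::map_dfr(
    intersect(c("fraction_comparisons", "coloc_tests",
                "coverage_comparisons", "macroglia_comparisons"), names(res)),
    function(nm) {
      d <- res[[nm]]
      tibble::tibble(analysis = nm,
                     key = do.call(paste, c(d[intersect(
                       c("group", "role", "measure", "region", "layer",
                         "layer_group"), names(d))], sep = "/")),
                     p_value = d$p_value)
    })
  readr::write_csv(pvals, file.path(config$output_dir, "all_p_values.csv"))
  log_path <- file.path(config$output_dir, "run_log.jsonl")
  unlink(log_path)
  if (!is.null(res$thresholds)) {
    for (i in seq_len(nrow(res$thresholds))) {
      log_jsonl(log_path, c(list(event = "threshold"),
                            as.list(res$thresholds[i, ])))
    }
  }
  audit <- exclusion_audit(records)
  for (i in seq_len(nrow(audit))) {
    log_jsonl(log_path, c(list(event = "layer_excluded"), as.list(audit[i, ])))
  }
  cfg <- unclass(config)
  cfg$threshold_policy <- NULL
  yaml::write_yaml(cfg, file.path(config$output_dir, "config.yaml"))
  invisible(config$output_dir)
}

log_jsonl <- function(path, entry) {
  con <- file(path, open = "a")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA), con)
}

#' End-to-end demonstration run
#'
#' Simulates all four marker cohorts under the study-condition defaults
#' ([default_scenario()]), analyzes each in memory, and (optionally)
#' writes the result tables per cohort. The whole run is deterministic
#' given `seed`.
#'
#' @param out_dir optional output directory; when given, result CSVs are
#'   written under one subdirectory per cohort.
#' @param seed integer seed for the simulated cohorts.
#' @param cohorts which cohorts to run.
#' @return a named list (per cohort) of [analyze_records()] results.
#' @export
run_demo <- function(out_dir = NULL, seed = 20221005,
                     cohorts = c("TUBB3", "GFAP", "IBA-1", "GS")) {
  res <- purrr::map(stats::setNames(cohorts, cohorts), function(co) {
    scenario <- default_scenario(co, seed = derive_seed(seed, match(co, cohorts)))
    sim <- simulate_cohort(scenario)
    analyze_records(sim$records)
  })
  if (!is.null(out_dir)) {
    for (co in cohorts) {
      cfg <- pipeline_config(list(data_dir = out_dir,
                                  output_dir = file.path(out_dir, co)))
      write_results(res[[co]], list(), cfg)
    }
  }
  res
}
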