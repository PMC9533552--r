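#' Donor cohort demographics
#'
#' The donor roster of the cross-section study this pipeline is designed
#' around: 9 AD donors and 12 age-matched controls (two controls with
#' unknown age and sex). Used for the age-matching check bundled with
#' the package; the analysis itself never consumes these rows.
#'
#' @return a tibble with columns `donor_id`, `group`, `age`, `sex`,
#'   `preparation`.
#' @examples
#' donor_demographics() |> dplyr::count(group)
#' @export
donor_demographics <- function() {
  tibble::tribble(
    ~donor_id, ~group, ~age, ~sex, ~preparation,
    "A1", "AD", 89, "M", "cross-section",
    "A2", "AD", 82, "F", "cross-section",
    "A3", "AD", 55, "F", "cross-section",
    "A4", "AD", 84, "M", "cross-section",
    "A5", "AD", 83, "M", "cross-section",
    "A6", "AD", 70, "M", "punch",
    "A7", "AD", 80, "M", "punch",
    "A8", "AD", 76, "F", "punch",
    "A9", "AD", 80, "M", "cross-section",
    "C1", "control", 80, "M", "cross-section",
    "C2", "control", 80, NA, "cross-section",
    "C3", "control", 72, "F", "cross-section",
    "C4", "control", 75, "M", "cross-section",
    "C5", "control", 75, "M", "cross-section",
    "C6", "control", 79, "M", "cross-section",
    "C7", "control", 75, "M", "cross-section",
    "C8", "control", 70, "M", "punch",
    "C9", "control", 68, "M", "punch",
    "C10", "control", 74, "M", "punch",
    "C11", "control", NA, NA, "cross-section",
    "C12", "control", NA, NA, "cross-section")
}

#' Age-matching check on the donor cohort
#'
#' Computes the per-group mean ages of the donors with a recorded age
#' and compares the two age distributions with the package's exact
#' tie-aware [ranksum_test()] -- the same machinery used for every
#' geo-layer comparison.
#'
#' @return a list: `mean_ad`, `mean_control`, `n_ad`, `n_control`, and
#'   `test` (a `ret_htest`).
#' @examples
#' age_matching_check()$mean_control
#' @export
age_matching_check <- function() {
  demo <- donor_demographics() |> dplyr::filter(!is.na(.data$age))
  ad <- demo$age[demo$group == "AD"]
  ct <- demo$age[demo$group == "control"]
  list(mean_ad = mean(ad), mean_control = mean(ct),
       n_ad = length(ad), n_control = length(ct),
       test = ranksum_test(ad, ct))
}
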