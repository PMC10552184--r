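# Packaged reference tables: published multi-laboratory challenge statistics.

read_extdata <- function(file) {
  tibble::as_tibble(
    utils::read.csv(system.file("extdata", file, package = "vxmkit"),
                    stringsAsFactors = FALSE))
}

#' Published DSA statistics from ASHI VXM challenge reports
#'
#' Per-DSA inter-laboratory statistics printed in challenge summary reports:
#' the percentage of laboratories reporting each donor-specific antibody for
#' a cell/serum pair, the mean and standard deviation of the reported MFIs,
#' the printed %CV, the antibody-survey consensus call with its agreement
#' percentage, and the pair-level percentages of laboratories predicting and
#' reporting positive T/B-cell crossmatches. The %CV column is redundant with
#' mean and SD and serves as a cross-check of the rounding convention
#' (see [round_half_up()]).
#'
#' @return A tibble, one row per (cell, serum, DSA).
#' @export
vxm_challenge_stats <- function() read_extdata("challenge_dsa_stats.csv")

#' Challenge participation counts, 2018-2022
#'
#' Per-challenge laboratory and virtual-crossmatch counts, with case-study
#' components as separate rows.
#'
#' @return A tibble with columns `year`, `challenge`, `component`, `n_labs`,
#'   `n_vxm`.
#' @export
vxm_participation <- function() read_extdata("participation.csv")

#' 2022 antibody/crossmatch survey demographics
#'
#' Participating laboratories per country in the two 2022 survey rounds.
#'
#' @return A tibble with columns `country`, `ac1`, `ac2`.
#' @export
vxm_demographics <- function() read_extdata("demographics_2022.csv")

#' 2022 VXM-1 participant group sizes
#'
#' Laboratory counts of the three crossmatch testing groups.
#'
#' @return A tibble with columns `group`, `n_labs`.
#' @export
vxm_groups <- function() read_extdata("groups_2022.csv")
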