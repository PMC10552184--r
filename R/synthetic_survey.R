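# Synthetic multi-laboratory survey generator with scenario presets.

CUTOFF_MIX_DEFAULT <- c("500-1000" = 0.66, "1001-2000" = 0.34)

CLASS1_TEMPLATE <- c(
  "A*01:01", "A*02:01", "A*03:01", "A*23:01", "A*24:02",
  "B*07:02", "B*08:01", "B*14:02", "B*18:01", "B*27:05", "B*38:01", "B*44:02",
  "C*02:02", "C*05:01", "C*06:02", "C*07:01")

CLASS2_TEMPLATE <- c(
  "DRB1*01:01", "DRB1*03:01", "DRB1*03:02", "DRB1*04:01", "DRB1*07:01",
  "DRB1*08:01", "DRB1*11:01", "DRB1*12:01", "DRB1*13:01", "DRB1*13:03",
  "DRB1*14:01", "DRB1*15:01", "DRB3*01:01", "DRB3*02:02", "DRB4*01:01",
  "DRB5*01:01", "DQA1*01:04/DQB1*05:01", "DQA1*05:01/DQB1*02:01",
  "DPB1*04:01")

#' Scenario presets for the synthetic survey generator
#' @format Character vector of preset names.
#' @export
VXM_SCENARIOS <- c("low_level_dsa", "off_panel_allele", "c_locus_only",
                   "shared_eplet", "high_mfi_cdc_negative", "custom")

scenario_preset <- function(scenario) {
  switch(
    scenario,
    # a single low-level class I DSA near the cutoff range: laboratories
    # split on whether they report it, and on the physical T-cell FCXM
    low_level_dsa = list(
      donor = donor_typing("cell-low", "A*02:01"),
      panel_template = CLASS1_TEMPLATE,
      true_profile = c("A*02:01" = 1377),
      interlab_cv = 0.44,
      pxm_model = list(t = c(-1.70, 1), b = c(-1.70, 1))
    ),
    # donor allele absent from the panel; same-group beads act as surrogates
    off_panel_allele = list(
      donor = donor_typing("cell-offpanel", "A*02:05"),
      panel_template = CLASS1_TEMPLATE,
      true_profile = c("A*02:01" = 1377),
      interlab_cv = 0.44,
      pxm_model = list(t = c(-1.70, 1), b = c(-1.70, 1))
    ),
    # strong C-locus-only DSA: clinically relevant despite lower HLA-C
    # surface expression
    c_locus_only = list(
      donor = donor_typing("cell-clocus", c("C*05:01", "C*06:02")),
      panel_template = CLASS1_TEMPLATE,
      true_profile = c("C*05:01" = 10024, "C*06:02" = 8924),
      interlab_cv = 0.30,
      pxm_model = list(t = c(-4.18, 1), b = c(-7.16, 1))
    ),
    # off-panel DR allele with all shared-eplet carrier beads stacking at
    # low MFI; the physical B-cell FCXM is positive although most virtual
    # assessments, driven by the weak surrogate beads, are negative
    shared_eplet = list(
      donor = donor_typing("cell-eplet", "DRB1*13:02"),
      panel_template = CLASS2_TEMPLATE,
      true_profile = c("DRB1*08:01" = 1250, "DRB1*11:01" = 1280,
                       "DRB1*12:01" = 1220, "DRB1*13:01" = 1201,
                       "DRB1*13:03" = 1336, "DRB1*14:01" = 1260,
                       "DRB1*03:01" = 1300, "DRB1*03:02" = 1310),
      interlab_cv = 0.19,
      pxm_model = list(t = c(-3.89, 0), b = c(2.442, 0))
    ),
    # very strong single class I DSA: FCXM clearly positive, but complement
    # fixation is unknown so the CDC prediction stays indeterminate; the
    # physical CDC is modelled consensus-negative
    high_mfi_cdc_negative = list(
      donor = donor_typing("cell-cdc", "B*08:01"),
      panel_template = CLASS1_TEMPLATE,
      true_profile = c("B*08:01" = 12235),
      interlab_cv = 0.30,
      pxm_model = list(t = c(-8.76, 1), b = c(-8.76, 1),
                       cdc_t = c(-14.68, 1), cdc_b = c(-14.68, 1))
    ),
    stop("unknown scenario '", scenario, "'", call. = FALSE)
  )
}

#' Configure a synthetic multi-laboratory survey
#'
#' Defines the generative model for one cell/serum combination assessed by
#' `n_labs` laboratories. Each laboratory draws every bead MFI log-normally
#' around the bead's true value with linear-scale coefficient of variation
#' `interlab_cv`, draws its positivity cutoff uniformly within a band
#' assigned by `cutoff_mix` (default: 66% of laboratories in 500-1000 MFI,
#' 34% in 1001-2000 MFI), reports DSA and virtual predictions by running the
#' package's own assessment engine on its noisy panel, and reports a physical
#' crossmatch drawn from a per-cell-type logistic model on the weighted true
#' DSA signal.
#'
#' Named presets (see [VXM_SCENARIOS]) bundle a donor, panel template, true
#' reactivity profile and physical-crossmatch model for the archetypal
#' discordance scenarios; `scenario = "custom"` requires `donor`,
#' `panel_template` and `true_profile`.
#'
#' @param scenario One of [VXM_SCENARIOS].
#' @param n_labs Number of laboratories (>= 1).
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the configuration.
#' @param interlab_cv Linear-scale CV of the per-laboratory MFI draws (> 0).
#' @param cutoff_mix Named probabilities over `"lo-hi"` cutoff bands,
#'   summing to 1.
#' @param pxm_model List of `c(intercept, slope)` pairs (elements `t`, `b`,
#'   optionally `cdc_t`, `cdc_b`); the physical positive probability is
#'   `plogis(intercept + slope * signal / 1000)` with `signal` the
#'   locus-weighted true DSA sum for that cell type.
#' @param donor,panel_template,true_profile Custom scenario inputs: a
#'   [donor_typing()], a character vector of bead specificities, and a named
#'   vector of true MFIs for reactive beads (others sit at
#'   `background_mfi`).
#' @param background_mfi True MFI of non-reactive beads.
#' @param threshold_jitter Log-scale SD of the per-laboratory multiplicative
#'   jitter on prediction thresholds (laboratories differ in their
#'   MFI-to-crossmatch calibration).
#' @param eplet_analysis_rate Fraction of laboratories performing
#'   eplet-pattern analysis on top of cutoff-based DSA calling; the rest run
#'   the assessment without eplet-inferred candidates, mirroring the reported
#'   heterogeneity in analysis practice.
#' @param cutoffs_base,thresholds_base Base [cutoff_policy()] (its global
#'   value is replaced by each laboratory's drawn cutoff) and
#'   [prediction_thresholds()].
#' @return A `scenario_config`.
#' @export
scenario_config <- function(scenario = "custom", n_labs = 50, seed = 1,
                            interlab_cv = NULL,
                            cutoff_mix = CUTOFF_MIX_DEFAULT,
                            pxm_model = NULL,
                            donor = NULL, panel_template = NULL,
                            true_profile = NULL,
                            background_mfi = 60,
                            threshold_jitter = 0.1,
                            eplet_analysis_rate = 0.3,
                            cutoffs_base = cutoff_policy(),
                            thresholds_base = prediction_thresholds()) {
  scenario <- match.arg(scenario, VXM_SCENARIOS)
  if (scenario != "custom") {
    preset <- scenario_preset(scenario)
    donor <- donor %||% preset$donor
    panel_template <- panel_template %||% preset$panel_template
    true_profile <- true_profile %||% preset$true_profile
    interlab_cv <- interlab_cv %||% preset$interlab_cv
    pxm_model <- pxm_model %||% preset$pxm_model
  }
  interlab_cv <- interlab_cv %||% 0.30
  pxm_model <- pxm_model %||% list(t = c(-6, 1), b = c(-5, 1))
  if (is.null(donor) || is.null(panel_template) || is.null(true_profile)) {
    stop("custom scenarios need donor, panel_template and true_profile",
         call. = FALSE)
  }
  stopifnot(n_labs >= 1, interlab_cv > 0,
            eplet_analysis_rate >= 0, eplet_analysis_rate <= 1,
            abs(sum(cutoff_mix) - 1) < 1e-8,
            all(names(true_profile) %in% panel_template))
  structure(
    list(scenario = scenario, n_labs = as.integer(n_labs),
         seed = as.integer(seed), interlab_cv = interlab_cv,
         cutoff_mix = cutoff_mix, pxm_model = pxm_model, donor = donor,
         panel_template = panel_template, true_profile = true_profile,
         background_mfi = background_mfi,
         threshold_jitter = threshold_jitter,
         eplet_analysis_rate = eplet_analysis_rate,
         cutoffs_base = cutoffs_base, thresholds_base = thresholds_base),
    class = "scenario_config"
  )
}

with_preserved_rng <- function(code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
  }
  force(code)
}

band_bounds <- function(band) {
  as.numeric(strsplit(band, "-", fixed = TRUE)[[1]])
}

#' Generate a synthetic multi-laboratory survey dataset
#'
#' Runs the generative model described in [scenario_config()]. All draws
#' flow from one seeded stream in a fixed order (per laboratory: cutoff band
#' and value, bead MFIs, threshold jitter, physical crossmatch outcomes), so
#' identical configurations produce identical datasets, and datasets differing
#' only in a true MFI value share all other randomness.
#'
#' @param cfg A [scenario_config()].
#' @return A `survey_dataset`: list with `submissions` (one row per lab:
#'   cutoff, virtual predictions, physical results), `dsa` (long table of
#'   reported DSA with MFI and match mode), `donors`, `config`.
#' @examples
#' ds <- generate_survey(scenario_config("low_level_dsa", n_labs = 20,
#'                                       seed = 42))
#' head(ds$submissions)
#' @export
generate_survey <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  template <- data.frame(
    bead_id = sprintf("bead%02d", seq_along(cfg$panel_template)),
    specificity = cfg$panel_template,
    raw_mfi = ifelse(cfg$panel_template %in% names(cfg$true_profile),
                     cfg$true_profile[cfg$panel_template],
                     cfg$background_mfi),
    stringsAsFactors = FALSE
  )
  cell_id <- cfg$donor$donor_id
  serum_id <- paste0("serum-", cfg$scenario)

  # noiseless truth: donor-directed weighted signal per cell type, feeding
  # the physical-crossmatch model
  truth_panel <- sab_panel(template, serum_id = serum_id)
  truth_cut <- cfg$cutoffs_base
  truth_cut$global <- min(vapply(names(cfg$cutoff_mix),
                                 function(b) band_bounds(b)[1], numeric(1)))
  truth_calls <- identify_dsa(cfg$donor, truth_panel, truth_cut,
                              include_eplet_calls = FALSE)
  sig_t <- fcxm_signal(truth_calls, cfg$thresholds_base, "t")
  sig_b <- fcxm_signal(truth_calls, cfg$thresholds_base, "b")
  p_of <- function(coef, signal) {
    if (is.null(coef)) NA_real_ else stats::plogis(coef[1] + coef[2] *
                                                     signal / 1000)
  }
  p_t <- p_of(cfg$pxm_model$t, sig_t)
  p_b <- p_of(cfg$pxm_model$b, sig_b)
  p_cdc_t <- p_of(cfg$pxm_model$cdc_t, sig_t)
  p_cdc_b <- p_of(cfg$pxm_model$cdc_b, sig_b)

  sdlog <- sqrt(log(1 + cfg$interlab_cv^2))
  nb <- nrow(template)
  sub_rows <- vector("list", cfg$n_labs)
  dsa_rows <- vector("list", cfg$n_labs)

  with_preserved_rng({
    set.seed(cfg$seed)
    for (i in seq_len(cfg$n_labs)) {
      lab <- sprintf("lab%03d", i)
      band <- sample(names(cfg$cutoff_mix), 1, prob = cfg$cutoff_mix)
      bounds <- band_bounds(band)
      lab_cutoff <- stats::runif(1, bounds[1], bounds[2])
      mfis <- stats::rlnorm(nb, meanlog = log(template$raw_mfi),
                            sdlog = sdlog)
      jit <- stats::rlnorm(3, 0, cfg$threshold_jitter)
      do_eplet <- stats::runif(1) < cfg$eplet_analysis_rate
      phys_u <- stats::runif(4)

      lab_panel <- sab_panel(
        transform(template, raw_mfi = mfis), serum_id = serum_id)
      cut <- cfg$cutoffs_base
      cut$global <- lab_cutoff
      base <- cfg$thresholds_base
      th <- prediction_thresholds(
        t_fcxm = base$t_fcxm * jit[1], b_fcxm = base$b_fcxm * jit[2],
        cdc = base$cdc * jit[3], locus_weights = base$locus_weights,
        additive = base$additive,
        indeterminate_band = base$indeterminate_band)
      calls <- identify_dsa(cfg$donor, lab_panel, cut,
                            include_eplet_calls = do_eplet)
      fc <- predict_fcxm(calls, th)
      cdc <- predict_cdcxm(calls, th, complement_binding = NULL)

      reported <- calls[calls$match_mode != "eplet_inferred", , drop = FALSE]
      if (nrow(reported) > 0L) {
        dsa_rows[[i]] <- tibble::tibble(
          lab_id = lab, cell_id = cell_id, serum_id = serum_id,
          specificity = reported$donor_target, mfi = reported$mfi,
          match_mode = reported$match_mode)
      }
      draw <- function(p, u) {
        if (is.na(p)) NA_character_
        else if (u < p) "positive" else "negative"
      }
      sub_rows[[i]] <- tibble::tibble(
        lab_id = lab, cell_id = cell_id, serum_id = serum_id,
        cutoff = lab_cutoff,
        t_vxm = fc$t, b_vxm = fc$b,
        t_cdc_vxm = cdc$t, b_cdc_vxm = cdc$b,
        t_fcxm = draw(p_t, phys_u[1]), b_fcxm = draw(p_b, phys_u[2]),
        t_cdcxm = draw(p_cdc_t, phys_u[3]),
        b_cdcxm = draw(p_cdc_b, phys_u[4]))
    }
  })

  structure(
    list(submissions = dplyr::bind_rows(sub_rows),
         dsa = if (all(vapply(dsa_rows, is.null, logical(1)))) {
           tibble::tibble(lab_id = character(), cell_id = character(),
                          serum_id = character(), specificity = character(),
                          mfi = numeric(), match_mode = character())
         } else dplyr::bind_rows(dsa_rows),
         donors = stats::setNames(list(cfg$donor), cell_id),
         config = cfg),
    class = "survey_dataset"
  )
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat("<survey_dataset> scenario ", x$config$scenario, ", ",
      nrow(x$submissions), " labs, ", nrow(x$dsa), " DSA reports\n", sep = "")
  invisible(x)
}

#' Recover inter-laboratory dispersion parameters from a generated survey
#'
#' Thin wrapper over [dsa_summary()] for parameter-recovery checks: with
#' enough laboratories the recovered linear-scale CV converges to the
#' configured `interlab_cv`.
#'
#' @param dataset A `survey_dataset`.
#' @param specificity DSA specificity to summarize.
#' @return List with `n`, `mean`, `sd` and `cv` (percent, unrounded).
#' @export
recover_parameters <- function(dataset, specificity) {
  s <- dsa_summary(dataset, specificity)
  if (s$n_reporting < 2L) {
    stop("parameter recovery needs at least 2 reporting laboratories",
         call. = FALSE)
  }
  list(n = s$n_reporting, mean = s$mean_mfi, sd = s$sd_mfi,
       cv = 100 * s$sd_mfi / s$mean_mfi)
}

#' Write a survey dataset to CSV files
#'
#' Emits `submissions.csv`, `dsa.csv`, one `donor_<id>.csv` per donor and
#' `panel_template.csv` in the formats the package's readers accept.
#'
#' @param dataset A `survey_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_survey <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(dataset$submissions, file.path(dir, "submissions.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$dsa, file.path(dir, "dsa.csv"), row.names = FALSE)
  for (id in names(dataset$donors)) {
    d <- dataset$donors[[id]]
    utils::write.csv(
      data.frame(locus = d$loci,
                 allele = vapply(d$entries, format, character(1))),
      file.path(dir, paste0("donor_", id, ".csv")), row.names = FALSE)
  }
  utils::write.csv(
    data.frame(bead_id = sprintf("bead%02d",
                                 seq_along(dataset$config$panel_template)),
               specificity = dataset$config$panel_template),
    file.path(dir, "panel_template.csv"), row.names = FALSE)
  invisible(dir)
}
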