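# Proficiency-survey consensus grading and inter-laboratory statistics.

#' Round half away from zero
#'
#' Survey percentages and %CV values are conventionally rounded half-up to
#' integers (43.54 -> 44, 80.77 -> 81), unlike R's banker's rounding.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Integer percentage of a count
#'
#' `pct(26, 47)` is 55: the half-up-rounded percentage used throughout survey
#' reporting.
#'
#' @param n Numerator count.
#' @param d Denominator count.
#' @export
pct <- function(n, d) {
  if (length(d) == 1L && d == 0) return(NA_real_)
  round_half_up(100 * n / d)
}

new_consensus_result <- function(analyte, n_labs, n_other, percent_agreement,
                                 consensus_call, graded, threshold, min_n) {
  structure(
    list(analyte = analyte, n_labs = n_labs, n_other = n_other,
         percent_agreement = percent_agreement,
         consensus_call = consensus_call, graded = graded,
         threshold = threshold, min_n = min_n),
    class = "consensus_result"
  )
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("<consensus_result>", if (!is.null(x$analyte)) x$analyte else "",
      "\n  n =", x$n_labs,
      if (x$n_other > 0) paste0("(+", x$n_other, " other)") else "",
      "\n  agreement:", x$percent_agreement, "% ->",
      x$consensus_call, if (x$graded) "(graded)" else "(not graded)", "\n")
  invisible(x)
}

consensus_grade <- function(reports, threshold, min_n, analyte) {
  reports <- as.character(reports)
  reports <- reports[!is.na(reports)]
  if (length(reports) == 0L) {
    stop("no reports to grade", call. = FALSE)
  }
  informative <- reports[reports %in% c("positive", "negative")]
  n_other <- length(reports) - length(informative)
  n <- length(informative)
  if (n == 0L) {
    return(new_consensus_result(analyte, 0L, n_other, NA_real_, "none",
                                FALSE, threshold, min_n))
  }
  n_pos <- sum(informative == "positive")
  shares <- c(positive = 100 * n_pos / n, negative = 100 * (n - n_pos) / n)
  top <- which.max(shares)
  call <- if (shares[top] >= threshold) names(shares)[top] else "none"
  new_consensus_result(
    analyte, n, n_other,
    percent_agreement = round_half_up(shares[[top]]),
    consensus_call = call,
    graded = n >= min_n && call != "none",
    threshold = threshold, min_n = min_n
  )
}

#' Grade a crossmatch analyte by laboratory consensus
#'
#' A physical T- or B-cell FCXM/CDCXM analyte reaches consensus when at least
#' `threshold`% (default 80%) of laboratories report the same
#' positive/negative result, and is graded only when at least `min_n`
#' (default 10) laboratories reported. Reports other than
#' positive/negative (`"other"`, indeterminate, `NA`) are excluded from the
#' consensus denominator but counted separately.
#'
#' @param reports Character vector of per-laboratory results
#'   (`"positive"`/`"negative"`; other values tallied as other).
#' @param threshold Consensus threshold in percent (inclusive).
#' @param min_n Minimum number of informative laboratories for grading.
#' @param analyte Optional analyte label.
#' @return A `consensus_result`.
#' @examples
#' grade_crossmatch(rep(c("positive", "negative"), c(81, 19)))
#' @export
grade_crossmatch <- function(reports, threshold = 80, min_n = 10,
                             analyte = NULL) {
  consensus_grade(reports, threshold, min_n, analyte)
}

#' Grade an antibody specificity by laboratory consensus
#'
#' Antibody specificities use the stricter 90% rule: a specificity reported
#' by at least 90% of participants, either positive or negative, reaches
#' consensus (again with a minimum of 10 laboratories for grading).
#'
#' @inheritParams grade_crossmatch
#' @examples
#' grade_specificity(rep(c("positive", "negative"), c(99, 1)),
#'                   analyte = "DR12")
#' @export
grade_specificity <- function(reports, threshold = 90, min_n = 10,
                              analyte = NULL) {
  consensus_grade(reports, threshold, min_n, analyte)
}

#' Inter-laboratory summary statistics for one DSA
#'
#' Computes the percentage of submitting laboratories that reported the DSA,
#' and the mean, sample standard deviation (n - 1) and half-up-rounded
#' percent coefficient of variation (%CV = 100 x SD / mean) of the reported
#' MFIs.
#'
#' @param mfis MFI values from the laboratories reporting the DSA.
#' @param n_submitters Number of laboratories submitting the cell/serum pair.
#' @param single_sd With a single reporter, report the SD as `NA` (default)
#'   or as zero.
#' @return A `summary_stats` list: `n_reporting`, `percent_labs`, `mean_mfi`,
#'   `sd_mfi`, `cv_percent`.
#' @examples
#' summarize_dsa(c(1000, 2000, 3000), n_submitters = 3)
#' @export
summarize_dsa <- function(mfis, n_submitters,
                          single_sd = c("na", "zero")) {
  single_sd <- match.arg(single_sd)
  mfis <- mfis[!is.na(mfis)]
  n <- length(mfis)
  if (any(mfis < 0)) stop("negative MFI", call. = FALSE)
  out <- list(n_reporting = n,
              percent_labs = if (n == 0L) 0 else pct(n, n_submitters),
              mean_mfi = NA_real_, sd_mfi = NA_real_, cv_percent = NA_real_)
  if (n >= 1L) {
    out$mean_mfi <- mean(mfis)
    out$sd_mfi <- if (n >= 2L) stats::sd(mfis)
                  else if (single_sd == "zero") 0 else NA_real_
    if (!is.na(out$sd_mfi) && out$mean_mfi > 0) {
      out$cv_percent <- round_half_up(100 * out$sd_mfi / out$mean_mfi)
    }
  }
  structure(out, class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf(
    "<summary_stats> %d labs (%s%%), mean MFI %.0f, SD %s, CV %s%%\n",
    x$n_reporting, format(x$percent_labs), x$mean_mfi,
    format(round_half_up(x$sd_mfi)), format(x$cv_percent)))
  invisible(x)
}

#' DSA summary statistics from a survey dataset
#'
#' Extracts the per-laboratory MFIs reported for a specificity within one
#' cell/serum pair of a [generate_survey()]-style dataset and summarizes
#' them with [summarize_dsa()]. The denominator defaults to the laboratories
#' submitting that pair; `denominator = "all"` uses every laboratory in the
#' dataset.
#'
#' @param dataset A `survey_dataset`.
#' @param specificity Specificity string (canonicalized via [parse_hla()]).
#' @param cell_id,serum_id Pair selector; default to the dataset's only pair.
#' @param denominator `"pair"` or `"all"`.
#' @inheritParams summarize_dsa
#' @export
dsa_summary <- function(dataset, specificity, cell_id = NULL, serum_id = NULL,
                        denominator = c("pair", "all"),
                        single_sd = c("na", "zero")) {
  denominator <- match.arg(denominator)
  spec <- format(parse_hla(specificity))
  dsa <- dataset$dsa
  sub <- dataset$submissions
  if (!is.null(cell_id)) {
    dsa <- dsa[dsa$cell_id == cell_id, , drop = FALSE]
    sub <- sub[sub$cell_id == cell_id, , drop = FALSE]
  }
  if (!is.null(serum_id)) {
    dsa <- dsa[dsa$serum_id == serum_id, , drop = FALSE]
    sub <- sub[sub$serum_id == serum_id, , drop = FALSE]
  }
  if (nrow(sub) == 0L) stop("no submissions for the requested pair",
                            call. = FALSE)
  n_submitters <- if (denominator == "pair") length(unique(sub$lab_id))
                  else length(unique(dataset$submissions$lab_id))
  summarize_dsa(dsa$mfi[dsa$specificity == spec], n_submitters,
                single_sd = single_sd)
}

#' VXM-versus-physical-crossmatch concordance table
#'
#' For every cell/serum pair and cell type, the percentage of laboratories
#' predicting a positive crossmatch in their virtual assessment against the
#' percentage reporting a positive physical crossmatch. Denominators are the
#' laboratories answering each field; indeterminate/other answers count in
#' the denominator, not the numerator.
#'
#' @param dataset A `survey_dataset` (or any list with a `submissions` tibble
#'   carrying `t_vxm`, `b_vxm`, `t_fcxm`, `b_fcxm` and optionally `t_cdcxm`,
#'   `b_cdcxm` columns).
#' @return Tibble with one row per pair x cell type: `n_vxm`, `pct_vxm_pos`,
#'   `n_pxm`, `pct_pxm_pos`.
#' @export
concordance <- function(dataset) {
  sub <- dataset$submissions
  pairs <- unique(sub[, c("cell_id", "serum_id")])
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    s <- sub[sub$cell_id == pairs$cell_id[i] &
               sub$serum_id == pairs$serum_id[i], , drop = FALSE]
    for (cell in c("t", "b")) {
      for (assay in c("fcxm", "cdcxm")) {
        vxm_col <- if (assay == "fcxm") paste0(cell, "_vxm")
                   else paste0(cell, "_cdc_vxm")
        pxm_col <- paste0(cell, "_", assay)
        if (!vxm_col %in% names(s) && !pxm_col %in% names(s)) next
        vxm <- if (vxm_col %in% names(s)) s[[vxm_col]] else character()
        pxm <- if (pxm_col %in% names(s)) s[[pxm_col]] else character()
        vxm <- vxm[!is.na(vxm)]
        pxm <- pxm[!is.na(pxm)]
        if (length(vxm) == 0L && length(pxm) == 0L) next
        rows[[length(rows) + 1L]] <- tibble::tibble(
          cell_id = pairs$cell_id[i], serum_id = pairs$serum_id[i],
          cell_type = cell, assay = assay,
          n_vxm = length(vxm),
          pct_vxm_pos = pct(sum(vxm == "positive"), length(vxm)),
          n_pxm = length(pxm),
          pct_pxm_pos = pct(sum(pxm == "positive"), length(pxm))
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(cell_id = character(), serum_id = character(),
                          cell_type = character(), assay = character(),
                          n_vxm = integer(), pct_vxm_pos = numeric(),
                          n_pxm = integer(), pct_pxm_pos = numeric()))
  }
  dplyr::bind_rows(rows)
}

#' Participation totals across challenges
#'
#' Sums per-challenge virtual-crossmatch counts (including case-study
#' components) and reports simple participation descriptives.
#'
#' @param records Data frame with a `n_vxm` column and optionally `n_labs`.
#' @return List with `total_vxm`, `n_components` and `median_labs`.
#' @examples
#' participation_summary(vxm_participation())
#' @export
participation_summary <- function(records) {
  if (nrow(records) == 0L) {
    return(list(total_vxm = 0, n_components = 0L, median_labs = NA_real_))
  }
  if (!"n_vxm" %in% names(records)) {
    stop("records must have a n_vxm column", call. = FALSE)
  }
  list(
    total_vxm = sum(records$n_vxm),
    n_components = nrow(records),
    median_labs = if ("n_labs" %in% names(records)) {
      stats::median(records$n_labs, na.rm = TRUE)
    } else NA_real_
  )
}

#' Category trends in general-entry responses
#'
#' Per-year percentage of laboratories in each category of a general-entry
#' question (serum treatment, vendor count, cutoff band). Years with no
#' responses are omitted; within a year the integer percentages sum to 100
#' up to rounding.
#'
#' @param responses Data frame with columns `year` and the category field.
#' @param field Name of the category column.
#' @return Tibble: `year`, `category`, `n`, `pct`.
#' @export
entry_trends <- function(responses, field) {
  if (!all(c("year", field) %in% names(responses))) {
    stop("responses must have columns year and ", field, call. = FALSE)
  }
  responses <- responses[!is.na(responses[[field]]), , drop = FALSE]
  out <- lapply(split(responses, responses$year), function(chunk) {
    counts <- table(chunk[[field]])
    tibble::tibble(year = chunk$year[1],
                   category = names(counts),
                   n = as.integer(counts),
                   pct = pct(as.integer(counts), nrow(chunk)))
  })
  dplyr::bind_rows(out)
}
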